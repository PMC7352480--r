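#' Build a log-odds scoring matrix from a PWM
#'
#' Each motif column is mixed with a pseudo-probability before taking
#' log2 odds against the background:
#' `score(i, b) = log2(((1 - 4 * pseudo) * p[b, i] + pseudo) / bg[b])`.
#' The matrix is also integer-scaled (default 1000 units per bit) so
#' that the exact score distribution can be computed by convolution
#' over integer bins.
#'
#' @param motif a [PWMotif-class].
#' @param background length-4 strictly positive probability vector over
#'   A, C, G, T (default uniform).
#' @param pseudo pseudo-probability mixed into each column (default
#'   1e-4); must be > 0 so zero motif entries stay finite.
#' @param scale integer score units per bit (default 1000).
#' @return A [LogOddsMatrix-class].
#' @export
buildLogOdds <- function(motif, background = rep(0.25, 4), pseudo = 1e-4,
                         scale = 1000L) {
  stopifnot(is(motif, "PWMotif"))
  if (length(background) != 4L)
    stop("background must have 4 entries (A, C, G, T)")
  if (any(background <= 0))
    stop("background entries must be strictly positive")
  background <- background / sum(background)
  if (pseudo <= 0) stop("pseudo must be > 0")
  p <- (1 - 4 * pseudo) * motifMatrix(motif) + pseudo
  scores <- log2(p / background)
  dimnames(scores) <- dimnames(motifMatrix(motif))
  int <- round(scores * scale)
  storage.mode(int) <- "integer"
  new("LogOddsMatrix", motifId = motifId(motif), rbpName = rbpName(motif),
      scores = scores, intScores = int, scale = as.numeric(scale),
      background = background)
}

#' Exact null distribution of the integer motif score
#'
#' Distribution of the integer-scaled log-odds score of a random k-mer
#' drawn i.i.d. from the background model, computed position by
#' position: at each motif column the four per-base scores are added
#' with their background weights (a discrete convolution). Exact up to
#' the integer binning; total mass 1 to 1e-9.
#'
#' @param lom a [LogOddsMatrix-class].
#' @return A [ScoreDistribution-class].
#' @export
scoreDistribution <- function(lom) {
  stopifnot(is(lom, "LogOddsMatrix"))
  int <- lom@intScores
  bg <- lom@background
  k <- ncol(int)
  lo <- 0L; hi <- 0L           # current support bounds (offsets)
  probs <- 1                   # mass over scores lo..hi
  for (j in seq_len(k)) {
    sc <- int[, j]
    nlo <- lo + min(sc); nhi <- hi + max(sc)
    acc <- numeric(nhi - nlo + 1L)
    for (b in 1:4) {
      sh <- (lo + sc[b]) - nlo   # left offset of the shifted copy
      idx <- seq.int(sh + 1L, sh + length(probs))
      acc[idx] <- acc[idx] + probs * bg[b]
    }
    probs <- acc; lo <- nlo; hi <- nhi
  }
  nz <- probs > 0
  new("ScoreDistribution", scores = as.integer(seq.int(lo, hi)[nz]),
      probs = probs[nz])
}

#' Tail probability of a score under the null distribution
#'
#' @param dist a [ScoreDistribution-class].
#' @param score integer score(s).
#' @return `P(S >= score)` for each input score.
#' @export
matchPvalue <- function(dist, score) {
  stopifnot(is(dist, "ScoreDistribution"))
  tail <- rev(cumsum(rev(dist@probs)))
  idx <- findInterval(score - 0.5, dist@scores) + 1L
  out <- numeric(length(score))
  inside <- idx <= length(tail)
  out[inside] <- tail[idx[inside]]
  out[!inside] <- 0
  out[score <= min(dist@scores)] <- 1
  out
}

#' Integer score threshold for a match p-value cutoff
#'
#' Smallest integer score `t` with tail mass `P(S >= t) <= alpha` under
#' the exact null distribution. When even the maximal score has tail
#' mass above `alpha` (short or degenerate motifs), the returned value
#' is `max(score) + 1`, a sentinel meaning no window can ever match; its
#' `noMatchPossible` attribute is set to `TRUE`.
#'
#' @param dist a [ScoreDistribution-class].
#' @param alpha match p-value cutoff in (0, 1); default 0.001.
#' @return Integer threshold (with attribute `noMatchPossible`).
#' @export
pvalueThreshold <- function(dist, alpha = 0.001) {
  stopifnot(is(dist, "ScoreDistribution"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single number in (0, 1)")
  tail <- rev(cumsum(rev(dist@probs)))
  ok <- which(tail <= alpha)
  if (!length(ok)) {
    t <- max(dist@scores) + 1L
    attr(t, "noMatchPossible") <- TRUE
  } else {
    t <- dist@scores[min(ok)]
    attr(t, "noMatchPossible") <- FALSE
  }
  t
}

# Map a sequence to base codes 1..4 (A,C,G,T); anything else (N) -> NA.
.baseCodes <- function(sequence) {
  x <- strsplit(toupper(as.character(sequence)), "", fixed = TRUE)[[1]]
  match(x, DNA_BASES)
}

# Integer score of every window of width k; NA where the window covers
# a non-ACGT character.
.windowScores <- function(int, codes) {
  k <- ncol(int)
  L <- length(codes)
  if (L < k) return(integer(0))
  nwin <- L - k + 1L
  total <- numeric(nwin)
  for (j in seq_len(k)) {
    total <- total + int[, j][codes[seq.int(j, j + nwin - 1L)]]
  }
  total
}

#' Scan a sequence for motif matches
#'
#' Reports every offset whose windowed integer score reaches the
#' threshold. Overlapping matches are all reported; windows containing
#' N never match; scanning is sense-strand only (the transcript side of
#' the biology -- regions from minus-strand events are already
#' reverse-complemented at extraction).
#'
#' @param lom a [LogOddsMatrix-class].
#' @param sequence character or DNAString over A, C, G, T, N.
#' @param threshold integer score threshold (from [pvalueThreshold()]).
#' @param dist optional [ScoreDistribution-class]; when supplied, each
#'   match is annotated with its exact tail p-value.
#' @return data.frame with columns `offset` (0-based), `score`
#'   (integer), `score_bits`, and `p_value` (NA unless `dist` given).
#'   Sequences shorter than the motif yield zero rows.
#' @export
scanSequence <- function(lom, sequence, threshold, dist = NULL) {
  stopifnot(is(lom, "LogOddsMatrix"))
  codes <- .baseCodes(sequence)
  sc <- .windowScores(lom@intScores, codes)
  hit <- which(!is.na(sc) & sc >= threshold)
  out <- data.frame(
    offset = hit - 1L,
    score = as.integer(sc[hit]),
    score_bits = sc[hit] / lom@scale,
    p_value = rep(NA_real_, length(hit))
  )
  if (!is.null(dist) && nrow(out)) out$p_value <- matchPvalue(dist, out$score)
  out
}

#' Does a sequence contain at least one motif match?
#'
#' @inheritParams scanSequence
#' @return logical scalar; `TRUE` iff [scanSequence()] is non-empty.
#' @export
hasMatch <- function(lom, sequence, threshold) {
  codes <- .baseCodes(sequence)
  sc <- .windowScores(lom@intScores, codes)
  any(!is.na(sc) & sc >= threshold)
}

# Vectorized presence/absence plus total match counts over many
# sequences; the workhorse behind enrichment counting. Sequences of
# equal length are scored together as one matrix pass per motif column.
.matchStats <- function(lom, seqs, threshold) {
  seqs <- toupper(as.character(seqs))
  int <- lom@intScores
  k <- ncol(int)
  present <- logical(length(seqs))
  totals <- integer(length(seqs))
  lens <- nchar(seqs)
  for (L in unique(lens)) {
    sel <- which(lens == L)
    if (L < k) next
    codes <- matrix(match(unlist(strsplit(seqs[sel], "", fixed = TRUE)),
                          DNA_BASES), nrow = length(sel), byrow = TRUE)
    nwin <- L - k + 1L
    total <- matrix(0, length(sel), nwin)
    for (j in seq_len(k)) {
      total <- total +
        matrix(int[, j][codes[, seq.int(j, j + nwin - 1L), drop = FALSE]],
               nrow = length(sel))
    }
    hits <- !is.na(total) & total >= threshold
    present[sel] <- rowSums(hits) > 0L
    totals[sel] <- rowSums(hits)
  }
  list(present = present, totals = totals)
}

#' Count regions containing a motif
#'
#' "Frequency" is the number of regions whose sequence has at least one
#' match (per-sequence presence), robust to repeat expansions; the total
#' match count across all regions is attached as attribute
#' `totalMatches` for inspection.
#'
#' @param regions a [ScanRegionSet-class], [Biostrings::DNAStringSet],
#'   or character vector of sequences.
#' @param lom a [LogOddsMatrix-class].
#' @param threshold integer score threshold.
#' @return Integer count with attribute `totalMatches`.
#' @export
countFrequency <- function(regions, lom, threshold) {
  seqs <- if (is(regions, "ScanRegionSet")) regionSequences(regions)
          else regions
  st <- .matchStats(lom, seqs, threshold)
  out <- sum(st$present)
  attr(out, "totalMatches") <- sum(st$totals)
  out
}

#' Write motif matches as TSV
#'
#' @param matches data.frame of matches carrying a `region_id` and
#'   `motif_id` column (see [scanRegions()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMatches <- function(matches, path) {
  write.table(matches, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Scan every region of a ScanRegionSet with one motif
#'
#' @param regions a [ScanRegionSet-class].
#' @param lom a [LogOddsMatrix-class].
#' @param alpha match p-value cutoff (default 0.001).
#' @param background,pseudo passed through when `lom` is a
#'   [PWMotif-class] instead of a prebuilt matrix.
#' @return data.frame with columns `region_id`, `motif_id`, `offset`,
#'   `score_bits`, `p_value`.
#' @export
scanRegions <- function(regions, lom, alpha = 0.001,
                        background = rep(0.25, 4), pseudo = 1e-4) {
  if (is(lom, "PWMotif")) lom <- buildLogOdds(lom, background, pseudo)
  dist <- scoreDistribution(lom)
  thr <- pvalueThreshold(dist, alpha)
  seqs <- regionSequences(regions)
  ids <- S4Vectors::mcols(regionRanges(regions))$region_id
  res <- lapply(seq_along(seqs), function(i) {
    m <- scanSequence(lom, seqs[[i]], thr, dist)
    if (!nrow(m)) return(NULL)
    cbind(region_id = ids[i], motif_id = lom@motifId,
          m[, c("offset", "score_bits", "p_value")])
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res))
    return(data.frame(region_id = character(), motif_id = character(),
                      offset = integer(), score_bits = numeric(),
                      p_value = numeric()))
  do.call(rbind, res)
}

#' Estimate a background base composition from sequences
#'
#' Pools base counts over a set of sequences (typically the
#' non-regulated event pool) into A/C/G/T frequencies for use as the
#' scanning background; N and other characters are ignored. A
#' pseudo-count of 1 per base keeps every frequency strictly positive.
#'
#' @param seqs a [ScanRegionSet-class], [Biostrings::DNAStringSet] or
#'   character vector of sequences.
#' @return named numeric vector of 4 probabilities summing to 1.
#' @export
estimateBackground <- function(seqs) {
  if (is(seqs, "ScanRegionSet")) seqs <- regionSequences(seqs)
  chars <- strsplit(paste(toupper(as.character(seqs)), collapse = ""),
                    "", fixed = TRUE)[[1]]
  counts <- table(factor(chars, levels = DNA_BASES)) + 1
  out <- as.numeric(counts) / sum(counts)
  names(out) <- DNA_BASES
  out
}
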