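# Independent oracles and small fixture builders shared across tests.

BASES <- c("A", "C", "G", "T")

clip01 <- function(x) pmin(1, pmax(0, x))

# Brute-force exact score distribution: enumerate all 4^k words,
# score each with the integer matrix, tabulate under the background.
bfScoreDistribution <- function(lom) {
  int <- lom@intScores
  bg <- lom@background
  k <- ncol(int)
  words <- as.matrix(expand.grid(rep(list(1:4), k)))
  sc <- rowSums(vapply(seq_len(k), function(j) int[, j][words[, j]],
                       numeric(nrow(words))))
  pr <- apply(words, 1, function(w) prod(bg[w]))
  agg <- rowsum(pr, sc)
  list(scores = as.integer(rownames(agg)), probs = as.numeric(agg))
}

# Brute-force threshold: smallest integer score with tail mass <= alpha
# over the enumeration (sentinel max+1 when none).
bfThreshold <- function(lom, alpha) {
  d <- bfScoreDistribution(lom)
  tail <- rev(cumsum(rev(d$probs)))
  ok <- which(tail <= alpha)
  if (!length(ok)) max(d$scores) + 1L else d$scores[min(ok)]
}

# Brute-force scan: rescore every window by character lookup,
# independently of the package's integer-code path.
bfScan <- function(lom, sequence, threshold) {
  int <- lom@intScores
  k <- ncol(int)
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  if (L < k) return(integer(0))
  hits <- integer(0)
  for (off in 0:(L - k)) {
    s <- 0
    ok <- TRUE
    for (j in 1:k) {
      b <- match(chars[off + j], BASES)
      if (is.na(b)) { ok <- FALSE; break }
      s <- s + int[b, j]
    }
    if (ok && s >= threshold) hits <- c(hits, off)
  }
  hits
}

# Exhaustive rank-sum two-sided p-value by enumerating every
# assignment of the pooled values to the first group (no ties assumed).
bfRankSumP <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  combs <- utils::combn(length(pooled), n1)
  W <- apply(combs, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  wobs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  lower <- mean(W <= wobs)
  upper <- mean(W >= wobs)
  min(1, 2 * min(lower, upper))
}

# All-pairs brute-force overlap support (half-open intervals).
bfOverlapSupport <- function(evStart, evEnd, evChrom, pkStart, pkEnd,
                             pkChrom, extension) {
  es <- pmax(0, evStart - extension)
  ee <- evEnd + extension
  vapply(seq_along(es), function(i) {
    any(pkChrom == evChrom[i] & pkStart < ee[i] & es[i] < pkEnd)
  }, logical(1))
}

# A minimal event data.frame with sensible defaults.
makeEvents <- function(n, event_type = "ES", chrom = "chr1",
                       start = seq(1000, by = 1000, length.out = n),
                       width = 100, strand = "+",
                       delta_psi = rep(0, n), posterior = rep(0.5, n),
                       psi_control = NULL, gene_id = NULL) {
  if (is.null(psi_control))
    psi_control <- pmin(0.9, pmax(0.05, 0.5 - delta_psi / 2))
  data.frame(
    event_id = sprintf("E%03d", seq_len(n)),
    gene_id = if (is.null(gene_id)) sprintf("G%03d", seq_len(n)) else gene_id,
    event_type = rep_len(event_type, n), chrom = rep_len(chrom, n),
    start = start, end = start + width, strand = rep_len(strand, n),
    psi_control = psi_control, psi_silenced = psi_control + delta_psi,
    delta_psi = delta_psi, posterior = posterior,
    stringsAsFactors = FALSE)
}

makeEventSet <- function(events, reads = NULL, n_rep = 3) {
  if (is.null(reads))
    reads <- matrix(50L, nrow(events), 2 * n_rep)
  SpliceEventSet(events, reads,
                 rep(c("control", "silenced"), each = ncol(reads) / 2))
}

# A genome built from explicit sequences.
makeGenome <- function(...) {
  seqs <- c(...)
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- names(seqs)
  out
}

# Random event table for property-style filter tests.
randomEventSet <- function(n, seed) {
  withr::with_seed(seed, {
    ev <- makeEvents(n,
                     delta_psi = round(runif(n, -0.5, 0.5), 3),
                     posterior = round(runif(n), 3))
    reads <- matrix(rpois(n * 6, 12), n, 6)
    makeEventSet(ev, reads)
  })
}

# A single sharp test motif whose consensus is its unique maximal word.
testMotif <- function(k = 6, consensus = c("A", "C", "A", "C", "A", "C"),
                      p = 0.9) {
  m <- vapply(consensus[seq_len(k)], function(b) {
    v <- rep((1 - p) / 3, 4); names(v) <- BASES; v[b] <- p; v
  }, numeric(4))
  dimnames(m) <- list(BASES, NULL)
  PWMotif("test_motif", m, "TEST")
}

# 8-row toy table exercising the read-support and significance
# filters; the expected subsets are applied by hand:
#   row reads(ctrl | sil)     dPSI  post  expressed  significant  null
#   1   12,11,3 | 15,10,9     0.25  0.95  yes        yes          no
#   2   12,3,3  | 15,10,9     0.25  0.95  no (1 qualifying ctrl)
#   3   50,50,50| 50,50,50    0.10  0.99  yes        no (dPSI at bound)
#   4   50,50,50| 50,50,50   -0.30  0.90  yes        no (post at bound)
#   5   50,50,50| 50,50,50    0.005 0.20  yes        no           yes
#   6   50,50,50| 50,50,50   -0.011 0.20  yes        no           no (dPSI)
#   7   50,50,50| 10,10,3     0.005 0.60  yes        no           no (post)
#   8   9,9,9   | 50,50,50    0.40  0.99  no (0 qualifying ctrl)
toyEventSet <- function() {
  reads <- rbind(
    c(12, 11, 3, 15, 10, 9),
    c(12, 3, 3, 15, 10, 9),
    matrix(50, 4, 6),
    c(50, 50, 50, 10, 10, 3),
    c(9, 9, 9, 50, 50, 50))
  ev <- makeEvents(8,
                   delta_psi = c(0.25, 0.25, 0.10, -0.30, 0.005, -0.011,
                                 0.005, 0.40),
                   posterior = c(0.95, 0.95, 0.99, 0.90, 0.20, 0.20,
                                 0.60, 0.99))
  makeEventSet(ev, reads)
}

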