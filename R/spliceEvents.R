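#' Filter events by read support
#'
#' Retains events whose supporting reads reach `min_reads` in at least
#' `min_samples` samples in each condition (control and silenced).
#'
#' @param x a [SpliceEventSet-class].
#' @param min_reads minimum supporting reads per qualifying sample
#'   (default 10).
#' @param min_samples minimum qualifying samples per condition
#'   (default 2).
#' @return The retained subset of `x`.
#' @export
filterExpressedEvents <- function(x, min_reads = 10, min_samples = 2) {
  stopifnot(is(x, "SpliceEventSet"))
  cond <- conditionLabels(x)
  if (anyNA(cond)) stop("missing condition label in colData")
  reads <- readSupport(x)
  keep <- rep(TRUE, nrow(x))
  for (cc in levels(cond)) {
    sub <- reads[, cond == cc, drop = FALSE]
    keep <- keep & rowSums(sub >= min_reads) >= min_samples
  }
  x[keep, ]
}

#' Call significantly regulated events
#'
#' Keeps events with `|delta_psi| > dpsi_min` and
#' `posterior > prob_min`; boundary values are excluded (strict
#' inequalities).
#'
#' @param x a [SpliceEventSet-class] (typically read-support filtered).
#' @param dpsi_min minimum absolute PSI change (default 0.1).
#' @param prob_min minimum posterior probability (default 0.9).
#' @return The significant subset of `x`.
#' @export
callSignificantEvents <- function(x, dpsi_min = 0.1, prob_min = 0.9) {
  stopifnot(is(x, "SpliceEventSet"))
  x[abs(deltaPsi(x)) > dpsi_min & posteriorProb(x) > prob_min, ]
}

#' Select the non-regulated null pool
#'
#' Keeps events with `|delta_psi| < dpsi_max` and
#' `posterior < prob_max` -- the pool from which control sets are
#' resampled during motif enrichment. Disjoint from the significant
#' set by construction for any thresholds with
#' `dpsi_max <= dpsi_min` and `prob_max <= prob_min`.
#'
#' @param x a [SpliceEventSet-class] (typically read-support filtered).
#' @param dpsi_max maximum absolute PSI change (default 0.01).
#' @param prob_max maximum posterior probability (default 0.5).
#' @param required_types optional character vector; an error is raised
#'   if the pool contains no event of one of these types (enlarge the
#'   simulation or relax thresholds).
#' @return The null-pool subset of `x`.
#' @export
selectNullPool <- function(x, dpsi_max = 0.01, prob_max = 0.5,
                           required_types = NULL) {
  stopifnot(is(x, "SpliceEventSet"))
  out <- x[abs(deltaPsi(x)) < dpsi_max & posteriorProb(x) < prob_max, ]
  if (!is.null(required_types)) {
    miss <- setdiff(required_types, unique(eventType(out)))
    if (length(miss))
      stop("null pool is empty for event type(s) ",
           paste(miss, collapse = ", "),
           "; enlarge the simulation or relax dpsi_max/prob_max")
  }
  out
}

#' Classify APA events as proximal/distal and call the 3'UTR direction
#'
#' Within each gene, APA events are sorted by genomic coordinate; on
#' the plus strand the smallest-coordinate site is proximal and the
#' largest distal (reversed on minus), middle sites are intermediate.
#' The gene-level `utr_direction` reflects how silencing shifts usage:
#' `shortening` when the proximal site gains (its delta PSI > 0) and
#' the distal loses, `lengthening` for the mirror pattern, `ambiguous`
#' when proximal and distal move in the same direction.
#'
#' @param x a [SpliceEventSet-class]; non-APA rows are ignored.
#' @param drop_single drop genes with a single APA event instead of
#'   raising an error (default `FALSE`).
#' @return A data.frame with one row per APA event: `gene_id`,
#'   `event_id`, `chrom`, `site_pos` (0-based), `strand`, `delta_psi`,
#'   `order` (1 = most proximal), `label` (proximal / intermediate /
#'   distal), `utr_direction`.
#' @export
classifyApa <- function(x, drop_single = FALSE) {
  stopifnot(is(x, "SpliceEventSet"))
  x <- x[eventType(x) == "APA", ]
  if (!nrow(x)) stop("no APA events to classify")
  gr <- SummarizedExperiment::rowRanges(x)
  df <- data.frame(
    gene_id = SummarizedExperiment::rowData(x)$gene_id,
    event_id = SummarizedExperiment::rowData(x)$event_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    site_pos = BiocGenerics::start(gr) - 1L,
    strand = as.character(BiocGenerics::strand(gr)),
    delta_psi = deltaPsi(x),
    stringsAsFactors = FALSE
  )
  out <- lapply(split(df, df$gene_id), function(g) {
    if (nrow(g) < 2L) {
      if (drop_single) return(NULL)
      stop("gene ", g$gene_id[1], " has < 2 APA events")
    }
    if (length(unique(g$strand)) != 1L)
      stop("gene ", g$gene_id[1], " has APA events on mixed strands")
    g <- g[order(g$site_pos), ]
    if (g$strand[1] == "-") g <- g[rev(seq_len(nrow(g))), ]
    g$order <- seq_len(nrow(g))
    g$label <- "intermediate"
    g$label[1] <- "proximal"
    g$label[nrow(g)] <- "distal"
    dp <- g$delta_psi[g$label == "proximal"]
    dd <- g$delta_psi[g$label == "distal"]
    g$utr_direction <- if (dp > 0 && dd < 0) "shortening"
                       else if (dp < 0 && dd > 0) "lengthening"
                       else "ambiguous"
    g
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

# Extract one set of windows as a ScanRegionSet. Coordinates are
# 0-based half-open genomic; sequences are sense-strand 5'->3'.
.makeRegions <- function(chrom, gstart, gend, strand, kind, event_id,
                         genome, truncated) {
  if (!length(chrom)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      region_id = character(), event_id = character(),
      region_kind = character(), truncated = logical())
    return(ScanRegionSet(gr, Biostrings::DNAStringSet()))
  }
  missing_chr <- setdiff(unique(chrom), names(genome))
  if (length(missing_chr))
    stop("chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "))
  seqs <- Biostrings::DNAStringSet(rep("", length(chrom)))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    at <- IRanges::IRanges(start = gstart[sel] + 1L, end = gend[sel])
    seqs[sel] <- Biostrings::extractAt(genome[[ch]], at)
  }
  rc <- strand == "-"
  if (any(rc)) seqs[rc] <- Biostrings::reverseComplement(seqs[rc])
  seqs <- as.character(seqs)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = gstart + 1L, end = gend),
    strand = strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    region_id = paste(event_id, kind, sep = ":"),
    event_id = event_id, region_kind = kind, truncated = truncated
  )
  ScanRegionSet(gr, Biostrings::DNAStringSet(seqs))
}

#' Extract exon-skipping scan windows
#'
#' For each cassette-exon (ES) event, returns the exon body plus
#' 200-nt flanks on both sides, where upstream/downstream are defined
#' in transcription direction (so, for minus-strand events, the
#' upstream flank lies at higher genomic coordinates and all sequences
#' are reverse-complemented to read 5'->3' of the pre-mRNA). Flanks
#' clipped at a chromosome end carry `truncated = TRUE`.
#'
#' @param x a [SpliceEventSet-class] of ES events (others rejected).
#' @param genome named [Biostrings::DNAStringSet].
#' @param flank flank width in nt (default 200).
#' @return A [ScanRegionSet-class] with three regions per event
#'   (`upstream_flank`, `exon_body`, `downstream_flank`).
#' @export
extractEsWindows <- function(x, genome, flank = 200) {
  stopifnot(is(x, "SpliceEventSet"))
  if (any(eventType(x) != "ES"))
    stop("extractEsWindows expects ES events only")
  gr <- SummarizedExperiment::rowRanges(x)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  missing_chr <- setdiff(unique(chrom), names(genome))
  if (length(missing_chr))
    stop("chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "))
  s <- BiocGenerics::start(gr) - 1L   # 0-based
  e <- BiocGenerics::end(gr)
  st <- as.character(BiocGenerics::strand(gr))
  L <- Biostrings::width(genome)[match(chrom, names(genome))]
  id <- SummarizedExperiment::rowData(x)$event_id

  left_s <- pmax(0L, s - flank); left_e <- s
  right_s <- e; right_e <- pmin(L, e + flank)
  left_tr <- (s - flank) < 0L
  right_tr <- (e + flank) > L

  plus <- st == "+"
  up_s <- ifelse(plus, left_s, right_s); up_e <- ifelse(plus, left_e, right_e)
  up_tr <- ifelse(plus, left_tr, right_tr)
  dn_s <- ifelse(plus, right_s, left_s); dn_e <- ifelse(plus, right_e, left_e)
  dn_tr <- ifelse(plus, right_tr, left_tr)

  up <- .makeRegions(chrom, up_s, up_e, st, "upstream_flank", id, genome, up_tr)
  body <- .makeRegions(chrom, s, e, st, "exon_body", id, genome,
                       rep(FALSE, length(id)))
  dn <- .makeRegions(chrom, dn_s, dn_e, st, "downstream_flank", id, genome,
                     dn_tr)
  ScanRegionSet(c(up@regions, body@regions, dn@regions),
                c(up@seqs, body@seqs, dn@seqs))
}

#' Extract APA scan windows
#'
#' One window per proximal/distal APA site, spanning the site position
#' plus `flank` nt on each side (201 nt at the default 100). Sequences
#' are sense-stranded; intermediate sites are not extracted.
#'
#' @param apa output of [classifyApa()].
#' @param genome named [Biostrings::DNAStringSet].
#' @param flank half-window in nt (default 100).
#' @return A [ScanRegionSet-class] with kinds `apa_proximal_window` and
#'   `apa_distal_window`.
#' @export
extractApaWindows <- function(apa, genome, flank = 100) {
  apa <- apa[apa$label %in% c("proximal", "distal"), , drop = FALSE]
  L <- Biostrings::width(genome)[match(apa$chrom, names(genome))]
  if (anyNA(L))
    stop("chromosome(s) absent from genome: ",
         paste(unique(apa$chrom[is.na(L)]), collapse = ", "))
  gs <- pmax(0L, apa$site_pos - flank)
  ge <- pmin(L, apa$site_pos + flank + 1L)
  tr <- (apa$site_pos - flank) < 0L | (apa$site_pos + flank + 1L) > L
  kind <- ifelse(apa$label == "proximal", "apa_proximal_window",
                 "apa_distal_window")
  # one call per kind keeps region_kind labels aligned
  out <- .makeRegions(apa$chrom, gs, ge, apa$strand, kind, apa$event_id,
                      genome, tr)
  out
}
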