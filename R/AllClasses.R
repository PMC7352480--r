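#' PWMotif: a position probability matrix for an RNA-binding protein
#'
#' Per-position base probabilities over the DNA alphabet (RNA motifs are
#' mapped U->T at ingestion). Rows are A, C, G, T; columns are motif
#' positions.
#'
#' @slot motifId single motif identifier.
#' @slot rbpName name of the RNA-binding protein the motif models.
#' @slot matrix 4 x k numeric matrix of column-stochastic probabilities.
#' @export
setClass("PWMotif",
  slots = c(motifId = "character", rbpName = "character", matrix = "matrix"),
  validity = function(object) {
    m <- object@matrix
    if (!is.numeric(m) || nrow(m) != 4L)
      return("matrix must be numeric with 4 rows (A, C, G, T)")
    if (!identical(rownames(m), DNA_BASES))
      return("matrix rows must be named A, C, G, T")
    if (ncol(m) < 1L) return("motif length must be >= 1")
    if (any(m < 0)) return("probabilities must be >= 0")
    if (any(abs(colSums(m) - 1) > 1e-6))
      return("each position's probabilities must sum to 1 (tol 1e-6)")
    if (length(object@motifId) != 1L || length(object@rbpName) != 1L)
      return("motifId and rbpName must be length-1")
    TRUE
  }
)

#' Construct a PWMotif
#'
#' @param motifId motif identifier.
#' @param matrix 4 x k matrix (rows A, C, G, T) of per-position base
#'   probabilities. Columns off by at most 1e-3 from unit sum are
#'   renormalized; larger deviations are an error.
#' @param rbpName protein name (defaults to `motifId`).
#' @return A [PWMotif-class] object.
#' @export
PWMotif <- function(motifId, matrix, rbpName = motifId) {
  if (is.null(rownames(matrix))) rownames(matrix) <- DNA_BASES
  cs <- colSums(matrix)
  if (any(abs(cs - 1) > 1e-3)) {
    stop(sprintf("motif '%s': column probabilities sum to %s (must be 1 +/- 1e-3)",
                 motifId, paste(signif(cs[abs(cs - 1) > 1e-3], 4), collapse = ", ")))
  }
  matrix <- sweep(matrix, 2, cs, "/")
  new("PWMotif", motifId = as.character(motifId),
      rbpName = as.character(rbpName), matrix = matrix)
}

#' LogOddsMatrix: log2-odds scores with an integer-scaled copy
#'
#' Scores are log2((mixed motif probability) / background), where the
#' motif column is first mixed with a small pseudo-probability so zero
#' entries stay finite. The integer copy (units of 1/scale bits) drives
#' the exact score-distribution convolution and all scanning.
#'
#' @slot motifId,rbpName identifiers carried over from the source motif.
#' @slot scores 4 x k numeric matrix, bits.
#' @slot intScores 4 x k integer matrix, `round(scores * scale)`.
#' @slot scale integer units per bit (default 1000).
#' @slot background length-4 background probabilities (A, C, G, T).
#' @export
setClass("LogOddsMatrix",
  slots = c(motifId = "character", rbpName = "character",
            scores = "matrix", intScores = "matrix",
            scale = "numeric", background = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@scores), dim(object@intScores)))
      return("scores and intScores dimensions differ")
    if (length(object@background) != 4L ||
        abs(sum(object@background) - 1) > 1e-9)
      return("background must be 4 probabilities summing to 1 (tol 1e-9)")
    if (any(object@background <= 0))
      return("background entries must be strictly positive")
    err <- abs(object@intScores / object@scale - object@scores)
    if (any(err > 1 / object@scale))
      return("integer scaling error exceeds 1/scale bits")
    TRUE
  }
)

#' ScoreDistribution: exact null distribution of integer motif scores
#'
#' Probability mass of the integer-scaled log-odds score of a random
#' k-mer drawn from the background model, computed by position-wise
#' convolution.
#'
#' @slot scores ascending integer support.
#' @slot probs probability mass per support point.
#' @export
setClass("ScoreDistribution",
  slots = c(scores = "integer", probs = "numeric"),
  validity = function(object) {
    if (length(object@scores) != length(object@probs))
      return("scores and probs lengths differ")
    if (is.unsorted(object@scores, strictly = TRUE))
      return("scores must be strictly ascending")
    if (abs(sum(object@probs) - 1) > 1e-9)
      return("probability masses must sum to 1 (tol 1e-9)")
    TRUE
  }
)

#' SpliceEventSet: quantified alternative-splicing events
#'
#' A RangedSummarizedExperiment whose rows are splicing events and whose
#' single assay `"reads"` holds per-sample supporting read counts.
#' Row metadata: `event_id`, `gene_id`, `event_type` (one of ES, MXE,
#' IR, A5SS, A3SS, AF, AL, TS, APA), `psi_control`, `psi_silenced`,
#' `delta_psi`, `posterior`. Column metadata: `condition` with levels
#' `control` and `silenced`. Coordinates are 0-based half-open
#' (BED convention) stored in the 1-based GRanges as start+1.
#'
#' @export
setClass("SpliceEventSet",
  contains = "RangedSummarizedExperiment",
  validity = function(object) {
    rd <- SummarizedExperiment::rowData(object)
    need <- c("event_id", "gene_id", "event_type", "psi_control",
              "psi_silenced", "delta_psi", "posterior")
    miss <- setdiff(need, colnames(rd))
    if (length(miss)) return(paste("missing rowData columns:",
                                   paste(miss, collapse = ", ")))
    if (!"reads" %in% SummarizedExperiment::assayNames(object))
      return("assay 'reads' is required")
    if (!"condition" %in% colnames(SummarizedExperiment::colData(object)))
      return("colData column 'condition' is required")
    bad <- setdiff(unique(rd$event_type), EVENT_TYPES)
    if (length(bad))
      return(paste("unknown event_type:", paste(bad, collapse = ", "),
                   "- accepted:", paste(EVENT_TYPES, collapse = ", ")))
    for (col in c("psi_control", "psi_silenced", "posterior")) {
      v <- rd[[col]]
      if (any(!is.na(v) & (v < 0 | v > 1)))
        return(paste(col, "outside [0,1]"))
    }
    if (any(abs(rd$delta_psi - (rd$psi_silenced - rd$psi_control)) > 1e-9))
      return("delta_psi inconsistent with psi_silenced - psi_control (tol 1e-9)")
    if (any(SummarizedExperiment::assay(object, "reads") < 0, na.rm = TRUE))
      return("read counts must be non-negative")
    TRUE
  }
)

#' Construct a SpliceEventSet
#'
#' @param events data.frame with columns `event_id`, `gene_id`,
#'   `event_type`, `chrom`, `start`, `end` (0-based half-open), `strand`,
#'   `psi_control`, `psi_silenced`, `delta_psi`, `posterior`.
#' @param reads integer matrix, one row per event, one column per sample.
#' @param condition factor/character of length `ncol(reads)` with values
#'   `control` / `silenced`.
#' @return A [SpliceEventSet-class].
#' @export
SpliceEventSet <- function(events, reads, condition) {
  stopifnot(is.data.frame(events), nrow(events) == nrow(reads))
  if (length(condition) != ncol(reads))
    stop("condition must have one label per read-count column")
  condition <- as.character(condition)
  badc <- setdiff(unique(condition), c("control", "silenced"))
  if (length(badc))
    stop("missing/unknown condition label(s): ", paste(badc, collapse = ", "))
  if (any(events$start < 0) || any(events$start >= events$end))
    stop("invalid interval: need 0 <= start < end")
  gr <- GenomicRanges::GRanges(
    seqnames = events$chrom,
    ranges = IRanges::IRanges(start = events$start + 1L, end = events$end),
    strand = events$strand
  )
  names(gr) <- events$event_id
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    event_id = events$event_id, gene_id = events$gene_id,
    event_type = events$event_type, psi_control = events$psi_control,
    psi_silenced = events$psi_silenced, delta_psi = events$delta_psi,
    posterior = events$posterior
  )
  reads <- as.matrix(reads)
  rownames(reads) <- events$event_id
  if (is.null(colnames(reads)))
    colnames(reads) <- paste(condition, ave(seq_along(condition),
                                            condition, FUN = seq_along),
                             sep = "_")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(reads = reads), rowRanges = gr,
    colData = S4Vectors::DataFrame(
      condition = factor(condition, levels = c("control", "silenced")),
      row.names = colnames(reads))
  )
  new("SpliceEventSet", se)
}

#' ScanRegionSet: strand-aware scan windows with their sequences
#'
#' Parallel GRanges (genomic footprint; mcols `region_id`, `event_id`,
#' `region_kind`, `truncated`) and DNAStringSet (sense-strand sequence,
#' 5'->3' of the transcript, i.e. reverse-complemented for minus-strand
#' events).
#'
#' @export
setClass("ScanRegionSet",
  slots = c(regions = "GRanges", seqs = "DNAStringSet"),
  validity = function(object) {
    if (length(object@regions) != length(object@seqs))
      return("regions and seqs lengths differ")
    need <- c("region_id", "event_id", "region_kind", "truncated")
    miss <- setdiff(need, colnames(S4Vectors::mcols(object@regions)))
    if (length(miss)) return(paste("missing region metadata:",
                                   paste(miss, collapse = ", ")))
    if (length(object@regions) &&
        !all(BiocGenerics::width(object@regions) ==
             Biostrings::width(object@seqs)))
      return("sequence length must equal interval length")
    bad <- setdiff(unique(S4Vectors::mcols(object@regions)$region_kind),
                   REGION_KINDS)
    if (length(bad)) return(paste("unknown region_kind:",
                                  paste(bad, collapse = ", ")))
    TRUE
  }
)

ScanRegionSet <- function(regions, seqs) {
  names(seqs) <- S4Vectors::mcols(regions)$region_id
  new("ScanRegionSet", regions = regions, seqs = seqs)
}
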