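#' Validate events against CLIP/RIP peak sets by interval overlap
#'
#' Each event interval is extended by `extension` bp on both sides
#' (clipped at position 0) and an event is supported by a study when
#' any of that study's peaks shares at least one base with the
#' extended interval -- the "coverage greater than zero" rule.
#' Overlap uses [GenomicRanges::findOverlaps()] and is strand-agnostic
#' by default because public peak sets mix strand conventions; set
#' `strict_strand = TRUE` to honor peak strand.
#'
#' @param events a [SpliceEventSet-class] or [GenomicRanges::GRanges]
#'   with an `event_id` metadata column.
#' @param peak_sets named list of [GenomicRanges::GRanges] peak sets
#'   (one per study; see [readBedPeaks()]).
#' @param extension bp added on each side (default 200).
#' @param strict_strand require matching strand (default `FALSE`).
#' @return data.frame with one row per event: `event_id`,
#'   `ext_start`, `ext_end` (0-based half-open), one logical column
#'   per study, `n_supporting_studies`, `supported`.
#' @export
overlapEvents <- function(events, peak_sets, extension = 200,
                          strict_strand = FALSE) {
  gr <- if (is(events, "SpliceEventSet"))
    SummarizedExperiment::rowRanges(events) else events
  if (is.null(S4Vectors::mcols(gr)$event_id))
    stop("events must carry an event_id metadata column")
  if (is.null(names(peak_sets)))
    names(peak_sets) <- paste0("study_", seq_along(peak_sets))
  ext <- gr
  newStart <- pmax(1L, BiocGenerics::start(gr) - as.integer(extension))
  newEnd <- BiocGenerics::end(gr) + as.integer(extension)
  IRanges::ranges(ext) <- IRanges::IRanges(newStart, newEnd)

  allPeakChroms <- unique(unlist(lapply(peak_sets, function(p)
    as.character(GenomicRanges::seqnames(p)))))
  missing_chr <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                         allPeakChroms)
  if (length(missing_chr))
    warning("chromosome(s) absent from all peak sets: ",
            paste(missing_chr, collapse = ", "))

  out <- data.frame(
    event_id = S4Vectors::mcols(gr)$event_id,
    ext_start = BiocGenerics::start(ext) - 1L,
    ext_end = BiocGenerics::end(ext),
    stringsAsFactors = FALSE
  )
  for (study in names(peak_sets)) {
    hits <- suppressWarnings(GenomicRanges::countOverlaps(
      ext, peak_sets[[study]], minoverlap = 1L,
      ignore.strand = !strict_strand))
    out[[study]] <- hits > 0L
  }
  studyCols <- names(peak_sets)
  out$n_supporting_studies <-
    rowSums(as.matrix(out[, studyCols, drop = FALSE]))
  out$supported <- out$n_supporting_studies >= 1L
  out
}
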