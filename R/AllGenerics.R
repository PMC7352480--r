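#' @rdname PWMotif-class
#' @param object,x an object.
#' @export
setGeneric("motifId", function(x) standardGeneric("motifId"))

#' @rdname PWMotif-class
#' @export
setGeneric("rbpName", function(x) standardGeneric("rbpName"))

#' @rdname PWMotif-class
#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))

#' @rdname PWMotif-class
#' @export
setGeneric("motifMatrix", function(x) standardGeneric("motifMatrix"))

#' @rdname SpliceEventSet-class
#' @param x a `SpliceEventSet`.
#' @export
setGeneric("eventType", function(x) standardGeneric("eventType"))

#' @rdname SpliceEventSet-class
#' @export
setGeneric("psiControl", function(x) standardGeneric("psiControl"))

#' @rdname SpliceEventSet-class
#' @export
setGeneric("psiSilenced", function(x) standardGeneric("psiSilenced"))

#' @rdname SpliceEventSet-class
#' @export
setGeneric("deltaPsi", function(x) standardGeneric("deltaPsi"))

#' @rdname SpliceEventSet-class
#' @export
setGeneric("posteriorProb", function(x) standardGeneric("posteriorProb"))

#' @rdname SpliceEventSet-class
#' @export
setGeneric("readSupport", function(x) standardGeneric("readSupport"))

#' @rdname SpliceEventSet-class
#' @export
setGeneric("conditionLabels", function(x) standardGeneric("conditionLabels"))

#' @rdname ScanRegionSet-class
#' @param x a `ScanRegionSet`.
#' @export
setGeneric("regionKind", function(x) standardGeneric("regionKind"))

#' @rdname ScanRegionSet-class
#' @export
setGeneric("regionSequences", function(x) standardGeneric("regionSequences"))

#' @rdname ScanRegionSet-class
#' @export
setGeneric("regionRanges", function(x) standardGeneric("regionRanges"))

#' @rdname ScanRegionSet-class
#' @export
setGeneric("regionTruncated", function(x) standardGeneric("regionTruncated"))

## PWMotif methods ----------------------------------------------------

#' @rdname PWMotif-class
#' @export
setMethod("motifId", "PWMotif", function(x) x@motifId)

#' @rdname PWMotif-class
#' @export
setMethod("rbpName", "PWMotif", function(x) x@rbpName)

#' @rdname PWMotif-class
#' @export
setMethod("motifLength", "PWMotif", function(x) ncol(x@matrix))

#' @rdname PWMotif-class
#' @export
setMethod("motifMatrix", "PWMotif", function(x) x@matrix)

#' @rdname PWMotif-class
#' @export
setMethod("show", "PWMotif", function(object) {
  cat("PWMotif", object@motifId, "(", object@rbpName, "), length",
      ncol(object@matrix), "\n")
  print(round(object@matrix, 3))
})

#' @rdname LogOddsMatrix-class
#' @param object a `LogOddsMatrix`.
#' @export
setMethod("show", "LogOddsMatrix", function(object) {
  cat("LogOddsMatrix", object@motifId, "- length", ncol(object@scores),
      "- scale", object@scale, "units/bit\n")
  cat("background:", paste(sprintf("%s=%.3f", DNA_BASES, object@background),
                           collapse = " "), "\n")
})

#' @rdname LogOddsMatrix-class
#' @export
setMethod("motifId", "LogOddsMatrix", function(x) x@motifId)

#' @rdname LogOddsMatrix-class
#' @export
setMethod("motifLength", "LogOddsMatrix", function(x) ncol(x@scores))

#' @rdname ScoreDistribution-class
#' @param object a `ScoreDistribution`.
#' @export
setMethod("show", "ScoreDistribution", function(object) {
  cat("ScoreDistribution over", length(object@scores),
      "integer scores in [", min(object@scores), ",", max(object@scores),
      "]\n")
})

## SpliceEventSet methods ---------------------------------------------

#' @rdname SpliceEventSet-class
#' @export
setMethod("eventType", "SpliceEventSet",
          function(x) SummarizedExperiment::rowData(x)$event_type)

#' @rdname SpliceEventSet-class
#' @export
setMethod("psiControl", "SpliceEventSet",
          function(x) SummarizedExperiment::rowData(x)$psi_control)

#' @rdname SpliceEventSet-class
#' @export
setMethod("psiSilenced", "SpliceEventSet",
          function(x) SummarizedExperiment::rowData(x)$psi_silenced)

#' @rdname SpliceEventSet-class
#' @export
setMethod("deltaPsi", "SpliceEventSet",
          function(x) SummarizedExperiment::rowData(x)$delta_psi)

#' @rdname SpliceEventSet-class
#' @export
setMethod("posteriorProb", "SpliceEventSet",
          function(x) SummarizedExperiment::rowData(x)$posterior)

#' @rdname SpliceEventSet-class
#' @export
setMethod("readSupport", "SpliceEventSet",
          function(x) SummarizedExperiment::assay(x, "reads"))

#' @rdname SpliceEventSet-class
#' @export
setMethod("conditionLabels", "SpliceEventSet",
          function(x) SummarizedExperiment::colData(x)$condition)

#' @rdname SpliceEventSet-class
#' @export
setMethod("show", "SpliceEventSet", function(object) {
  tab <- table(eventType(object))
  cat("SpliceEventSet with", nrow(object), "events x", ncol(object),
      "samples\n")
  cat("event types:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = " "), "\n")
  cat("conditions:", paste(levels(conditionLabels(object)), collapse = "/"),
      sprintf("(%s)", paste(table(conditionLabels(object)), collapse = "/")),
      "\n")
})

## ScanRegionSet methods ----------------------------------------------

#' @rdname ScanRegionSet-class
#' @export
setMethod("regionKind", "ScanRegionSet",
          function(x) S4Vectors::mcols(x@regions)$region_kind)

#' @rdname ScanRegionSet-class
#' @export
setMethod("regionSequences", "ScanRegionSet", function(x) x@seqs)

#' @rdname ScanRegionSet-class
#' @export
setMethod("regionRanges", "ScanRegionSet", function(x) x@regions)

#' @rdname ScanRegionSet-class
#' @export
setMethod("regionTruncated", "ScanRegionSet",
          function(x) S4Vectors::mcols(x@regions)$truncated)

#' @rdname ScanRegionSet-class
#' @export
setMethod("length", "ScanRegionSet", function(x) length(x@regions))

#' @rdname ScanRegionSet-class
#' @param i index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "ScanRegionSet", function(x, i, j, ..., drop = FALSE) {
  ScanRegionSet(x@regions[i], x@seqs[i])
})

#' @rdname ScanRegionSet-class
#' @export
setMethod("show", "ScanRegionSet", function(object) {
  tab <- table(regionKind(object))
  cat("ScanRegionSet with", length(object), "regions\n")
  if (length(object))
    cat("kinds:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
})
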