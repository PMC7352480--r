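#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom stats p.adjust rnorm runif rpois sd median cor.test
#'   wilcox.test t.test chisq.test pchisq rlnorm rgamma rbinom ave
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

EVENT_TYPES <- c("ES", "MXE", "IR", "A5SS", "A3SS", "AF", "AL", "TS", "APA")

# external event-type labels accepted at the parser boundary
EVENT_TYPE_ALIASES <- c(CE = "ES", SES = "ES", MES = "MXE", RI = "IR",
                        TE = "APA", "A5'SS" = "A5SS", "A3'SS" = "A3SS")

REGION_KINDS <- c("upstream_flank", "exon_body", "downstream_flank",
                  "apa_proximal_window", "apa_distal_window")

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs the expression, and restores the caller's RNG
#' state so library code never clobbers a user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-stage seed from a global seed
#'
#' Deterministic fan-out: each pipeline stage draws from its own stream so
#' stages are individually reproducible no matter which subset is run.
#' Result is always a valid 32-bit integer seed.
#'
#' @param seed integer global seed.
#' @param stage character stage tag.
#' @return integer seed.
#' @export
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

#' @keywords internal
clip01 <- function(x) pmin(1, pmax(0, x))

#' @keywords internal
checkProb <- function(x, what) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) {
    stop(sprintf("%s outside [0,1] at row(s) %s", what,
                 paste(utils::head(which(bad), 5), collapse = ", ")))
  }
  invisible(x)
}
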