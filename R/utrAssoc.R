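#' Median split of an expression vector
#'
#' Samples strictly above the median are labelled `high`; samples at
#' or below it are `low` (ties at the median go to low -- arbitrary
#' but fixed). A constant vector cannot be split and is an error.
#'
#' @param expression numeric vector, length >= 4.
#' @return factor of `high` / `low` labels, same length and names.
#' @export
medianSplit <- function(expression) {
  if (length(expression) < 4L) stop("need at least 4 samples")
  if (anyNA(expression)) stop("expression vector contains NA")
  if (max(expression) == min(expression))
    stop("degenerate split: all expression values identical")
  med <- median(expression)
  out <- factor(ifelse(expression > med, "high", "low"),
                levels = c("low", "high"))
  names(out) <- names(expression)
  out
}

#' Associate 3'UTR usage (PDUI) with regulator expression
#'
#' Dual-criterion association applied per 3'UTR site: (i) Pearson
#' correlation between the site's PDUI and the expression vector
#' across samples, and (ii) a Wilcoxon rank-sum test of PDUI between
#' the high- and low-expression halves of a median split. Missing PDUI
#' entries are excluded pairwise; sites with fewer than `min_n`
#' usable samples are skipped with a reason code. P-values are
#' BH-adjusted within each test family and a site is significant only
#' when both adjusted values are at most `q_threshold` (set
#' `adjust = FALSE` to threshold the raw p-values instead). The
#' rank-sum test is exact where [stats::wilcox.test()] supports it
#' (small samples, no ties) and normal-approximate otherwise.
#'
#' @param pdui numeric matrix, sites x samples, values in \[0, 1\] or NA.
#' @param expression numeric vector of regulator expression, one value
#'   per sample (column of `pdui`).
#' @param q_threshold significance level on the (adjusted) p-values
#'   (default 0.05).
#' @param min_n minimum non-missing samples per site (default 10).
#' @param adjust apply BH within each family (default `TRUE`).
#' @return data.frame with one row per site: `site_id`, `n_used`,
#'   `pearson_r`, `pearson_p`, `pearson_q`, `wilcoxon_p`,
#'   `wilcoxon_q`, `median_high`, `median_low`, `significant`,
#'   `reason` (NA unless skipped).
#' @export
associatePdui <- function(pdui, expression, q_threshold = 0.05,
                          min_n = 10, adjust = TRUE) {
  pdui <- as.matrix(pdui)
  if (ncol(pdui) != length(expression))
    stop("dimension mismatch: ", ncol(pdui), " PDUI columns vs ",
         length(expression), " expression values")
  checkProb(pdui[!is.na(pdui)], "PDUI")
  grp <- medianSplit(expression)
  n <- nrow(pdui)
  out <- data.frame(
    site_id = if (is.null(rownames(pdui))) paste0("site_", seq_len(n))
              else rownames(pdui),
    n_used = NA_integer_, pearson_r = NA_real_, pearson_p = NA_real_,
    pearson_q = NA_real_, wilcoxon_p = NA_real_, wilcoxon_q = NA_real_,
    median_high = NA_real_, median_low = NA_real_,
    significant = FALSE, reason = NA_character_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    ok <- !is.na(pdui[i, ])
    out$n_used[i] <- sum(ok)
    if (sum(ok) < min_n) {
      out$reason[i] <- "too_few_samples"
      next
    }
    x <- pdui[i, ok]
    if (sd(x) == 0) {
      out$reason[i] <- "constant_pdui"
      next
    }
    hi <- x[grp[ok] == "high"]; lo <- x[grp[ok] == "low"]
    if (!length(hi) || !length(lo)) {
      out$reason[i] <- "one_sided_split"
      next
    }
    ct <- cor.test(x, expression[ok], method = "pearson")
    wt <- suppressWarnings(wilcox.test(hi, lo))
    out$pearson_r[i] <- unname(ct$estimate)
    out$pearson_p[i] <- ct$p.value
    out$wilcoxon_p[i] <- wt$p.value
    out$median_high[i] <- median(hi)
    out$median_low[i] <- median(lo)
  }
  tested <- !is.na(out$pearson_p)
  if (adjust) {
    out$pearson_q[tested] <- p.adjust(out$pearson_p[tested], "BH")
    out$wilcoxon_q[tested] <- p.adjust(out$wilcoxon_p[tested], "BH")
  } else {
    out$pearson_q[tested] <- out$pearson_p[tested]
    out$wilcoxon_q[tested] <- out$wilcoxon_p[tested]
  }
  out$significant <- tested & out$pearson_q <= q_threshold &
    out$wilcoxon_q <= q_threshold
  out
}
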