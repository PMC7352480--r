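#' Compute isoform fractions (IF) and dIF
#'
#' The isoform fraction is the isoform TPM divided by its parent gene
#' TPM (the sum of TPMs of the gene's isoforms), computed per sample
#' before any filtering -- so per gene and sample the fractions sum to
#' 1. Samples where the gene TPM is zero give missing fractions and
#' are excluded from condition means. Lowly expressed genes (mean TPM
#' below `min_gene_tpm` in both conditions) and minor isoforms (mean
#' IF below `min_if` in both conditions) are then dropped.
#'
#' @param tpm numeric matrix, isoforms x samples, non-negative.
#' @param isoform_gene named character vector (or two-column
#'   data.frame `isoform_id`, `gene_id`) mapping every row of `tpm` to
#'   its gene.
#' @param condition factor/character per column: `control` / `silenced`.
#' @param min_gene_tpm gene-level expression floor (default 1).
#' @param min_if isoform-contribution floor (default 0.01).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assays
#'   `tpm` and `IF`, rowData `gene_id`, `meanIF_control`,
#'   `meanIF_silenced`, `dIF`, and colData `condition`. Set
#'   `min_gene_tpm = 0, min_if = 0` for the unfiltered object.
#' @export
computeIsoformFractions <- function(tpm, isoform_gene, condition,
                                    min_gene_tpm = 1, min_if = 0.01) {
  tpm <- as.matrix(tpm)
  if (any(tpm < 0, na.rm = TRUE)) stop("TPM values must be non-negative")
  if (is.data.frame(isoform_gene)) {
    map <- isoform_gene$gene_id
    names(map) <- isoform_gene$isoform_id
    isoform_gene <- map
  }
  iso <- rownames(tpm)
  if (is.null(iso)) stop("tpm must have isoform row names")
  unmapped <- setdiff(iso, names(isoform_gene))
  if (length(unmapped))
    stop("isoform(s) without a gene mapping: ",
         paste(utils::head(unmapped, 5), collapse = ", "))
  gene <- unname(isoform_gene[iso])
  condition <- factor(as.character(condition),
                      levels = c("control", "silenced"))
  if (anyNA(condition)) stop("condition labels must be control/silenced")

  geneTpm <- rowsum(tpm, gene)[gene, , drop = FALSE]
  IF <- tpm / geneTpm
  IF[geneTpm == 0] <- NA

  meanIF <- function(cc) rowMeans(IF[, condition == cc, drop = FALSE],
                                  na.rm = TRUE)
  mc <- meanIF("control"); ms <- meanIF("silenced")
  mc[is.nan(mc)] <- NA; ms[is.nan(ms)] <- NA

  geneMean <- function(cc) {
    g <- rowsum(tpm[, condition == cc, drop = FALSE], gene)
    rowMeans(g)[gene]
  }
  gKeep <- geneMean("control") >= min_gene_tpm |
           geneMean("silenced") >= min_gene_tpm
  iKeep <- (!is.na(mc) & mc >= min_if) | (!is.na(ms) & ms >= min_if)
  keep <- gKeep & iKeep

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = tpm, IF = IF),
    rowData = S4Vectors::DataFrame(
      gene_id = gene, meanIF_control = mc, meanIF_silenced = ms,
      dIF = ms - mc, row.names = iso),
    colData = S4Vectors::DataFrame(condition = condition,
                                   row.names = colnames(tpm))
  )
  se[keep, ]
}

#' Test isoform switches
#'
#' Per isoform, a two-sided unequal-variance (Welch) t test compares
#' the replicate-level isoform fractions between conditions; p-values
#' are Benjamini-Hochberg corrected across all tested isoforms. An
#' isoform switches significantly when its corrected p-value is at
#' most `q_max` and `|dIF|` strictly exceeds `dif_min`. When both
#' conditions have zero variance the p-value is 1 for equal means and
#' 0 otherwise (the test statistic is degenerate).
#'
#' @param se output of [computeIsoformFractions()].
#' @param dif_min minimum absolute IF change (default 0.1, strict).
#' @param q_max BH-corrected p-value ceiling (default 0.05).
#' @return `se` with rowData columns `p_value`, `q_value`,
#'   `significant` added.
#' @export
testSwitches <- function(se, dif_min = 0.1, q_max = 0.05) {
  cond <- SummarizedExperiment::colData(se)$condition
  IF <- SummarizedExperiment::assay(se, "IF")
  a <- IF[, cond == "control", drop = FALSE]
  b <- IF[, cond == "silenced", drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L)
    stop("need at least 2 replicates per condition")
  p <- vapply(seq_len(nrow(IF)), function(i) {
    x <- a[i, ][!is.na(a[i, ])]
    y <- b[i, ][!is.na(b[i, ])]
    if (length(x) < 2L || length(y) < 2L) return(NA_real_)
    if (sd(x) == 0 && sd(y) == 0)
      return(if (mean(x) == mean(y)) 1 else 0)
    t.test(x, y, var.equal = FALSE)$p.value
  }, numeric(1))
  q <- p.adjust(p, method = "BH")
  rd <- SummarizedExperiment::rowData(se)
  rd$p_value <- p
  rd$q_value <- q
  rd$significant <- !is.na(q) & q <= q_max & abs(rd$dIF) > dif_min
  SummarizedExperiment::rowData(se) <- rd
  se
}

#' 5'/3' UTR lengths from transcript models
#'
#' Transcript models are rows of a GTF-like TSV: `transcript_id`,
#' `gene_id`, `chrom`, `strand`, `exon_starts`, `exon_ends`
#' (comma-separated, 0-based half-open, genomically sorted),
#' `cds_start`, `cds_end` (0-based half-open; NA for non-coding).
#' UTR lengths are exonic nucleotides before/after the CDS in
#' transcription direction.
#'
#' @param models data.frame of transcript models.
#' @return `models` with numeric columns `utr5_len` and `utr3_len`
#'   added (NA for non-coding transcripts).
#' @export
utrLengths <- function(models) {
  parse1 <- function(s) as.numeric(strsplit(as.character(s), ",")[[1]])
  n <- nrow(models)
  utr5 <- utr3 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cs <- models$cds_start[i]; ce <- models$cds_end[i]
    if (is.na(cs) || is.na(ce)) next
    es <- parse1(models$exon_starts[i]); ee <- parse1(models$exon_ends[i])
    if (length(es) != length(ee) || any(es >= ee))
      stop("transcript ", models$transcript_id[i], ": malformed exons")
    if (is.unsorted(es))
      stop("transcript ", models$transcript_id[i],
           ": exons must be sorted in genomic order")
    if (any(utils::head(ee, -1) > utils::tail(es, -1)))
      stop("transcript ", models$transcript_id[i], ": overlapping exons")
    left <- sum(pmax(0, pmin(ee, cs) - es))          # exonic nt before CDS
    right <- sum(pmax(0, ee - pmax(es, ce)))         # exonic nt after CDS
    if (models$strand[i] == "+") { utr5[i] <- left; utr3[i] <- right }
    else { utr5[i] <- right; utr3[i] <- left }
  }
  models$utr5_len <- utr5
  models$utr3_len <- utr3
  models
}

#' Annotate UTR-length consequences of isoform switches
#'
#' For each gene with at least one significantly gained (dIF > 0) and
#' one significantly lost (dIF < 0) isoform, the largest-|dIF| pair is
#' annotated: `delta_3utr = 3'UTR(up) - 3'UTR(down)` (and likewise for
#' the 5'UTR), giving `3UTR_shortening` when the gained isoform's
#' 3'UTR is shorter by at least `min_delta` nt, `3UTR_lengthening` for
#' the mirror case, and symmetric 5'UTR categories. Deltas below
#' `min_delta` (annotation jitter) give no call. All significant
#' up/down pairs are additionally returned in `attr(x, "all_pairs")`.
#'
#' @param se output of [testSwitches()].
#' @param models transcript models (see [utrLengths()]); every
#'   significant isoform must be present.
#' @param min_delta minimum UTR-length difference in nt to call a
#'   consequence (default 50).
#' @return data.frame with one row per switching gene: `gene_id`,
#'   `up_isoform`, `down_isoform`, `dIF_up`, `dIF_down`, `delta_3utr`,
#'   `delta_5utr`, `categories` (comma-joined; "none" when no delta
#'   passes).
#' @export
annotateConsequences <- function(se, models, min_delta = 50) {
  rd <- SummarizedExperiment::rowData(se)
  if (is.null(rd$significant))
    stop("run testSwitches() before annotateConsequences()")
  models <- utrLengths(models)
  sig <- rd[rd$significant, , drop = FALSE]
  iso <- rownames(sig)
  missing_m <- setdiff(iso, models$transcript_id)
  if (length(missing_m))
    stop("no transcript model for isoform(s): ",
         paste(utils::head(missing_m, 5), collapse = ", "))
  rows <- list()
  pairs <- list()
  for (g in unique(sig$gene_id)) {
    gi <- sig[sig$gene_id == g, , drop = FALSE]
    up <- gi[gi$dIF > 0, , drop = FALSE]
    dn <- gi[gi$dIF < 0, , drop = FALSE]
    if (!nrow(up) || !nrow(dn)) next
    for (ui in rownames(up)) for (di in rownames(dn))
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene_id = g, up_isoform = ui, down_isoform = di)
    ui <- rownames(up)[which.max(abs(up$dIF))]
    di <- rownames(dn)[which.max(abs(dn$dIF))]
    mu <- models[match(ui, models$transcript_id), ]
    md <- models[match(di, models$transcript_id), ]
    d3 <- mu$utr3_len - md$utr3_len
    d5 <- mu$utr5_len - md$utr5_len
    cats <- character(0)
    if (!is.na(d3) && abs(d3) >= min_delta)
      cats <- c(cats, if (d3 < 0) "3UTR_shortening" else "3UTR_lengthening")
    if (!is.na(d5) && abs(d5) >= min_delta)
      cats <- c(cats, if (d5 < 0) "5UTR_shortening" else "5UTR_lengthening")
    if (!length(cats)) cats <- "none"
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, up_isoform = ui, down_isoform = di,
      dIF_up = up[ui, "dIF"], dIF_down = dn[di, "dIF"],
      delta_3utr = d3, delta_5utr = d5,
      categories = paste(cats, collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), up_isoform = character(),
               down_isoform = character(), dIF_up = numeric(),
               dIF_down = numeric(), delta_3utr = numeric(),
               delta_5utr = numeric(), categories = character())
  attr(out, "all_pairs") <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene_id = character(), up_isoform = character(),
               down_isoform = character())
  out
}
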