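simpleTpm <- function() {
  tpm <- rbind(
    i1 = c(3, 3, 3, 1, 1, 1),
    i2 = c(1, 1, 1, 3, 3, 3),
    i3 = c(10, 12, 11, 10, 12, 11))
  colnames(tpm) <- paste0(rep(c("c", "s"), each = 3), 1:3)
  list(tpm = tpm,
       map = c(i1 = "G1", i2 = "G1", i3 = "G2"),
       cond = rep(c("control", "silenced"), each = 3))
}

test_that("isoform fractions divide by the parent gene total", {
  d <- simpleTpm()
  se <- computeIsoformFractions(d$tpm, d$map, d$cond)
  IF <- SummarizedExperiment::assay(se, "IF")
  expect_equal(unname(IF["i1", 1]), 0.75)
  expect_equal(unname(IF["i2", 1]), 0.25)
  expect_equal(unname(IF["i3", ]), rep(1, 6))
  rd <- SummarizedExperiment::rowData(se)
  expect_equal(unname(rd["i1", "dIF"]), 0.25 - 0.75)
  expect_equal(unname(rd["i3", "dIF"]), 0)
})

test_that("zero gene TPM gives missing fractions excluded from means", {
  tpm <- rbind(i1 = c(2, 0, 4, 2, 2, 2), i2 = c(2, 0, 4, 2, 2, 2))
  colnames(tpm) <- paste0("s", 1:6)
  se <- computeIsoformFractions(tpm, c(i1 = "G", i2 = "G"),
                                rep(c("control", "silenced"), each = 3))
  IF <- SummarizedExperiment::assay(se, "IF")
  expect_true(all(is.na(IF[, 2])))
  expect_equal(unname(SummarizedExperiment::rowData(se)$meanIF_control),
               c(0.5, 0.5))
})

test_that("fractions sum to one per gene and sample before filtering", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- 120
      gene <- sprintf("G%02d", sample(30, n, TRUE))
      tpm <- matrix(rexp(n * 6, 0.1), n, 6,
                    dimnames = list(sprintf("i%03d", 1:n), paste0("s", 1:6)))
      names(gene) <- rownames(tpm)
      se <- computeIsoformFractions(tpm, gene,
                                    rep(c("control", "silenced"), each = 3),
                                    min_gene_tpm = 0, min_if = 0)
      IF <- SummarizedExperiment::assay(se, "IF")
      sums <- rowsum(IF, SummarizedExperiment::rowData(se)$gene_id)
      expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-9))
    })
  }
})

test_that("unmapped isoforms and low-expression rows are handled", {
  d <- simpleTpm()
  expect_error(computeIsoformFractions(d$tpm, c(i1 = "G1"), d$cond),
               "without a gene mapping")
  # a sub-threshold gene disappears
  tpm2 <- rbind(d$tpm, i4 = rep(0.2, 6))
  se <- computeIsoformFractions(tpm2, c(d$map, i4 = "G3"), d$cond)
  expect_false("i4" %in% rownames(se))
})

test_that("switch testing is strict at |dIF| = 0.1 and needs replicates", {
  d <- simpleTpm()
  se <- computeIsoformFractions(d$tpm, d$map, d$cond)
  se <- testSwitches(se)
  rd <- SummarizedExperiment::rowData(se)
  expect_true(rd["i1", "significant"])   # dIF -0.5, zero noise
  expect_false(rd["i3", "significant"])  # dIF 0

  # dIF exactly 0.1 with a perfect (p = 0) test is still not a switch
  tpm <- rbind(a = c(40, 40, 40, 50, 50, 50), b = c(60, 60, 60, 50, 50, 50))
  colnames(tpm) <- paste0("s", 1:6)
  se2 <- computeIsoformFractions(tpm, c(a = "G", b = "G"),
                                 rep(c("control", "silenced"), each = 3))
  se2 <- testSwitches(se2)
  rd2 <- SummarizedExperiment::rowData(se2)
  expect_equal(unname(rd2[["dIF"]]), c(0.1, -0.1))
  expect_equal(unname(rd2[["p_value"]]), c(0, 0))
  expect_false(any(rd2$significant))

  se1 <- computeIsoformFractions(d$tpm[, c(1, 4)], d$map,
                                 c("control", "silenced"))
  expect_error(testSwitches(se1), "2 replicates")
})

test_that("per-sample TPM rescaling changes no fraction, dIF, or decision", {
  withr::with_seed(10, {
    n <- 60
    gene <- sprintf("G%02d", sample(20, n, TRUE))
    tpm <- matrix(rexp(n * 6, 0.05), n, 6,
                  dimnames = list(sprintf("i%03d", 1:n), paste0("s", 1:6)))
    names(gene) <- rownames(tpm)
    cond <- rep(c("control", "silenced"), each = 3)
    scaled <- sweep(tpm, 2, c(7, 0.3, 2, 11, 0.9, 4), "*")
    a <- testSwitches(computeIsoformFractions(tpm, gene, cond))
    b <- testSwitches(computeIsoformFractions(scaled, gene, cond))
    expect_equal(SummarizedExperiment::assay(a, "IF"),
                 SummarizedExperiment::assay(b, "IF"))
    expect_equal(SummarizedExperiment::rowData(a)$dIF,
                 SummarizedExperiment::rowData(b)$dIF)
    expect_equal(SummarizedExperiment::rowData(a)$significant,
                 SummarizedExperiment::rowData(b)$significant)
  })
})

test_that("retained dIF values balance to zero when nothing is filtered", {
  withr::with_seed(12, {
    n <- 40
    gene <- rep(sprintf("G%02d", 1:10), each = 4)
    tpm <- matrix(rexp(n * 6, 0.05) + 5, n, 6,
                  dimnames = list(sprintf("i%03d", 1:n), paste0("s", 1:6)))
    names(gene) <- rownames(tpm)
    se <- computeIsoformFractions(tpm, gene,
                                  rep(c("control", "silenced"), each = 3),
                                  min_gene_tpm = 0, min_if = 0)
    sums <- rowsum(SummarizedExperiment::rowData(se)$dIF,
                   SummarizedExperiment::rowData(se)$gene_id)
    expect_true(all(abs(sums) < 1e-9))
  })
})

test_that("UTR lengths come out of multi-exon models on both strands", {
  models <- data.frame(
    transcript_id = c("t1", "t2", "t3"),
    gene_id = "G", chrom = "chr1", strand = c("+", "-", "+"),
    # t1: exons [0,100) + [200,400); CDS [50,300): 5'UTR 50, 3'UTR 100
    exon_starts = c("0,200", "0,200", "0"),
    exon_ends = c("100,400", "100,400", "500"),
    cds_start = c(50, 50, NA), cds_end = c(300, 300, NA))
  out <- utrLengths(models)
  expect_equal(out$utr5_len, c(50, 100, NA))
  expect_equal(out$utr3_len, c(100, 50, NA))

  bad <- models[1, ]
  bad$exon_starts <- "200,0"; bad$exon_ends <- "400,100"
  expect_error(utrLengths(bad), "sorted")
})

test_that("switch consequences pair top isoforms and respect the 50-nt floor", {
  # G1: up isoform with short 3'UTR (300) vs down with long (5000)
  models <- data.frame(
    transcript_id = c("u", "d", "u2", "d2", "u3", "d3"),
    gene_id = rep(c("G1", "G2", "G3"), each = 2),
    chrom = "chr1", strand = "+",
    exon_starts = "0",
    exon_ends = as.character(1000 + c(300, 5000, 700, 700, 600, 200)),
    cds_start = 500, cds_end = 1000)
  mkSe <- function() {
    tpm <- matrix(10, 6, 6, dimnames = list(models$transcript_id,
                                            paste0("s", 1:6)))
    tpm[c("u", "u2", "u3"), 4:6] <- 18
    tpm[c("d", "d2", "d3"), 4:6] <- 2
    map <- models$gene_id; names(map) <- models$transcript_id
    testSwitches(computeIsoformFractions(
      tpm, map, rep(c("control", "silenced"), each = 3)))
  }
  cons <- annotateConsequences(mkSe(), models)
  expect_equal(cons$categories[cons$gene_id == "G1"], "3UTR_shortening")
  expect_equal(cons$categories[cons$gene_id == "G2"], "none")  # equal UTRs
  expect_equal(cons$categories[cons$gene_id == "G3"], "3UTR_lengthening")
  expect_true(all(cons$dIF_up > 0 & cons$dIF_down < 0))

  # 5'UTR classification: gained isoform with the longer 5'UTR
  models5 <- data.frame(
    transcript_id = c("u", "d"), gene_id = "G1", chrom = "chr1",
    strand = "+", exon_starts = "0", exon_ends = "2000",
    cds_start = c(500, 100), cds_end = 1500)
  cons5 <- annotateConsequences(mkSe()[1:2, ], models5)
  expect_equal(cons5$categories, "5UTR_lengthening")

  expect_error(annotateConsequences(mkSe(), models[-1, ]),
               "no transcript model")
})
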