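test_that("read-support filter keeps events with enough reads in both conditions", {
  x <- toyEventSet()
  kept <- filterExpressedEvents(x)
  expect_equal(SummarizedExperiment::rowData(kept)$event_id,
               sprintf("E%03d", c(1, 3, 4, 5, 6, 7)))
})

test_that("the toy table flows through all filters to the hand-checked subsets", {
  expressed <- filterExpressedEvents(toyEventSet())
  sig <- callSignificantEvents(expressed)
  expect_equal(SummarizedExperiment::rowData(sig)$event_id, "E001")
  pool <- selectNullPool(expressed)
  expect_equal(SummarizedExperiment::rowData(pool)$event_id, "E005")
})

test_that("significance and null-pool boundaries are strict", {
  ev <- makeEvents(4, delta_psi = c(0.1, 0.100001, -0.009999, 0.01),
                   posterior = c(0.99, 0.9, 0.499, 0.499))
  x <- makeEventSet(ev)
  sig <- callSignificantEvents(x)
  # |dPSI| = 0.1 exactly excluded; posterior = 0.9 exactly excluded
  expect_equal(nrow(sig), 0)
  pool <- selectNullPool(x)
  # |dPSI| = 0.01 exactly excluded
  expect_equal(SummarizedExperiment::rowData(pool)$event_id, "E003")
})

test_that("filters match a brute-force row filter and are order-independent", {
  for (seed in 1:5) {
    x <- randomEventSet(60, seed)
    rd <- SummarizedExperiment::rowData(x)
    reads <- readSupport(x)
    bfExpr <- rowSums(reads[, 1:3] >= 10) >= 2 &
      rowSums(reads[, 4:6] >= 10) >= 2
    bfSig <- bfExpr & abs(rd$delta_psi) > 0.1 & rd$posterior > 0.9
    bfNull <- bfExpr & abs(rd$delta_psi) < 0.01 & rd$posterior < 0.5

    expressed <- filterExpressedEvents(x)
    sig <- callSignificantEvents(expressed)
    pool <- selectNullPool(expressed)
    expect_equal(SummarizedExperiment::rowData(sig)$event_id,
                 rd$event_id[bfSig])
    expect_equal(SummarizedExperiment::rowData(pool)$event_id,
                 rd$event_id[bfNull])
    # disjointness for any table
    expect_length(intersect(SummarizedExperiment::rowData(sig)$event_id,
                            SummarizedExperiment::rowData(pool)$event_id), 0)
    # order independence: significance filter commutes with expression filter
    sig2 <- filterExpressedEvents(callSignificantEvents(x))
    expect_equal(SummarizedExperiment::rowData(sig2)$event_id,
                 SummarizedExperiment::rowData(sig)$event_id)
    # idempotence
    expect_equal(nrow(filterExpressedEvents(expressed)), nrow(expressed))
  }
})

test_that("null pool can demand event types", {
  x <- makeEventSet(makeEvents(3, delta_psi = 0.3, posterior = 0.99))
  expect_error(selectNullPool(x, required_types = "ES"), "enlarge")
})

apaEventSet <- function(strand = "+", dpsi = c(0.3, -0.3),
                        sites = c(1000, 2500)) {
  ev <- makeEvents(2, event_type = "APA", start = sites, width = 1,
                   strand = strand, delta_psi = dpsi,
                   posterior = c(0.99, 0.99), gene_id = c("G1", "G1"))
  makeEventSet(ev)
}

test_that("APA classification orders sites by transcription direction", {
  # plus strand: smaller coordinate is proximal; proximal gains on
  # silencing -> 3'UTR shortening
  apa <- classifyApa(apaEventSet("+"))
  expect_equal(apa$label[apa$site_pos == 1000], "proximal")
  expect_equal(apa$label[apa$site_pos == 2500], "distal")
  expect_equal(unique(apa$utr_direction), "shortening")

  # minus strand, same coordinates: proximal/distal swap
  apam <- classifyApa(apaEventSet("-"))
  expect_equal(apam$label[apam$site_pos == 2500], "proximal")
  expect_equal(apam$label[apam$site_pos == 1000], "distal")
  # dPSI still attached to the same genomic sites, so the direction flips
  expect_equal(unique(apam$utr_direction), "lengthening")

  # same-sign movement is ambiguous
  amb <- classifyApa(apaEventSet("+", dpsi = c(0.2, 0.2)))
  expect_equal(unique(amb$utr_direction), "ambiguous")

  # lengthening pattern
  lng <- classifyApa(apaEventSet("+", dpsi = c(-0.25, 0.25)))
  expect_equal(unique(lng$utr_direction), "lengthening")
})

test_that("APA classification rejects degenerate genes and labels intermediates", {
  one <- makeEventSet(makeEvents(1, event_type = "APA"))
  expect_error(classifyApa(one), "< 2 APA")
  expect_null(classifyApa(one, drop_single = TRUE))

  mixed <- makeEventSet(makeEvents(2, event_type = "APA",
                                   strand = c("+", "-"),
                                   gene_id = c("G1", "G1")))
  expect_error(classifyApa(mixed), "mixed strands")

  three <- makeEventSet(makeEvents(3, event_type = "APA",
                                   start = c(100, 900, 5000), width = 1,
                                   delta_psi = c(0.3, 0.0, -0.3),
                                   posterior = 0.99,
                                   gene_id = rep("G1", 3)))
  lab <- classifyApa(three)
  expect_equal(lab$label[order(lab$site_pos)],
               c("proximal", "intermediate", "distal"))
})

test_that("proximal/distal labels swap exactly when strand flips", {
  for (seed in 1:5) {
    sites <- withr::with_seed(seed, sort(sample(500:5000, 4)))
    p <- classifyApa(makeEventSet(makeEvents(
      4, event_type = "APA", start = sites, width = 1, strand = "+",
      delta_psi = c(0.3, 0, 0, -0.3), posterior = 0.99,
      gene_id = rep("G1", 4))))
    m <- classifyApa(makeEventSet(makeEvents(
      4, event_type = "APA", start = sites, width = 1, strand = "-",
      delta_psi = c(0.3, 0, 0, -0.3), posterior = 0.99,
      gene_id = rep("G1", 4))))
    p <- p[order(p$site_pos), ]; m <- m[order(m$site_pos), ]
    expect_equal(p$label, rev(m$label))
  }
})

test_that("ES window extraction is strand-aware with truncation flags", {
  chr <- paste(rep(BASES, 500), collapse = "")  # 2000 nt
  genome <- makeGenome(chr1 = chr)
  ev <- makeEvents(1, start = 500, width = 100)
  x <- makeEventSet(ev)
  w <- extractEsWindows(x, genome)
  df <- as.data.frame(regionRanges(w))
  rownames(df) <- regionKind(w)
  expect_equal(df["upstream_flank", "start"] - 1, 300)   # 0-based [300,500)
  expect_equal(df["upstream_flank", "end"], 500)
  expect_equal(df["exon_body", "start"] - 1, 500)
  expect_equal(df["downstream_flank", "end"], 800)
  expect_false(any(regionTruncated(w)))
  # sequences equal direct slices
  expect_equal(as.character(regionSequences(w)[["E001:upstream_flank"]]),
               substr(chr, 301, 500))

  # minus strand: the upstream flank sits at higher genomic coordinates
  # and is reverse-complemented
  xm <- makeEventSet(makeEvents(1, start = 500, width = 100, strand = "-"))
  wm <- extractEsWindows(xm, genome)
  dfm <- as.data.frame(regionRanges(wm))
  rownames(dfm) <- regionKind(wm)
  expect_equal(dfm["upstream_flank", "start"] - 1, 600)
  expect_equal(dfm["upstream_flank", "end"], 800)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(chr, 601, 800))))
  expect_equal(as.character(regionSequences(wm)[["E001:upstream_flank"]]), rc)

  # truncation at the chromosome start
  xt <- makeEventSet(makeEvents(1, start = 50, width = 70))
  wt <- extractEsWindows(xt, genome)
  dft <- as.data.frame(regionRanges(wt))
  rownames(dft) <- regionKind(wt)
  expect_equal(dft["upstream_flank", "start"] - 1, 0)
  expect_equal(dft["upstream_flank", "end"], 50)
  expect_true(regionTruncated(wt)[regionKind(wt) == "upstream_flank"])

  expect_error(extractEsWindows(
    makeEventSet(makeEvents(1, chrom = "chrX")), genome), "absent")
  expect_error(extractEsWindows(
    makeEventSet(makeEvents(1, event_type = "APA")), genome), "ES events")
})

test_that("minus-strand extraction is the mirror of the plus-strand extraction", {
  seqs <- withr::with_seed(33, paste(sample(BASES, 3000, TRUE), collapse = ""))
  genome <- makeGenome(chr1 = seqs)
  mirror <- makeGenome(chr1 = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seqs))))
  s <- 1200; wdt <- 90
  plus <- extractEsWindows(makeEventSet(makeEvents(1, start = s,
                                                   width = wdt)), genome)
  # the same exon on the mirrored chromosome, minus strand
  ms <- 3000 - (s + wdt)
  minus <- extractEsWindows(makeEventSet(makeEvents(
    1, start = ms, width = wdt, strand = "-")), mirror)
  for (kind in c("upstream_flank", "exon_body", "downstream_flank"))
    expect_equal(
      as.character(regionSequences(minus)[[paste0("E001:", kind)]]),
      as.character(regionSequences(plus)[[paste0("E001:", kind)]]))
})

test_that("APA windows are 201 nt, centered, and sense-stranded", {
  chr <- withr::with_seed(2, paste(sample(BASES, 2000, TRUE), collapse = ""))
  genome <- makeGenome(chr1 = chr)
  apa <- classifyApa(apaEventSet("+", sites = c(1000, 1500)))
  w <- extractApaWindows(apa, genome)
  df <- as.data.frame(regionRanges(w))
  i <- which(S4Vectors::mcols(regionRanges(w))$event_id ==
             apa$event_id[apa$site_pos == 1000])
  expect_equal(df$start[i] - 1, 900)
  expect_equal(df$end[i], 1101)
  expect_equal(Biostrings::width(regionSequences(w)), c(201, 201))
  expect_equal(as.character(regionSequences(w)[[i]]),
               substr(chr, 901, 1101))

  # minus strand: window sequence is the reverse complement of the slice
  apam <- classifyApa(apaEventSet("-", sites = c(1000, 1500)))
  wm <- extractApaWindows(apam, genome)
  im <- which(S4Vectors::mcols(regionRanges(wm))$event_id ==
              apam$event_id[apam$site_pos == 1000])
  expect_equal(as.character(regionSequences(wm)[[im]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(chr, 901, 1101)))))

  # truncation near the chromosome start
  apat <- classifyApa(apaEventSet("+", sites = c(40, 900)))
  wt <- extractApaWindows(apat, genome)
  expect_true(any(regionTruncated(wt)))
})
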