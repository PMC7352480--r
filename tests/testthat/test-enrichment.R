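plantedSeqs <- function(n, n_with, word, len = 60, seed = 1) {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("G", "T"), len, TRUE), collapse = ""), character(1))
    for (i in seq_len(n_with)) {
      off <- sample.int(len - nchar(word), 1)
      substr(seqs[i], off, off + nchar(word) - 1) <- word
    }
    seqs
  })
}

test_that("frequency counts per-sequence presence and tracks total matches", {
  lom <- buildLogOdds(testMotif())
  thr <- pvalueThreshold(scoreDistribution(lom), 0.001)
  seqs <- plantedSeqs(3, 2, "ACACAC")
  n <- countFrequency(seqs, lom, thr)
  expect_equal(as.integer(n), 2)
  expect_gte(attr(n, "totalMatches"), 2)

  expect_equal(as.integer(countFrequency(rep(strrep("N", 50), 4), lom, thr)), 0)

  # equals the brute-force per-sequence presence sum
  rnd <- withr::with_seed(5, vapply(1:30, function(i)
    paste(sample(BASES, 80, TRUE), collapse = ""), character(1)))
  expect_equal(as.integer(countFrequency(rnd, lom, thr)),
               sum(vapply(rnd, function(s) length(bfScan(lom, s, thr)) > 0,
                          logical(1))))
})

test_that("null-set sampling is seeded, without replacement, and size-checked", {
  flags <- c(rep(TRUE, 4), rep(FALSE, 6))
  ns1 <- sampleNullSets(flags, set_size = 5, n_sets = 20, seed = 99)
  ns2 <- sampleNullSets(flags, set_size = 5, n_sets = 20, seed = 99)
  expect_identical(ns1$sets, ns2$sets)
  expect_identical(ns1$freqs, ns2$freqs)
  # without replacement within each set
  expect_true(all(apply(ns1$sets, 2, anyDuplicated) == 0))
  # frequency is the flag count of the drawn indices
  expect_equal(ns1$freqs, as.integer(colSums(matrix(flags[ns1$sets], 5))))

  # forced draw: pool size equals set size
  full <- sampleNullSets(flags, set_size = 10, n_sets = 100, seed = 1)
  expect_true(all(full$freqs == 4L))

  # motif absent everywhere -> all-zero frequencies
  none <- sampleNullSets(rep(FALSE, 10), set_size = 3, n_sets = 100, seed = 1)
  expect_true(all(none$freqs == 0L))

  expect_error(sampleNullSets(flags, set_size = 11), "smaller")
})

test_that("z-scores use the population sd with declared degenerate conventions", {
  null <- c(rep(2, 50), rep(6, 50))          # mean 4, population sd 2
  expect_equal(computeZ(10, null)$z, 3)
  expect_equal(computeZ(4, null)$z, 0)
  expect_equal(computeZ(4, null)$null_sd, 2)

  flat <- rep(3, 100)
  expect_equal(computeZ(3, flat)$z, 0)
  expect_equal(computeZ(7, flat)$z, Inf)
  expect_equal(computeZ(1, flat)$z, -Inf)
  expect_error(computeZ(5, 2), "at least 2")
})

test_that("z is invariant to relabeling of regions within the regulated set", {
  lom <- buildLogOdds(testMotif())
  thr <- pvalueThreshold(scoreDistribution(lom), 0.001)
  seqs <- plantedSeqs(20, 8, "ACACAC", seed = 7)
  nullFlags <- withr::with_seed(8, sample(c(TRUE, FALSE), 100, TRUE,
                                          prob = c(0.1, 0.9)))
  ns <- sampleNullSets(nullFlags, 20, 100, seed = 3)
  z1 <- computeZ(as.integer(countFrequency(seqs, lom, thr)), ns$freqs)
  z2 <- computeZ(as.integer(countFrequency(rev(seqs), lom, thr)), ns$freqs)
  expect_equal(z1, z2)
})

test_that("run-level enrichment equals manual composition of the three steps", {
  motif <- testMotif()
  cfg <- simulationConfig(
    seed = 41, n_es_events = 150, fraction_regulated = 0.25,
    chrom_length = 2e5, n_apa_genes = 0, low_coverage_fraction = 0,
    motif_plant = list(list(motif_id = "test_motif",
                            region_kind = "upstream_flank",
                            direction = "exclusion", fg = 0.7, bg = 0.05)))
  genome <- simulateGenome(cfg)
  sim <- simulateEvents(cfg, genome, list(test_motif = motif))
  expressed <- filterExpressedEvents(sim$events)
  sig <- callSignificantEvents(expressed)
  pool <- selectNullPool(expressed)

  res <- runEnrichment(sig, pool, list(test_motif = motif), sim$genome,
                       seed = 77)
  cell <- res[res$region == "upstream_flank" & res$direction == "exclusion", ]
  expect_equal(nrow(cell), 1)

  # manual composition
  lom <- buildLogOdds(motif)
  thr <- pvalueThreshold(scoreDistribution(lom), 0.001)
  sigW <- extractEsWindows(sig, sim$genome)
  keep <- regionKind(sigW) == "upstream_flank" & !regionTruncated(sigW)
  excl <- S4Vectors::mcols(regionRanges(sigW))$event_id %in%
    SummarizedExperiment::rowData(sig)$event_id[deltaPsi(sig) < -0.1]
  regSeqs <- regionSequences(sigW)[keep & excl]
  obs <- as.integer(countFrequency(as.character(regSeqs), lom, thr))

  poolW <- extractEsWindows(pool, sim$genome)
  keepP <- regionKind(poolW) == "upstream_flank" & !regionTruncated(poolW)
  poolSeqs <- as.character(regionSequences(poolW)[keepP])
  flags <- vapply(poolSeqs, function(s) hasMatch(lom, s, thr), logical(1))
  ns <- sampleNullSets(unname(flags), length(regSeqs), 100,
                       seed = stageSeed(77, paste("test_motif", "ES",
                                                  "upstream_flank",
                                                  "exclusion")))
  zz <- computeZ(obs, ns$freqs)
  expect_equal(cell$observed, obs)
  expect_equal(cell$null_mean, zz$null_mean)
  expect_equal(cell$null_sd, zz$null_sd)
  expect_equal(cell$z, zz$z)
  expect_equal(cell$enriched, zz$z > 1.96)
})

test_that("chi-squared contrast matches the closed form and degenerates to zero", {
  lom <- buildLogOdds(testMotif())
  thr <- pvalueThreshold(scoreDistribution(lom), 0.001)
  # engineer the table ((30,15),(10,25)): 30/40 shortening regions with
  # the consensus, 15/40 lengthening regions with it
  shortS <- plantedSeqs(40, 30, "ACACAC", seed = 11)
  longS <- plantedSeqs(40, 15, "ACACAC", seed = 12)
  res <- motifPresenceChisq(shortS, longS, lom, thr)
  O <- res$table
  # closed form sum((O - E)^2 / E) with margin-product expectations
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$statistic, sum((O - E)^2 / E), tolerance = 1e-9)
  expect_equal(res$p_value, pchisq(res$statistic, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # the engineered counts must be what we planted (sanity on the fixture)
  expect_equal(unname(O[, "shortening"]), c(30, 10))
  expect_equal(unname(O[, "lengthening"]), c(15, 25))

  # identical proportions give statistic 0 and p 1
  eq <- motifPresenceChisq(plantedSeqs(40, 20, "ACACAC", seed = 13),
                           plantedSeqs(20, 10, "ACACAC", seed = 14),
                           lom, thr)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  expect_error(motifPresenceChisq(shortS, character(0), lom, thr),
               "non-empty")
  # all-zero margin: no sequence anywhere has the motif
  expect_error(motifPresenceChisq(plantedSeqs(10, 0, "ACACAC", seed = 15),
                                  plantedSeqs(10, 0, "ACACAC", seed = 16),
                                  lom, thr),
               "margin")
})
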