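#' Resample null control sets and record motif frequencies
#'
#' Draws `n_sets` independent control sets, each of exactly `set_size`
#' regions sampled without replacement from the null pool, and records
#' the motif frequency (number of regions with at least one match) of
#' each set. Presence flags are precomputed once per pool region, so
#' resampling costs no additional scanning.
#'
#' @param flags logical vector: per null-pool region, does it contain
#'   the motif?
#' @param set_size regions per control set (the number of regulated
#'   regions).
#' @param n_sets number of control sets (default 100).
#' @param seed integer seed; draws are reproducible and leave the
#'   caller's RNG untouched.
#' @return list with `freqs` (integer per set), `sets` (set_size x
#'   n_sets index matrix), `set_size`, `n_sets`, `seed`.
#' @export
sampleNullSets <- function(flags, set_size, n_sets = 100, seed = 1) {
  n <- length(flags)
  if (n < set_size)
    stop("null pool (", n, " regions) smaller than set size (", set_size,
         "); sampling with replacement is never done")
  sets <- withSeed(seed, {
    vapply(seq_len(n_sets), function(i) sample.int(n, set_size),
           integer(set_size))
  })
  sets <- matrix(sets, nrow = set_size)
  freqs <- as.integer(colSums(matrix(flags[sets], nrow = set_size)))
  list(freqs = freqs, sets = sets, set_size = set_size, n_sets = n_sets,
       seed = seed)
}

#' Enrichment z-score against resampled null frequencies
#'
#' `z = (observed - mean(null)) / sd(null)` with the population
#' standard deviation (denominator n): the control sets are the full
#' reference population for this statistic. When the null sd is zero,
#' `z` is 0 if the observation equals the null mean and a signed
#' infinity otherwise (so the enrichment call `z > cutoff` still
#' behaves sensibly).
#'
#' @param observed observed motif frequency in the regulated set.
#' @param null_freqs integer frequencies of the control sets (>= 2).
#' @return list with `z`, `null_mean`, `null_sd`.
#' @export
computeZ <- function(observed, null_freqs) {
  if (length(null_freqs) < 2L)
    stop("need at least 2 null frequencies")
  m <- mean(null_freqs)
  s <- sqrt(mean((null_freqs - m)^2))
  z <- if (s > 0) (observed - m) / s
       else if (observed == m) 0
       else sign(observed - m) * Inf
  list(z = z, null_mean = m, null_sd = s)
}

# Build the per-event region tables (regulated + null) used by
# enrichment: ES windows for ES events, proximal/distal windows for
# APA events. Truncated regions are excluded from both sides so window
# lengths stay matched.
.enrichmentRegions <- function(events, genome, flank, apa_flank) {
  parts <- list()
  if (any(eventType(events) == "ES"))
    parts$es <- extractEsWindows(events[eventType(events) == "ES", ],
                                 genome, flank = flank)
  if (sum(eventType(events) == "APA") >= 2L) {
    apa <- classifyApa(events, drop_single = TRUE)
    if (!is.null(apa) && nrow(apa))
      parts$apa <- extractApaWindows(apa, genome, flank = apa_flank)
  }
  if (!length(parts)) return(NULL)
  regions <- do.call(c, unname(lapply(parts, function(p) p@regions)))
  seqs <- do.call(c, unname(lapply(parts, function(p) p@seqs)))
  rs <- ScanRegionSet(regions, seqs)
  rs[!regionTruncated(rs)]
}

#' RBP motif enrichment with a resampled null
#'
#' The core statistic: for every motif x event type x region kind x
#' direction of regulation, the number of regulated regions containing
#' the motif (match p-value below `alpha` under the exact score null)
#' is compared with the frequencies observed in `n_sets` control sets
#' of the same size drawn from equivalent regions of non-regulated
#' events. A motif is called enriched in a cell when its z-score
#' exceeds `z_cutoff` (no multiple-testing adjustment; the fixed
#' cutoff is the decision rule).
#'
#' Directions: `inclusion` (delta PSI > `dpsi_min`) and `exclusion`
#' (delta PSI < -`dpsi_min`). Cassette exons contribute
#' upstream-flank, exon-body and downstream-flank regions; APA events
#' contribute proximal- and distal-site windows.
#'
#' @param significant [SpliceEventSet-class] of regulated events
#'   (after [filterExpressedEvents()] and [callSignificantEvents()]).
#' @param null_pool [SpliceEventSet-class] from [selectNullPool()].
#' @param motifs list of [PWMotif-class].
#' @param genome named [Biostrings::DNAStringSet].
#' @param alpha match p-value cutoff (default 0.001).
#' @param n_sets control sets per cell (default 100).
#' @param z_cutoff enrichment call threshold (default 1.96).
#' @param background,pseudo log-odds construction parameters.
#' @param flank,apa_flank window sizes in nt (defaults 200 and 100).
#' @param dpsi_min direction threshold (default 0.1).
#' @param seed integer; per-cell sampling seeds are derived
#'   deterministically from it.
#' @return data.frame with one row per cell: `motif_id`, `rbp`,
#'   `event_type`, `region`, `direction`, `n_regulated`, `observed`,
#'   `total_matches`, `null_mean`, `null_sd`, `z`, `enriched`.
#'   Run parameters are attached as `attr(x, "metadata")`.
#' @export
runEnrichment <- function(significant, null_pool, motifs, genome,
                          alpha = 0.001, n_sets = 100, z_cutoff = 1.96,
                          background = rep(0.25, 4), pseudo = 1e-4,
                          flank = 200, apa_flank = 100, dpsi_min = 0.1,
                          seed = 1) {
  stopifnot(is(significant, "SpliceEventSet"), is(null_pool, "SpliceEventSet"))
  reg <- .enrichmentRegions(significant, genome, flank, apa_flank)
  nul <- .enrichmentRegions(null_pool, genome, flank, apa_flank)
  if (is.null(reg) || !length(reg)) stop("no regulated regions to scan")
  if (is.null(nul) || !length(nul)) stop("no null-pool regions to scan")

  regType <- eventType(significant)[match(
    S4Vectors::mcols(reg@regions)$event_id,
    SummarizedExperiment::rowData(significant)$event_id)]
  regDpsi <- deltaPsi(significant)[match(
    S4Vectors::mcols(reg@regions)$event_id,
    SummarizedExperiment::rowData(significant)$event_id)]
  regDir <- ifelse(regDpsi > dpsi_min, "inclusion",
                   ifelse(regDpsi < -dpsi_min, "exclusion", NA))
  nulType <- eventType(null_pool)[match(
    S4Vectors::mcols(nul@regions)$event_id,
    SummarizedExperiment::rowData(null_pool)$event_id)]
  regKind <- regionKind(reg)
  nulKind <- regionKind(nul)

  rows <- list()
  for (m in motifs) {
    lom <- buildLogOdds(m, background = background, pseudo = pseudo)
    dist <- scoreDistribution(lom)
    thr <- pvalueThreshold(dist, alpha)
    if (isTRUE(attr(thr, "noMatchPossible"))) {
      regStats <- list(present = logical(length(reg)),
                       totals = integer(length(reg)))
      nulFlags <- logical(length(nul))
    } else {
      regStats <- .matchStats(lom, regionSequences(reg), thr)
      nulFlags <- .matchStats(lom, regionSequences(nul), thr)$present
    }
    for (et in sort(unique(regType))) {
      kinds <- sort(unique(regKind[regType == et]))
      for (kind in kinds) {
        for (dir in c("inclusion", "exclusion")) {
          sel <- which(regType == et & regKind == kind &
                       !is.na(regDir) & regDir == dir)
          if (!length(sel)) next
          pool <- which(nulType == et & nulKind == kind)
          if (!length(pool)) next
          ns <- sampleNullSets(
            nulFlags[pool], set_size = length(sel), n_sets = n_sets,
            seed = stageSeed(seed, paste(motifId(m), et, kind, dir)))
          obs <- sum(regStats$present[sel])
          zz <- computeZ(obs, ns$freqs)
          rows[[length(rows) + 1L]] <- data.frame(
            motif_id = motifId(m), rbp = rbpName(m), event_type = et,
            region = kind, direction = dir, n_regulated = length(sel),
            observed = obs, total_matches = sum(regStats$totals[sel]),
            null_mean = zz$null_mean, null_sd = zz$null_sd, z = zz$z,
            enriched = zz$z > z_cutoff, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif_id = character(), rbp = character(),
               event_type = character(), region = character(),
               direction = character(), n_regulated = integer(),
               observed = integer(), total_matches = integer(),
               null_mean = numeric(), null_sd = numeric(), z = numeric(),
               enriched = logical())
  attr(out, "metadata") <- list(
    alpha = alpha, n_sets = n_sets, z_cutoff = z_cutoff,
    background = background, pseudo = pseudo, flank = flank,
    apa_flank = apa_flank, dpsi_min = dpsi_min, seed = seed)
  out
}

#' Chi-squared contrast of motif presence between two region sets
#'
#' Builds the 2 x 2 table of (has motif / no motif) x (shortening /
#' lengthening) and applies the Pearson chi-squared test on 1 degree
#' of freedom, without continuity correction by default. The p-value
#' is reported raw. Units are events (each region set row is one
#' event's window).
#'
#' @param shortening,lengthening [ScanRegionSet-class]s (or sequence
#'   vectors) for the two contrasted classes; both must be non-empty.
#' @param lom a [LogOddsMatrix-class].
#' @param threshold integer score threshold.
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return list with `statistic`, `p_value`, and `table` (2 x 2).
#' @export
motifPresenceChisq <- function(shortening, lengthening, lom, threshold,
                               correct = FALSE) {
  getSeqs <- function(x) if (is(x, "ScanRegionSet")) regionSequences(x) else x
  s1 <- getSeqs(shortening); s2 <- getSeqs(lengthening)
  if (!length(s1) || !length(s2))
    stop("both region sets must be non-empty")
  f1 <- .matchStats(lom, s1, threshold)$present
  f2 <- .matchStats(lom, s2, threshold)$present
  tab <- matrix(c(sum(f1), sum(!f1), sum(f2), sum(!f2)), nrow = 2,
                dimnames = list(motif = c("has_motif", "no_motif"),
                                class = c("shortening", "lengthening")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-squared test undefined: a table margin is zero")
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       table = tab)
}
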