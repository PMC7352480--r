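#' Simulation configuration
#'
#' One validated object holds every knob of the synthetic-data
#' generators. Defaults are the study conditions the analysis is
#' benchmarked under: 100 regulated + 1000 non-regulated cassette-exon
#' events, regulated effect |delta PSI| around 0.4 with posterior above
#' 0.95, 3 replicates per condition, planted-motif rates 50% foreground
#' vs 5% background, isoform switches of dIF 0.3 with replicate IF
#' noise sd 0.02, and 3000 PDUI sites (10% associated at Pearson r of
#' about 0.5) over 200 samples.
#'
#' @param seed global integer seed; per-stage seeds are derived via
#'   [stageSeed()].
#' @param n_chromosomes,chrom_length,gc_content genome shape.
#' @param n_es_events,fraction_regulated,dpsi_effect,low_coverage_fraction
#'   cassette-exon event generation: total events, fraction regulated,
#'   mean |delta PSI| of regulated events, fraction of events drawn
#'   with read support below the expression filter.
#' @param read_mean mean supporting reads of expressed events.
#' @param n_replicates samples per condition.
#' @param n_apa_genes,apa_fraction_regulated,apa_shortening_fraction
#'   tandem-APA generation (two sites per gene).
#' @param motif_plant list of plant specs, each a list with
#'   `motif_id`, `region_kind`, `direction` (inclusion / exclusion for
#'   ES regions; shortening / lengthening for APA windows), `fg`
#'   (plant rate in regulated events of that direction) and `bg`
#'   (plant rate in all other events).
#' @param n_genes,isoforms_per_gene,switch_fraction,dif_effect,if_noise_sd,tpm_noise_sd,switch_shortening_fraction
#'   isoform TPM generation.
#' @param pdui_n_sites,pdui_fraction_associated,pdui_slope,pdui_noise_sd,pdui_n_samples,pdui_missing_rate
#'   PDUI generation; the implied Pearson correlation of associated
#'   sites is `slope / sqrt(slope^2 + noise_sd^2)`.
#' @param clip_fraction_covered,clip_n_studies,clip_n_decoys,clip_peak_width
#'   CLIP peak generation.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(
    seed = 1,
    n_chromosomes = 1, chrom_length = 1e6, gc_content = 0.41,
    n_es_events = 1100, fraction_regulated = 100 / 1100,
    dpsi_effect = 0.4, low_coverage_fraction = 0.1,
    read_mean = 50, n_replicates = 3,
    n_apa_genes = 100, apa_fraction_regulated = 0.5,
    apa_shortening_fraction = 0.7,
    motif_plant = list(),
    n_genes = 200, isoforms_per_gene = c(2, 4), switch_fraction = 0.25,
    dif_effect = 0.3, if_noise_sd = 0.02, tpm_noise_sd = 0.3,
    switch_shortening_fraction = 0.5,
    pdui_n_sites = 3000, pdui_fraction_associated = 0.1,
    pdui_slope = 0.1, pdui_noise_sd = 0.1 * sqrt(3),
    pdui_n_samples = 200, pdui_missing_rate = 0.05,
    clip_fraction_covered = 0.8, clip_n_studies = 3,
    clip_n_decoys = 200, clip_peak_width = 50) {
  cfg <- as.list(environment())
  rates <- c(gc_content, fraction_regulated, low_coverage_fraction,
             apa_fraction_regulated, apa_shortening_fraction,
             switch_fraction, pdui_fraction_associated,
             pdui_missing_rate, clip_fraction_covered)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (dpsi_effect <= 0.1 || dpsi_effect > 0.9)
    stop("dpsi_effect must lie in (0.1, 0.9] to yield significant events")
  if (dif_effect <= 0 || dif_effect > 0.5)
    stop("dif_effect must lie in (0, 0.5]")
  for (p in motif_plant) {
    need <- c("motif_id", "region_kind", "direction", "fg", "bg")
    if (!all(need %in% names(p)))
      stop("each motif_plant entry needs: ", paste(need, collapse = ", "))
    if (p$fg < 0 || p$fg > 1 || p$bg < 0 || p$bg > 1)
      stop("plant rates must lie in [0, 1]")
  }
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a genome
#'
#' I.i.d. bases at the configured GC content; reproducible
#' byte-for-byte under the config seed.
#'
#' @param config a [simulationConfig()].
#' @return named [Biostrings::DNAStringSet] (`chr1`, `chr2`, ...).
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  gc <- config$gc_content
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  withSeed(stageSeed(config$seed, "genome"), {
    seqs <- vapply(seq_len(config$n_chromosomes), function(i)
      paste(sample(DNA_BASES, config$chrom_length, replace = TRUE,
                   prob = p), collapse = ""),
      character(1))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- paste0("chr", seq_len(config$n_chromosomes))
    out
  })
}

# Draw one word from a PWM (per-position categorical draw).
.sampleWord <- function(motif) {
  paste(apply(motifMatrix(motif), 2, function(col)
    sample(DNA_BASES, 1L, prob = col)), collapse = "")
}

# Lay out non-overlapping slots of the given widths across chromosomes.
.layoutSlots <- function(widths, chrom_lengths, margin = 250L) {
  chrom <- integer(length(widths)); start <- integer(length(widths))
  ci <- 1L; cursor <- margin
  for (i in seq_along(widths)) {
    while (cursor + widths[i] + margin > chrom_lengths[ci]) {
      ci <- ci + 1L
      if (ci > length(chrom_lengths))
        stop("genome too small for the requested number of events; ",
             "increase chrom_length or n_chromosomes")
      cursor <- margin
    }
    chrom[i] <- ci; start[i] <- cursor
    cursor <- cursor + widths[i]
  }
  list(chrom = chrom, start = start)
}

#' Simulate splicing events with planted motif signal
#'
#' Generates cassette-exon (ES) events and tandem-APA gene pairs on
#' the given genome. Regulated events draw |delta PSI| around the
#' configured effect with posterior at least 0.95; non-regulated
#' events draw |delta PSI| below 0.005 with posterior at most 0.3.
#' Read support makes a known subset survive the expression filter
#' (recorded in the manifest). For every `motif_plant` spec, exact
#' words sampled from the named PWM are written into the configured
#' window of regulated events of the matching direction at the
#' foreground rate and into all other events' windows at the
#' background rate; every planted instance is recorded. Plants that
#' would overlap an earlier plant are re-drawn (error after 100
#' attempts).
#'
#' @param config a [simulationConfig()].
#' @param genome output of [simulateGenome()] (or any compatible
#'   genome).
#' @param motifs named list of [PWMotif-class] covering every
#'   `motif_plant$motif_id`.
#' @param flank,apa_flank scan-window geometry to plant into
#'   (defaults 200 and 100, matching the extraction defaults).
#' @return list with `events` ([SpliceEventSet-class]), `genome`
#'   (edited copy), `manifest` (per-event truth) and `plants`
#'   (per-plant record).
#' @export
simulateEvents <- function(config, genome, motifs = list(),
                           flank = 200, apa_flank = 100) {
  stopifnot(inherits(config, "SimulationConfig"))
  for (p in config$motif_plant)
    if (!p$motif_id %in% names(motifs))
      stop("motif_plant references unknown motif: ", p$motif_id)
  withSeed(stageSeed(config$seed, "events"), {
    nES <- config$n_es_events
    nAPA <- config$n_apa_genes
    Ls <- Biostrings::width(genome)

    exonW <- sample(80:150, nES, replace = TRUE)
    esWidths <- as.integer(flank + exonW + flank + 150L)
    apaWidths <- rep.int(as.integer(2L * (2L * apa_flank + 1L) + 600L), nAPA)
    lay <- .layoutSlots(c(esWidths, apaWidths), Ls)

    ## --- ES events -------------------------------------------------
    esChrom <- names(genome)[lay$chrom[seq_len(nES)]]
    esStart <- lay$start[seq_len(nES)] + flank         # exon start, 0-based
    esEnd <- esStart + exonW
    esStrand <- sample(c("+", "-"), nES, replace = TRUE)
    regulated <- seq_len(nES) <= round(config$fraction_regulated * nES)
    lowcov <- runif(nES) < config$low_coverage_fraction
    mag <- pmin(0.85, pmax(0.15,
                           rnorm(nES, config$dpsi_effect, 0.05)))
    sign_ <- sample(c(1, -1), nES, replace = TRUE)
    dpsi <- ifelse(regulated, mag * sign_, runif(nES, -0.005, 0.005))
    post <- ifelse(regulated, runif(nES, 0.95, 1), runif(nES, 0.05, 0.3))
    psiC <- runif(nES, pmax(0.02, -dpsi + 0.01), pmin(0.98, 1 - dpsi - 0.01))
    esDir <- ifelse(!regulated, NA,
                    ifelse(dpsi > 0, "inclusion", "exclusion"))

    es <- data.frame(
      event_id = sprintf("ES%04d", seq_len(nES)),
      gene_id = sprintf("esG%04d", seq_len(nES)),
      event_type = "ES", chrom = esChrom, start = esStart, end = esEnd,
      strand = esStrand, psi_control = psiC, psi_silenced = psiC + dpsi,
      delta_psi = dpsi, posterior = post, stringsAsFactors = FALSE)

    ## --- APA events (two sites per gene) ---------------------------
    apa <- NULL
    apaDirGene <- character(0)
    if (nAPA > 0) {
      apaChrom <- names(genome)[lay$chrom[nES + seq_len(nAPA)]]
      apaBase <- lay$start[nES + seq_len(nAPA)]
      site1 <- apaBase + apa_flank          # leftmost site, 0-based
      site2 <- site1 + 600L
      apaStrand <- sample(c("+", "-"), nAPA, replace = TRUE)
      apaReg <- runif(nAPA) < config$apa_fraction_regulated
      apaShort <- runif(nAPA) < config$apa_shortening_fraction
      apaDirGene <- ifelse(!apaReg, NA,
                           ifelse(apaShort, "shortening", "lengthening"))
      amag <- pmin(0.85, pmax(0.15, rnorm(nAPA, config$dpsi_effect, 0.05)))
      apost <- ifelse(apaReg, runif(nAPA, 0.95, 1), runif(nAPA, 0.05, 0.3))
      # proximal is the leftmost site on +, the rightmost on -
      proxIsSite1 <- apaStrand == "+"
      # delta PSI of proximal site: + for shortening genes
      dProx <- ifelse(apaReg, ifelse(apaShort, amag, -amag),
                      runif(nAPA, -0.005, 0.005))
      dDist <- ifelse(apaReg, -dProx, runif(nAPA, -0.005, 0.005))
      d1 <- ifelse(proxIsSite1, dProx, dDist)
      d2 <- ifelse(proxIsSite1, dDist, dProx)
      pC1 <- runif(nAPA, pmax(0.02, -d1 + 0.01), pmin(0.98, 1 - d1 - 0.01))
      pC2 <- runif(nAPA, pmax(0.02, -d2 + 0.01), pmin(0.98, 1 - d2 - 0.01))
      apa <- data.frame(
        event_id = c(sprintf("APA%04d.1", seq_len(nAPA)),
                     sprintf("APA%04d.2", seq_len(nAPA))),
        gene_id = rep(sprintf("apaG%04d", seq_len(nAPA)), 2),
        event_type = "APA",
        chrom = rep(apaChrom, 2),
        start = c(site1, site2), end = c(site1, site2) + 1L,
        strand = rep(apaStrand, 2),
        psi_control = c(pC1, pC2),
        psi_silenced = c(pC1 + d1, pC2 + d2),
        delta_psi = c(d1, d2), posterior = rep(apost, 2),
        stringsAsFactors = FALSE)
    }

    all <- if (is.null(apa)) es else rbind(es, apa)
    nAll <- nrow(all)

    ## --- read support ----------------------------------------------
    nSamp <- 2L * config$n_replicates
    lowAll <- c(lowcov, rep(FALSE, nAll - nES))
    reads <- matrix(0L, nAll, nSamp)
    reads[!lowAll, ] <- 10L + rpois(sum(!lowAll) * nSamp, config$read_mean)
    reads[lowAll, ] <- rpois(sum(lowAll) * nSamp, 4)
    cond <- rep(c("control", "silenced"), each = config$n_replicates)
    colnames(reads) <- paste(cond, rep(seq_len(config$n_replicates), 2),
                             sep = "_")
    passes <- rep(TRUE, nAll)
    for (cc in c("control", "silenced")) {
      sub <- reads[, cond == cc, drop = FALSE]
      passes <- passes & rowSums(sub >= 10L) >= 2L
    }

    ## --- motif planting --------------------------------------------
    plants <- list()
    occupied <- list()  # per chrom: 2-col matrix of [start, end) plants
    plantInto <- function(chrom, winStart, winEnd, strand, word,
                          motif_id, event_id, kind, class_) {
      k <- nchar(word)
      if (winEnd - winStart < k) return(NULL)
      for (attempt in 1:100) {
        off <- sample.int(winEnd - winStart - k + 1L, 1L) - 1L
        gs <- if (strand == "+") winStart + off else winEnd - off - k
        ge <- gs + k
        occ <- occupied[[chrom]]
        if (!is.null(occ) && any(occ[, 1] < ge & gs < occ[, 2])) next
        occupied[[chrom]] <<- rbind(occ, c(gs, ge))
        return(data.frame(motif_id = motif_id, event_id = event_id,
                          region_kind = kind, chrom = chrom,
                          plant_start = gs, plant_end = ge,
                          strand = strand, offset = off, word = word,
                          class = class_, stringsAsFactors = FALSE))
      }
      stop("could not place a motif plant without collision after ",
           "100 attempts (event ", event_id, ")")
    }

    # genomic span of a sense-strand window for an ES event
    esWindow <- function(i, kind) {
      s <- es$start[i]; e <- es$end[i]; st <- es$strand[i]
      if (kind == "exon_body") return(c(s, e))
      upLeft <- (kind == "upstream_flank") == (st == "+")
      if (upLeft) c(s - flank, s) else c(e, e + flank)
    }

    for (p in config$motif_plant) {
      motif <- motifs[[p$motif_id]]
      if (p$region_kind %in% c("upstream_flank", "exon_body",
                               "downstream_flank")) {
        for (i in seq_len(nES)) {
          isFg <- !is.na(esDir[i]) && esDir[i] == p$direction
          rate <- if (isFg) p$fg else p$bg
          if (runif(1) >= rate) next
          w <- .sampleWord(motif)
          win <- esWindow(i, p$region_kind)
          plants[[length(plants) + 1L]] <- plantInto(
            es$chrom[i], win[1], win[2], es$strand[i], w, p$motif_id,
            es$event_id[i], p$region_kind, if (isFg) "fg" else "bg")
        }
      } else if (p$region_kind %in% c("apa_proximal_window",
                                      "apa_distal_window") && nAPA > 0) {
        wantProx <- p$region_kind == "apa_proximal_window"
        for (g in seq_len(nAPA)) {
          isFg <- !is.na(apaDirGene[g]) && apaDirGene[g] == p$direction
          rate <- if (isFg) p$fg else p$bg
          if (runif(1) >= rate) next
          st <- apa$strand[g]
          siteIsS1 <- (st == "+") == wantProx
          site <- if (siteIsS1) apa$start[g] else apa$start[nAPA + g]
          eid <- if (siteIsS1) apa$event_id[g] else apa$event_id[nAPA + g]
          w <- .sampleWord(motif)
          plants[[length(plants) + 1L]] <- plantInto(
            apa$chrom[g], site - apa_flank, site + apa_flank + 1L, st,
            w, p$motif_id, eid, p$region_kind,
            if (isFg) "fg" else "bg")
        }
      } else {
        stop("unknown region_kind in motif_plant: ", p$region_kind)
      }
    }
    plants <- if (length(plants)) do.call(rbind, plants) else
      data.frame(motif_id = character(), event_id = character(),
                 region_kind = character(), chrom = character(),
                 plant_start = integer(), plant_end = integer(),
                 strand = character(), offset = integer(),
                 word = character(), class = character())

    ## write the plants into the genome (minus-strand windows receive
    ## the reverse complement so the sense-strand sequence carries the
    ## sampled word)
    if (nrow(plants)) {
      for (ch in unique(plants$chrom)) {
        sub <- plants[plants$chrom == ch, ]
        val <- ifelse(sub$strand == "+", sub$word,
                      vapply(sub$word, function(w) as.character(
                        Biostrings::reverseComplement(
                          Biostrings::DNAString(w))), character(1)))
        genome[[ch]] <- Biostrings::replaceAt(
          genome[[ch]],
          IRanges::IRanges(sub$plant_start + 1L, sub$plant_end),
          val)
      }
    }

    manifest <- data.frame(
      event_id = all$event_id, gene_id = all$gene_id,
      event_type = all$event_type, chrom = all$chrom,
      start = all$start, end = all$end, strand = all$strand,
      delta_psi = all$delta_psi, posterior = all$posterior,
      regulated = c(regulated,
                    if (nAPA > 0) rep(!is.na(apaDirGene), 2) else logical(0)),
      direction = c(esDir,
                    if (nAPA > 0) rep(apaDirGene, 2) else character(0)),
      low_coverage = lowAll, passes_read_filter = passes,
      stringsAsFactors = FALSE)

    list(events = SpliceEventSet(all, reads, cond), genome = genome,
         manifest = manifest, plants = plants)
  })
}

#' Simulate an isoform TPM matrix with planted switches
#'
#' Per gene, condition-level isoform fractions come from a Dirichlet
#' draw; switch genes shift a pair of isoforms by the configured dIF
#' in opposite directions in the silenced condition. Replicate IFs add
#' Gaussian noise (renormalized onto the simplex), and TPMs are gene
#' expression times IF times log-normal noise. Transcript models give
#' the switch pair opposite-length 3'UTRs so the consequence caller is
#' exercised.
#'
#' @param config a [simulationConfig()].
#' @return list with `tpm` (matrix), `map` (isoform to gene
#'   data.frame), `models` (transcript-model data.frame), `condition`
#'   (per-sample labels), `manifest` (per-switch-gene truth).
#' @export
simulateIsoformTpm <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(stageSeed(config$seed, "isoform"), {
    nG <- config$n_genes
    nRep <- config$n_replicates
    e <- config$dif_effect
    nIso <- sample(seq(config$isoforms_per_gene[1],
                       config$isoforms_per_gene[2]), nG, replace = TRUE)
    isSwitch <- seq_len(nG) <= round(config$switch_fraction * nG)
    shortUp <- runif(nG) < config$switch_shortening_fraction

    cond <- rep(c("control", "silenced"), each = nRep)
    tpm <- NULL; map <- NULL; models <- NULL; manifest <- NULL
    utr3pool <- c(200L, 1500L)
    rowsT <- list(); rowsMap <- list(); rowsMod <- list(); rowsMan <- list()
    for (g in seq_len(nG)) {
      k <- nIso[g]
      gid <- sprintf("isoG%04d", g)
      iso <- sprintf("%s.%d", gid, seq_len(k))
      base <- rgamma(k, 2); base <- base / sum(base)
      if (isSwitch[g]) {
        # the first two isoforms are the switch pair; keep head-room so
        # the planted +/- e shift stays inside the simplex
        if (k == 2L) {
          b1 <- runif(1, 0.15, min(0.45, 1 - e - 0.05))
          base <- c(b1, 1 - b1)
        } else {
          b1 <- runif(1, 0.15, 0.45)
          b2 <- runif(1, e + 0.05, min(0.5, 0.95 - b1))
          r <- rgamma(k - 2, 2)
          base <- c(b1, b2, (1 - b1 - b2) * r / sum(r))
        }
      }
      ctl <- base
      sil <- base
      if (isSwitch[g]) { sil[1] <- sil[1] + e; sil[2] <- sil[2] - e }
      geneBase <- if (isSwitch[g]) rlnorm(1, 3.5, 0.5) + 5 else rlnorm(1, 2, 1.5)
      mat <- matrix(NA_real_, k, 2 * nRep)
      for (s in seq_len(2 * nRep)) {
        target <- if (cond[s] == "control") ctl else sil
        f <- pmax(0, target + rnorm(k, 0, config$if_noise_sd))
        f <- f / sum(f)
        mat[, s] <- geneBase * exp(rnorm(1, 0, config$tpm_noise_sd)) * f
      }
      rownames(mat) <- iso
      rowsT[[g]] <- mat
      rowsMap[[g]] <- data.frame(isoform_id = iso, gene_id = gid)
      # one-exon transcripts; switch pair gets opposite-length 3'UTRs
      off <- (g - 1L) * 20000L
      utr3 <- sample(seq(200L, 1500L, by = 50L), k, replace = TRUE)
      if (isSwitch[g]) {
        utr3[1] <- if (shortUp[g]) utr3pool[1] else utr3pool[2]
        utr3[2] <- if (shortUp[g]) utr3pool[2] else utr3pool[1]
      }
      rowsMod[[g]] <- data.frame(
        transcript_id = iso, gene_id = gid, chrom = "chrT", strand = "+",
        exon_starts = as.character(off + 500L),
        exon_ends = as.character(off + 1600L + utr3),
        cds_start = off + 1000L, cds_end = off + 1600L,
        stringsAsFactors = FALSE)
      if (isSwitch[g])
        rowsMan[[length(rowsMan) + 1L]] <- data.frame(
          gene_id = gid, up_isoform = iso[1], down_isoform = iso[2],
          true_dIF = e,
          expected_consequence = if (shortUp[g]) "3UTR_shortening"
                                 else "3UTR_lengthening",
          stringsAsFactors = FALSE)
    }
    tpm <- do.call(rbind, rowsT)
    colnames(tpm) <- paste(cond, rep(seq_len(nRep), 2), sep = "_")
    list(tpm = tpm, map = do.call(rbind, rowsMap),
         models = do.call(rbind, rowsMod), condition = cond,
         manifest = if (length(rowsMan)) do.call(rbind, rowsMan) else
           data.frame(gene_id = character(), up_isoform = character(),
                      down_isoform = character(), true_dIF = numeric(),
                      expected_consequence = character()))
  })
}

#' Simulate a PDUI matrix with planted expression associations
#'
#' Associated sites follow `PDUI = clip01(a + slope * z(expr) * s +
#' noise)` with a random association sign `s`; null sites are
#' independent noise around a random baseline. A configurable fraction
#' of entries is set missing.
#'
#' @param config a [simulationConfig()].
#' @return list with `pdui` (sites x samples matrix), `expression`
#'   (per-sample vector), `manifest` (`site_id`, `associated`, `sign`).
#' @export
simulatePdui <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(stageSeed(config$seed, "pdui"), {
    nS <- config$pdui_n_sites
    nSamp <- config$pdui_n_samples
    expr <- rlnorm(nSamp, 2, 1)
    names(expr) <- sprintf("S%03d", seq_len(nSamp))
    # standardize on the log scale: expression effects on usage are
    # multiplicative, and the skew of the raw scale would otherwise
    # dilute the planted linear association
    z <- as.numeric(scale(log(expr)))
    assoc <- seq_len(nS) <= round(config$pdui_fraction_associated * nS)
    sgn <- sample(c(1, -1), nS, replace = TRUE)
    a <- runif(nS, 0.35, 0.65)
    pdui <- matrix(NA_real_, nS, nSamp,
                   dimnames = list(sprintf("site_%04d", seq_len(nS)),
                                   names(expr)))
    for (i in seq_len(nS)) {
      mu <- if (assoc[i]) a[i] + config$pdui_slope * sgn[i] * z else a[i]
      pdui[i, ] <- clip01(mu + rnorm(nSamp, 0, config$pdui_noise_sd))
    }
    miss <- matrix(runif(nS * nSamp) < config$pdui_missing_rate, nS, nSamp)
    pdui[miss] <- NA
    list(pdui = pdui, expression = expr,
         manifest = data.frame(site_id = rownames(pdui),
                               associated = assoc, sign = sgn))
  })
}

#' Simulate CLIP peak sets around regulated events
#'
#' A configured fraction of the regulated, filter-passing events
#' receives one peak inside its 200 bp-extended interval, assigned to
#' a random study; each study additionally receives decoy peaks placed
#' away from all extended event intervals.
#'
#' @param config a [simulationConfig()].
#' @param sim output of [simulateEvents()] (uses `events` geometry and
#'   `manifest` truth).
#' @param extension extension used to define "inside" (default 200).
#' @return list with `peaks` (named list of GRanges, one per study)
#'   and `manifest` (`event_id`, `covered`, `study`).
#' @export
simulateClipPeaks <- function(config, sim, extension = 200) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(stageSeed(config$seed, "clip"), {
    man <- sim$manifest
    gr <- SummarizedExperiment::rowRanges(sim$events)
    Ls <- Biostrings::width(sim$genome)
    names(Ls) <- names(sim$genome)
    w <- config$clip_peak_width
    target <- man$regulated & man$passes_read_filter
    covered <- target & runif(nrow(man)) < config$clip_fraction_covered
    study <- rep(NA_integer_, nrow(man))
    study[covered] <- sample.int(config$clip_n_studies, sum(covered),
                                 replace = TRUE)
    peakRows <- vector("list", config$clip_n_studies)
    extStart <- pmax(0L, man$start - extension)
    extEnd <- pmin(Ls[man$chrom], man$end + extension)
    for (i in which(covered)) {
      lo <- extStart[i]; hi <- extEnd[i] - w
      if (hi <= lo) { lo <- extStart[i]; hi <- lo + 1L }
      ps <- lo + sample.int(max(1L, hi - lo), 1L) - 1L
      peakRows[[study[i]]] <- rbind(
        peakRows[[study[i]]],
        data.frame(chrom = man$chrom[i], start = ps, end = ps + w))
    }
    # decoys: rejection-sample positions clear of all extended intervals
    for (st in seq_len(config$clip_n_studies)) {
      placed <- 0L; attempts <- 0L
      while (placed < config$clip_n_decoys && attempts < 50L *
             config$clip_n_decoys) {
        attempts <- attempts + 1L
        ch <- sample(names(Ls), 1L)
        ps <- sample.int(Ls[[ch]] - w, 1L) - 1L
        sameChr <- man$chrom == ch
        if (any(sameChr & extStart < ps + w & ps < extEnd)) next
        peakRows[[st]] <- rbind(
          peakRows[[st]],
          data.frame(chrom = ch, start = ps, end = ps + w))
        placed <- placed + 1L
      }
    }
    peaks <- lapply(seq_len(config$clip_n_studies), function(st) {
      df <- peakRows[[st]]
      if (is.null(df)) return(GenomicRanges::GRanges())
      g <- GenomicRanges::GRanges(df$chrom,
                                  IRanges::IRanges(df$start + 1L, df$end),
                                  strand = "+")
      S4Vectors::metadata(g)$study_id <- paste0("study_", st)
      g
    })
    names(peaks) <- paste0("study_", seq_len(config$clip_n_studies))
    list(peaks = peaks,
         manifest = data.frame(event_id = man$event_id, covered = covered,
                               study = ifelse(is.na(study), NA,
                                              paste0("study_", study))))
  })
}
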