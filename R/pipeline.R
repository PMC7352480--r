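#' Built-in synthetic motif library
#'
#' Three deterministic position weight matrices used by the examples,
#' the simulators and the end-to-end pipeline: a CA-rich 6-mer
#' modelling the C/A-rich element preference of hnRNPL-class splicing
#' factors, a G-rich and a U-rich control motif. All three are
#' synthetic constructions, not measured matrices.
#'
#' @return named list of [PWMotif-class].
#' @export
exampleMotifs <- function() {
  col <- function(base, p = 0.90) {
    v <- rep((1 - p) / 3, 4); names(v) <- DNA_BASES
    v[base] <- p
    v
  }
  mk <- function(id, rbp, bases) {
    m <- vapply(bases, col, numeric(4))
    dimnames(m) <- list(DNA_BASES, NULL)
    PWMotif(id, m, rbp)
  }
  list(
    CArich_syn = mk("CArich_syn", "HNRNPL_like", c("A", "C", "A", "C", "A", "C")),
    Grich_syn = mk("Grich_syn", "Grich_ctrl", c("G", "G", "T", "G", "G", "G")),
    Urich_syn = mk("Urich_syn", "Urich_ctrl", c("T", "T", "T", "G", "T", "T"))
  )
}

#' Random position weight matrices
#'
#' Dirichlet(1)-column PWMs, handy for calibration experiments.
#'
#' @param n number of motifs.
#' @param k motif length (recycled).
#' @param seed integer seed.
#' @return named list of [PWMotif-class].
#' @export
randomMotifs <- function(n, k = 6, seed = 1) {
  k <- rep_len(k, n)
  withSeed(seed, {
    out <- lapply(seq_len(n), function(i) {
      m <- matrix(rgamma(4 * k[i], 1), nrow = 4)
      m <- sweep(m, 2, colSums(m), "/")
      rownames(m) <- DNA_BASES
      PWMotif(sprintf("rand%02d", i), m)
    })
    names(out) <- vapply(out, motifId, character(1))
    out
  })
}

#' Analysis thresholds
#'
#' All tunable thresholds of the pipeline in one list, at their
#' standard defaults: read filter (>= 10 reads in >= 2 samples per
#' condition), significance (|delta PSI| > 0.1 and posterior > 0.9),
#' null pool (|delta PSI| < 0.01 and posterior < 0.5), motif match
#' p-value < 0.001, 200-nt exon flanks and 100-nt APA half-windows,
#' 100 control sets at z > 1.96, gene TPM >= 1, isoform IF >= 0.01,
#' |dIF| > 0.1 at BH q <= 0.05.
#'
#' @param ... overrides for any threshold.
#' @return named list.
#' @export
pipelineParams <- function(...) {
  p <- list(min_reads = 10, min_samples = 2, dpsi_min = 0.1,
            prob_min = 0.9, null_dpsi_max = 0.01, null_prob_max = 0.5,
            alpha = 0.001, flank = 200, apa_flank = 100, n_sets = 100,
            z_cutoff = 1.96, min_gene_tpm = 1, min_if = 0.01,
            dif_min = 0.1, q_max = 0.05, pdui_min_n = 10,
            clip_extension = 200)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  p
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Chains every stage on seeded synthetic inputs: simulate genome and
#' events, filter by read support, call significant events and the
#' null pool, scan significant regions for motifs, run the
#' resampled-null enrichment, classify APA events and contrast motif
#' presence between 3'UTR-shortening and -lengthening windows, test
#' isoform switches and their UTR consequences, run the PDUI dual
#' criterion, and overlap events with simulated CLIP peaks. All
#' outputs are TSV files under `out_dir` plus a `run_metadata.tsv`
#' echoing every threshold and seed; outputs are byte-identical across
#' runs with the same configuration.
#'
#' @param config a [simulationConfig()]; its `seed` drives every
#'   stage through [stageSeed()].
#' @param out_dir output directory (created if needed).
#' @param motifs named list of [PWMotif-class] (default
#'   [exampleMotifs()]).
#' @param stages character vector of stages to run, any of
#'   `"simulate"`, `"filter-events"`, `"scan"`, `"enrich"`,
#'   `"switch"`, `"utr-assoc"`, `"clip-overlap"`, or `"all"`
#'   (default). Stages after `simulate` require the stages they
#'   depend on in the same call.
#' @param params a [pipelineParams()] list.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
runPipeline <- function(config = simulationConfig(), out_dir,
                        motifs = exampleMotifs(), stages = "all",
                        params = pipelineParams()) {
  allStages <- c("simulate", "filter-events", "scan", "enrich", "switch",
                 "utr-assoc", "clip-overlap")
  if (identical(stages, "all")) stages <- allStages
  bad <- setdiff(stages, allStages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config, params = params)

  if ("simulate" %in% stages) {
    genome0 <- simulateGenome(config)
    sim <- simulateEvents(config, genome0, motifs,
                          flank = params$flank,
                          apa_flank = params$apa_flank)
    res$sim <- sim
    writeGenomeFasta(sim$genome, file.path(out_dir, "genome.fa"))
    writeMemeMotifs(motifs, file.path(out_dir, "motifs.meme"))
    writeEventTable(sim$events, file.path(out_dir, "events.tsv"))
    .writeTsv(sim$manifest, file.path(out_dir, "manifest_events.tsv"))
    .writeTsv(sim$plants, file.path(out_dir, "manifest_plants.tsv"))
    .log("simulate", nrow(sim$events), " events, ",
         nrow(sim$plants), " planted motif instances")
  }

  needSim <- function() {
    if (is.null(res$sim))
      stop("this stage requires the 'simulate' stage in the same call")
    res$sim
  }

  if ("filter-events" %in% stages) {
    sim <- needSim()
    expressed <- filterExpressedEvents(sim$events, params$min_reads,
                                       params$min_samples)
    significant <- callSignificantEvents(expressed, params$dpsi_min,
                                         params$prob_min)
    nullPool <- selectNullPool(expressed, params$null_dpsi_max,
                               params$null_prob_max)
    res$expressed <- expressed
    res$significant <- significant
    res$null_pool <- nullPool
    writeEventTable(expressed, file.path(out_dir, "filtered_events.tsv"))
    writeEventTable(significant, file.path(out_dir, "significant_events.tsv"))
    writeEventTable(nullPool, file.path(out_dir, "null_pool.tsv"))
    .log("filter-events", nrow(sim$events), " -> ", nrow(expressed),
         " expressed; ", nrow(significant), " significant; ",
         nrow(nullPool), " null pool")
  }

  if ("scan" %in% stages) {
    sig <- res$significant
    if (is.null(sig)) stop("'scan' requires 'filter-events'")
    sim <- needSim()
    esSig <- sig[eventType(sig) == "ES", ]
    matches <- NULL
    if (nrow(esSig)) {
      regions <- extractEsWindows(esSig, sim$genome, flank = params$flank)
      matches <- do.call(rbind, lapply(motifs, function(m)
        scanRegions(regions, m, alpha = params$alpha)))
    }
    if (is.null(matches))
      matches <- data.frame(region_id = character(), motif_id = character(),
                            offset = integer(), score_bits = numeric(),
                            p_value = numeric())
    res$matches <- matches
    writeMatches(matches, file.path(out_dir, "motif_matches.tsv"))
    .log("scan", nrow(matches), " matches over significant ES regions")
  }

  if ("enrich" %in% stages) {
    if (is.null(res$significant)) stop("'enrich' requires 'filter-events'")
    sim <- needSim()
    enr <- runEnrichment(res$significant, res$null_pool, motifs,
                         sim$genome, alpha = params$alpha,
                         n_sets = params$n_sets,
                         z_cutoff = params$z_cutoff,
                         flank = params$flank,
                         apa_flank = params$apa_flank,
                         dpsi_min = params$dpsi_min,
                         seed = stageSeed(config$seed, "enrich"))
    res$enrichment <- enr
    .writeTsv(enr, file.path(out_dir, "enrichment.tsv"))
    .log("enrich", nrow(enr), " cells, ", sum(enr$enriched),
         " enriched at z > ", params$z_cutoff)

    # APA classification + shortening-vs-lengthening motif contrast
    sig <- res$significant
    if (sum(eventType(sig) == "APA") >= 2L) {
      apa <- classifyApa(sig, drop_single = TRUE)
      .writeTsv(apa, file.path(out_dir, "apa_classification.tsv"))
      wins <- extractApaWindows(apa, sim$genome, flank = params$apa_flank)
      dirOf <- apa$utr_direction[match(
        S4Vectors::mcols(wins@regions)$event_id, apa$event_id)]
      shortW <- wins[dirOf == "shortening" & !regionTruncated(wins)]
      longW <- wins[dirOf == "lengthening" & !regionTruncated(wins)]
      if (length(shortW) && length(longW)) {
        m1 <- motifs[[1]]
        lom <- buildLogOdds(m1)
        thr <- pvalueThreshold(scoreDistribution(lom), params$alpha)
        cs <- tryCatch(motifPresenceChisq(shortW, longW, lom, thr),
                       error = function(e) NULL)
        if (is.null(cs)) {
          .log("enrich", "shortening vs lengthening contrast undefined ",
               "(zero table margin); skipped")
        } else {
        .writeTsv(data.frame(motif_id = motifId(m1),
                             statistic = cs$statistic,
                             p_value = cs$p_value,
                             short_with = cs$table[1, 1],
                             short_without = cs$table[2, 1],
                             long_with = cs$table[1, 2],
                             long_without = cs$table[2, 2]),
                  file.path(out_dir, "chisq_shortening_lengthening.tsv"))
        res$chisq <- cs
        .log("enrich", "shortening vs lengthening chi-squared p = ",
             signif(cs$p_value, 4))
        }
      }
    }
  }

  if ("switch" %in% stages) {
    iso <- simulateIsoformTpm(config)
    res$iso_sim <- iso
    quants <- computeIsoformFractions(iso$tpm, iso$map, iso$condition,
                                      params$min_gene_tpm, params$min_if)
    quants <- testSwitches(quants, params$dif_min, params$q_max)
    cons <- annotateConsequences(quants, iso$models)
    res$switches <- quants
    res$consequences <- cons
    rd <- SummarizedExperiment::rowData(quants)
    .writeTsv(data.frame(isoform_id = rownames(rd), as.data.frame(rd)),
              file.path(out_dir, "switch_table.tsv"))
    .writeTsv(cons, file.path(out_dir, "switch_consequences.tsv"))
    .writeTsv(iso$manifest, file.path(out_dir, "manifest_switch.tsv"))
    .log("switch", sum(rd$significant), " significant isoforms, ",
         nrow(cons), " consequence-annotated genes")
  }

  if ("utr-assoc" %in% stages) {
    ps <- simulatePdui(config)
    res$pdui_sim <- ps
    assoc <- associatePdui(ps$pdui, ps$expression,
                           q_threshold = params$q_max,
                           min_n = params$pdui_min_n)
    res$pdui_assoc <- assoc
    .writeTsv(assoc, file.path(out_dir, "pdui_association.tsv"))
    .writeTsv(ps$manifest, file.path(out_dir, "manifest_pdui.tsv"))
    .log("utr-assoc", sum(assoc$significant), " of ", nrow(assoc),
         " sites significant on the dual criterion")
  }

  if ("clip-overlap" %in% stages) {
    sim <- needSim()
    cp <- simulateClipPeaks(config, sim, extension = params$clip_extension)
    res$clip_sim <- cp
    rep_ <- overlapEvents(sim$events, cp$peaks,
                          extension = params$clip_extension)
    res$clip_report <- rep_
    .writeTsv(rep_, file.path(out_dir, "clip_overlap.tsv"))
    .writeTsv(cp$manifest, file.path(out_dir, "manifest_clip.tsv"))
    .log("clip-overlap", sum(rep_$supported), " of ", nrow(rep_),
         " events supported by >= 1 study")
  }

  meta <- c(list(seed = config$seed), params)
  .writeTsv(data.frame(key = names(meta),
                       value = vapply(meta, function(v)
                         paste(v, collapse = ","), character(1))),
            file.path(out_dir, "run_metadata.tsv"))
  invisible(res)
}
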