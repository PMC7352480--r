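# spliceRBP

Downstream analysis of alternative-splicing (AS) regulation after a
long non-coding RNA knockdown. Silencing a lncRNA that sequesters a
splicing factor (the motivating case is an hnRNPL-binding lncRNA in
breast-cancer cells) shifts cassette-exon inclusion, tandem
polyadenylation-site choice and isoform usage; this package provides
the statistical machinery to go from quantified AS events to the
RNA-binding proteins (RBPs) that plausibly drive them:

- **Event filtering** — keep events with >= 10 supporting reads in
  >= 2 samples per condition; call events significant when
  |&Delta;PSI| > 0.1 with posterior probability > 0.9; build the
  non-regulated null pool (|&Delta;PSI| < 0.01, posterior < 0.5).
- **Scan windows** — cassette exons with 200-nt intronic flanks
  (transcription-direction aware), and 201-nt windows around
  proximal/distal APA sites sorted per gene.
- **PWM scanning with exact p-values** — motif log-odds scores
  `log2(((1-4c)p + c)/bg)` are integer-scaled (1000 units/bit) and the
  full null score distribution of a random k-mer is computed by
  convolution, so the match cutoff p < 0.001 is an exact score
  threshold, not an approximation.
- **Resampled-null enrichment** — per motif x event type x region x
  direction of regulation, the number of regulated regions containing
  the motif is z-scored against the mean and standard deviation of 100
  control sets of equal size drawn from equivalent regions of
  non-regulated events; cells with z > 1.96 are called enriched:

  z = (observed − mean(null)) / sd(null)

- **3'UTR direction contrast** — Pearson chi-squared (1 df, no
  continuity correction) of motif presence in shortening vs
  lengthening APA windows.
- **Isoform switching** — isoform fraction IF = TPM_iso / TPM_gene,
  dIF = IF_silenced − IF_control; switches need BH-corrected
  p <= 0.05 and |dIF| > 0.1, and are annotated with 5'/3'UTR
  shortening/lengthening consequences from transcript models.
- **PDUI association** — dual criterion per 3'UTR site: Pearson
  correlation of distal polyA usage (PDUI) with regulator expression
  AND a Wilcoxon rank-sum test across a median split, both BH-corrected.
- **CLIP validation** — events extended by 200 bp and intersected with
  CLIP/RIP peak sets; any shared base counts as support.
- **Synthetic data** — seeded generators for every input (genome,
  event tables with planted motif words, isoform TPMs with planted
  dIF, PDUI matrices with planted correlations, CLIP peaks) plus
  machine-readable truth manifests, so the whole pipeline is testable
  without external downloads.

## Worked example

```r
library(spliceRBP)

motifs <- exampleMotifs()             # CA-rich "hnRNPL-like" + controls
cfg <- simulationConfig(
  seed = 7, n_es_events = 120, fraction_regulated = 0.2,
  chrom_length = 2e5, n_apa_genes = 20,
  motif_plant = list(list(motif_id = "CArich_syn",
                          region_kind = "upstream_flank",
                          direction = "exclusion", fg = 0.8, bg = 0.05)))
genome <- simulateGenome(cfg)
sim <- simulateEvents(cfg, genome, motifs)
sim$events
#> SpliceEventSet with 160 events x 6 samples
#> event types: APA=40 ES=120
#> conditions: control/silenced (3/3)

expressed <- filterExpressedEvents(sim$events)   # 148 of 160 kept
sig <- callSignificantEvents(expressed)          # 41 regulated
pool <- selectNullPool(expressed)                # 107 non-regulated

enr <- runEnrichment(sig, pool, motifs["CArich_syn"], sim$genome, seed = 5)
subset(enr, region == "upstream_flank" & direction == "exclusion",
       c(observed, n_regulated, null_mean, null_sd, z, enriched))
#>   observed n_regulated null_mean null_sd        z enriched
#>        6          12      1.12  0.886  5.51     TRUE
```

The CA-rich motif planted in the upstream flanks of exclusion-direction
events comes out strongly enriched (z = 5.5: 6 of 12 regulated flanks
carry a match vs 1.1 +/- 0.9 expected under the resampled null), and no
enrichment is called in exon bodies — the qualitative pattern expected
for an intronic silencer released by the knockdown.

`runPipeline(cfg, out_dir)` chains every stage (simulation, filters,
scanning, enrichment, APA contrast, switching, PDUI association, CLIP
overlap) and writes TSV outputs plus truth manifests and a
`run_metadata.tsv` echoing every threshold; outputs are byte-identical
under a fixed seed. `inst/scripts/run_pipeline.R` is a thin
command-line wrapper.

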