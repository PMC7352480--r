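---
title: "Models and methods behind spliceRBP"
author: "spliceRBP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spliceRBP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceRBP)
```

# The analytical setting

A long non-coding RNA that physically binds a splicing factor acts as
a decoy: knocking the lncRNA down releases the factor and shifts the
splicing decisions of that factor's target pre-mRNAs. The observable
consequences in an RNA-seq contrast of silenced vs control cells are
(i) changed inclusion of cassette exons, (ii) shifted choice among
tandem polyadenylation (APA) sites — hence 3'UTR shortening or
lengthening — and (iii) isoform switching. spliceRBP implements the
inference chain from quantified splicing events to candidate
RNA-binding proteins (RBPs): filter events, extract the sequence
neighborhoods where a regulator would act, scan them with RBP binding
models, and ask whether any motif is over-represented in regulated
events relative to matched non-regulated events.

The package consumes the *outputs* of a splice-graph quantifier (PSI,
&Delta;PSI and a posterior probability per event) and of an isoform
quantifier (TPM); estimating PSI or TPM from reads is out of scope.

# Event filtering

Thresholds follow the conventions of the field and are all strict
inequalities, exposed in `pipelineParams()`:

| step | rule | default |
|---|---|---|
| expression filter | reads &ge; `min_reads` in &ge; `min_samples` samples per condition | 10, 2 |
| significant events | \|&Delta;PSI\| > `dpsi_min` and posterior > `prob_min` | 0.1, 0.9 |
| null pool | \|&Delta;PSI\| < `dpsi_max` and posterior < `prob_max` | 0.01, 0.5 |

Because `dpsi_max <= dpsi_min` and `prob_max <= prob_min`, the
significant set and the null pool are disjoint for any input — a
property the test suite asserts on random tables. The posterior used
by the null-pool rule is the quantifier's posterior probability of
differential splicing; which statistic plays this role is
configurable, since quantifiers differ.

# Scan windows

Windows are defined on the transcript (sense) strand, because RBP
binding is an RNA-side phenomenon: "upstream" means 5' of the exon in
transcription direction, and all sequences from minus-strand events
are reverse-complemented before scanning. Cassette-exon (ES) events
yield three windows — a 200-nt upstream flank, the exon body, and a
200-nt downstream flank. For APA events, the sites of each gene are
sorted by coordinate; the most proximal and most distal (strand-aware)
each receive a 201-nt window (site &plusmn; 100 nt). Genes with more
than two sites keep their intermediate sites labelled but unscanned,
since the proximal/distal dichotomy is the unit of the analysis.
Windows clipped at a chromosome end carry a truncation flag and are
excluded from enrichment so that window lengths stay matched between
regulated and control sets.

The direction of 3'UTR change is derived from the &Delta;PSI signs of
the extreme sites: usage shifting toward the proximal site (proximal
&Delta;PSI > 0, distal < 0) is *shortening*, the mirror pattern is
*lengthening*, and same-sign movement is *ambiguous*. This mapping is
a reconstruction — the anchor case is a gene whose short-3'UTR isoform
gains usage upon silencing, which this rule classifies as shortening.

# Motif scanning with exact p-values

RBP binding models are position probability matrices over {A, C, G, U},
mapped to the DNA alphabet at ingestion. Scores are log-odds in bits,

$$s(i, b) = \log_2 \frac{(1 - 4c)\,p_{ib} + c}{\,q_b\,},$$

with pseudo-probability $c = 10^{-4}$ (RNAcompete-style matrices
contain zeros) and background $q$ (uniform by default; an empirical
background can be supplied). Scores are rounded to integer units of
1/1000 bit; the rounding error is bounded by 1/1000 bit per position
and tested. On the integer scale, the exact distribution of the score
of a random background k-mer is a k-step discrete convolution
(`scoreDistribution()`), and the match threshold for p < 0.001 is the
smallest integer score whose tail mass is at most 0.001
(`pvalueThreshold()`). Motifs too short or degenerate to ever reach a
0.001 tail return a sentinel meaning "no window can match" — e.g. any
3-mer under a uniform background, whose best word already has
probability $4^{-3} > 0.001$. The test suite verifies distribution,
threshold and scanner bin-for-bin against brute-force enumeration of
all $4^k$ words for k up to 8.

Scanning reports every window position at or above the threshold;
windows containing N never match; only the sense strand is scanned.

# Enrichment with a resampled null

For each motif, event type, region kind and direction of regulation
(inclusion: &Delta;PSI > 0.1; exclusion: &Delta;PSI < −0.1), the
observed frequency is the number of regulated regions containing at
least one match. Presence rather than total match count makes the
statistic robust to repeat expansions; total counts are kept as an
auxiliary column. The null reference is 100 control sets, each exactly
as large as the regulated set, drawn without replacement from the same
kind of region in null-pool events; the enrichment z-score divides the
centered observation by the *population* standard deviation of the 100
control frequencies (they are the full reference population, not a
sample from a larger one). A cell is enriched when z > 1.96. When the
null sd is zero the z is 0 for an observation at the null mean and a
signed infinity otherwise.

Two calibration facts shape how results should be read. First, with
100 control sets the z > 1.96 call has a one-sided false-positive rate
above the nominal 2.5% — an exact simulation of the statistic gives
3.8–5.2% depending on the per-region presence rate, because the
without-replacement null slightly underestimates the binomial variance
of the observation and the counts are discrete. At the package's
default problem size (100 regulated and ~1000 null events) the
realized rate is about 4%. Second, the anticonservatism grows as
problem size shrinks; with only ~20 regulated events per cell the rate
reaches ~6%. Interpreting a z barely above 1.96 as strong evidence is
therefore not recommended; the planted-signal benchmarks in the test
suite operate at z around 5–12. No multiple-testing correction is
applied across cells — the fixed 1.96 cutoff is the decision rule, as
is conventional for this statistic.

The shortening-vs-lengthening contrast is a Pearson chi-squared test
(1 df, no continuity correction, raw p) on the 2&times;2 table of
motif presence by direction, counting events; both the continuity
correction and gene-level counting are available as options since
either convention is defensible.

# Isoform switching

Isoform fractions IF = TPM~iso~ / TPM~gene~ are computed per sample
*before* filtering, so &Sigma;IF = 1 per gene and sample is an
invariant (checked to 1e-9); samples with zero gene TPM give missing
fractions excluded from condition means. Genes under 1 TPM (mean, both
conditions) and isoforms under IF 0.01 (both conditions) are then
dropped. dIF = mean IF~silenced~ − mean IF~control~. The significance
test is a per-isoform Welch t test on replicate-level fractions with
BH correction — deliberately simple and documented, since the
replicate-level test behind published switching tools is an internal
detail of those tools; it is swappable. A switch needs q &le; 0.05
*and* |dIF| > 0.1 (strict). Consequences pair the largest-|dIF|
gained and lost isoforms of a gene and compare UTR lengths from
transcript models; differences under 50 nt (annotation jitter) give
no call. All significant up/down pairs are also emitted, so the
pairing heuristic hides nothing.

# PDUI association

Per 3'UTR site, the distal polyA usage index (PDUI, a fraction in
[0,1]) is tested against regulator expression twice: a Pearson
correlation across samples, and a Wilcoxon rank-sum test between the
high and low halves of a median split (samples strictly above the
median are "high"; ties at the median go to low — arbitrary but
fixed). Missing PDUI entries are excluded pairwise; sites with fewer
than 10 usable samples are skipped with a reason code. Both p-value
families are BH-corrected and a site is significant only when both
adjusted values are &le; 0.05 — the dual criterion is by construction
never laxer than either single test. A raw-p mode exists because the
multiplicity treatment of the original two-test design is a
convention choice.

# CLIP overlap

Events are extended by 200 bp on each side and an event is supported
by a study when any peak shares at least one base with the extended
interval (half-open intersection; "coverage greater than zero").
Overlap is strand-agnostic by default because public peak sets mix
strand conventions; a strict-strand mode exists. The sorted
interval-tree implementation is tested against an all-pairs brute
force at 10,000 events &times; 3 peak sets.

# The synthetic-data generators

Every input the pipeline consumes can be generated from a seeded
`simulationConfig()`, whose defaults are the benchmark study
conditions: an i.i.d. genome at GC 0.41; 1100 cassette-exon events of
which 100 are regulated (|&Delta;PSI| ~ N(0.4, 0.05) clipped to
[0.15, 0.85], posterior &ge; 0.95, against a null of |&Delta;PSI| <
0.005 with posterior &le; 0.3); read support that makes a known subset
survive the expression filter; 3 replicates per condition; planted
motif instances as exact words sampled position-wise from the PWM
(not consensus-only, so scanning power is realistic) at 50% of
regulated foreground regions vs 5% background; isoform switches of
dIF 0.3 with replicate IF noise sd 0.02 on a Dirichlet baseline;
3000 PDUI sites of which 10% follow
PDUI = clip~01~(a + 0.1·z(log expr) + &epsilon;) with &epsilon; sd
0.1&radic;3, giving a planted correlation of 0.5 on the standardized
log scale (expression itself is log-normal; standardizing the raw
skewed scale would dilute both the correlation and the median-split
separation); and CLIP peaks covering 80% of regulated events plus
decoys placed away from all events. Where the benchmark left a value
open (GC content, read depth, exon widths, gene/isoform counts,
noise sds) the defaults are one-time choices of realistic magnitudes
for a bulk RNA-seq knockdown design, stated here and not revisited.

Every generator writes a machine-readable truth manifest, and all
generators are pure functions of the config: the same seed gives
byte-identical outputs, with per-stage seeds derived from the global
seed via `stageSeed()` so stages are individually reproducible.

What the generators deliberately do not emulate: genomic sequence
composition beyond i.i.d. bases (no repeats, no dinucleotide
structure), correlated events within genes, mapping biases in read
support, isoform-length effects on TPM, or batch structure. Passing
the planted-signal benchmarks therefore demonstrates correctness of
the statistical machinery under its own assumptions, not robustness
to every artifact of real libraries — the empirical-background option
in the scanner exists precisely because real intronic sequence is not
i.i.d.

# Numerical and engineering choices

Coordinates are 0-based half-open internally (BED convention) and
converted at parser boundaries; GRanges holds them 1-based as usual.
Integer score scaling is 1000 units/bit. Degenerate situations have
fixed documented behavior: zero null sd (signed-infinity z), zero
gene TPM (missing IF), zero replicate variance in the switch test
(p = 1 if means equal, else 0), constant PDUI or one-sided splits
(skipped with reason), chi-squared with a zero margin (error). The
enrichment scan cost is kept linear by scoring all equal-length
windows in one matrix pass per motif column and by precomputing
per-pool-region presence flags once, so the 100 control sets cost no
additional scanning.

Problem sizes in the test suite are the stated study conditions where
a criterion names them (100 regulated / 1000 null events, 50 seeded
enrichment runs, 100 switching runs, 20 PDUI seeds at 3000 sites,
10,000 overlap events) and modest otherwise; the full suite runs in
about ten minutes on one CPU.

# Known limitations

- The enrichment z is anticonservative (~4% one-sided at default
  sizes, worse for small regulated sets); treat marginal calls with
  caution.
- Sense-strand scanning assumes the event tables' strand annotation
  is correct; there is no antisense rescue.
- The switch test assumes approximately normal replicate IFs; with
  2–3 replicates the Welch test is only a screening device.
- UTR-consequence calls depend entirely on the supplied transcript
  models; no novel 3' ends are inferred.
- `classifyApa()` requires consistent strand annotation within a gene
  and at least two sites; single-site genes are either dropped or an
  error, by caller's choice.
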