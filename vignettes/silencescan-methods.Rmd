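---
title: "Methods: detecting rapid maturation-induced transcriptional silencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting rapid maturation-induced transcriptional silencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silencescan)
```

## The scientific problem

When dendritic cells (DCs) encounter a maturation stimulus such as LPS, a
large set of genes is switched off within the first hour — a primary
silencing response that precedes any detectable change in steady-state mRNA,
because mRNA half-lives buffer transcript abundance. Catching this response
therefore requires measuring transcription *rates* (chromatin-bound nascent
transcripts) rather than mRNA, and the chromatin event that accompanies it —
rapid histone-H4 deacetylation over promoters — rather than repressive marks
that appear later.

silencescan implements the full integrative analysis as a tested, reusable
pipeline:

1. **Promoter deacetylation calling** from two-channel tiling-array signals
   (`compute_ratio_track()`, `call_promoters()`).
2. **Transcription-rate classification** from positioned nascent-fraction
   and mRNA-fraction reads (`filter_reads()`, `assign_reads()`,
   `compute_rpkm()`, `classify_change()`).
3. **Integration** of the two into the deacetylated-silenced gene set
   (`integrate_silencing()`).
4. **TSS-centered occupancy profiling** of replicate-consistent
   transcription-factor peaks for each gene set against the all-genes
   baseline (`reproducible_peaks()`, `occupancy_profiles()`).
5. **Promoter motif enrichment** with a Pscan-style z statistic
   (`score_promoters()`, `set_enrichment()`).

Because the analysis targets planted ground truth rather than a downloadable
dataset, the package ships a first-class synthetic-data generator
(`truth_config()`, `simulate_experiment()`) that emulates the statistical
structure of the real inputs; every stage is validated by recovering what
the generator planted.

## Coordinate conventions

All coordinates are 0-based half-open (BED convention) inside the package;
GFF3/GTF input is converted at the file boundary. The TSS is `start` on the
`+` strand and `end - 1` on the `-` strand. Promoter windows are exact
strand mirrors: for a window `upstream`/`downstream` around the TSS, the
`-` strand interval is `[tss - downstream + 1, tss + upstream + 1)`, so its
length is always `upstream + downstream` and reflection symmetry holds
exactly. Genes with multiple annotated transcripts are collapsed to the
exon union with the 5'-most start on the gene strand; the analysis operates
at gene level (one promoter per gene), and alternative-TSS analysis is out
of scope.

## Deacetylation calling

The two-channel model follows the array design: ~50-bp probes whose 5' ends
are ~10 bp apart, tiling each promoter from 3.5 kb upstream to 0.75 kb
downstream of the TSS (421 probes per full window). Per probe we form
`acetylation = log2(iDC/input)` and `deacetylation = log2(iDC/LPS1h)`;
positive deacetylation means the mark was lost on stimulation. Intensities
are floored at 1.0 (a non-positive intensity is an error naming the probe).

The vendor software used on the original arrays does not publish its peak
rule, so the caller is a fully specified sliding-window test, with all three
numbers exposed as arguments:

* window of `win_probes = 5` consecutive probes;
* `decreased` if any window has `min_probes_above = 4` probes with
  deacetylation at or above `threshold_t = 1.0` log2 units;
* `increased` by the mirrored rule on the negated signal;
* score = the extremal qualifying window mean; `peak_offset` = that
  window's midpoint relative to the TSS, strand-aware (upstream negative).

If both directions qualify in one promoter the direction with the larger
absolute window mean wins, with exact ties going to `decreased`. This keeps
the caller exactly antisymmetric under sign flips; note that a
threshold-monotonicity statement ("raising `threshold_t` never grows the
decreased set") holds exactly on one-sided signals and is tested there,
because with two-sided signals the tie-break may flip as thresholds move.
Promoters with fewer than `win_probes` probes are returned `unchanged` and
flagged `insufficient_probes`. Reproducibility across biological replicates
is handled by `consensus_calls()`, which demands the same direction in at
least `min_replicates = 2` replicate call sets.

With the generator's defaults (planted delta 1.5 log2 units over ±500 bp
around the TSS, per-channel log-normal noise of 0.3 log2 units) the
per-probe detection probability is ~0.88, so a 5-probe window passes the
4-of-5 rule with high probability somewhere in the ~100-probe planted
region, while a null promoter needs 4 coincident ~2.4-sigma excursions in
one window — which is why the caller's measured false-positive rate is
essentially zero and its sensitivity near one in the acceptance runs.

## Read filtering, assignment, RPKM and classification

Reads are rejected, in priority order, if they contain non-ACGT characters,
map to more than one genomic location, consist of a mono- or di-nucleotide
tandem repeat covering at least 90% of the read (the repeat filter is named
but not quantified in the field; 90% run coverage is our fixed rule), or
overlap an annotated rRNA locus (residual reads escaping depletion).

Assignment is by full containment: a nascent read counts for a gene if
contained in the gene span (introns and exons — nascent transcripts cover
the whole transcription unit), an mRNA read only if contained in a single
exon. Reads contained in more than one gene are dropped as ambiguous. Read
strand is ignored (library strandedness is not modeled). Fixed-length reads
(default 50 nt) avoid junction ambiguity by construction.

Expression is reported as RPKM — reads per kb of feature length per million
assigned reads — using the span length for the nascent fraction and the
exonic length for the mRNA fraction. The library size is the total of
*assigned genic* reads (a deliberate choice; an explicit `library_size`
argument overrides it). Classification applies strict fold cutoffs to
`r = (rpkm_LPS1h + eps)/(rpkm_untreated + eps)` with `eps = 0.1`
pseudo-RPKM so genes falling to zero reads get a finite fold: a gene is
`induced` at tier *k* if `r > k`, `silenced` if `r < 1/k`, `not_expressed`
if both conditions sit below the 1-RPKM baseline. Tiers 2, 3 and 5 nest by
construction. Strictness at the boundary means an exact 5-fold drop is
silenced at tiers 2 and 3 but *not* at tier 5 — boundary genes are thereby
deterministic.

## Integration

`integrate_silencing()` intersects the promoter calls with the nascent
classification. "Expressed" is anchored to the untreated nascent RPKM
(at least 1 RPKM), matching the immature-cell reference the pie-chart
statistic uses. The summary reports (a) the percent of deacetylated genes
that are expressed and (b) the percent of those with a more-than-2-fold
drop in transcription rate; gene sets at every tier feed the occupancy and
motif stages. The headline percentages from the original study (~4% of
promoters deacetylated, 85% of those expressed, 70% of those silenced)
derive from raw array/sequencing data processed with unpublished vendor
parameters, so they are not reproduction targets here; the synthetic
recovery statistics take their place.

## Peak occupancy profiles

narrowPeak calls are filtered at `p < 1e-5` (strict) and kept only when a
peak overlaps a peak of the other biological replicate by at least 1 nt
(the published wording "overlapping by >1 nt" is ambiguous between >=1 and
>=2; we default to 1 and expose `min_overlap_nt`). The retained record
carries the union interval of the overlapping pair(s). A peak's position is
its summit when present, otherwise the interval midpoint (summits are not
guaranteed in all narrowPeak dialects). For each gene set — and always the
all-genes baseline — the profile reports the percent of genes with at least
one peak position within windows of increasing size centered on the TSS
(monotone in window size by construction, asserted on every run),
strand-aware signed distance bins, and a per-gene binary heat-map matrix
over ±2 kb. `compare_profiles()` adds the set/baseline ratio plus a
two-proportion z-test p-value; the test is descriptive plumbing, not a
statistic from the original analysis.

## Motif enrichment

Motifs are JASPAR-style count matrices. Column probabilities receive a
pseudocount of 1% of the column sum apportioned by the background
composition (uniform by default), giving a finite log2-odds matrix; a
promoter's score for a motif is the best position-and-strand hit, min-max
normalized by the motif's attainable extremes so scores live in [0, 1].
`N` bases score at the background expectation, which keeps promoters
clipped at contig edges (padded with N) in the dense matrix. The scan
window is 450 bp upstream to 50 bp downstream of the TSS. Enrichment of a
gene set against the all-promoters background is
`z = (mean_set - mean_bg) / (sd_bg / sqrt(n_set))` with a one-sided normal
p-value; motifs are called significant at `p < 1e-3` with no multiplicity
correction — the threshold semantics of the published analysis are kept
deliberately. The z of the full background against itself is exactly zero.

The packaged motif file (`inst/extdata/motifs_synthetic.jaspar`) contains
three synthetic matrices — an ETS-core-like motif (GGAA core), an
NF-kB-like motif and a flat decoy — built for this package; they are
labeled synthetic and are not JASPAR entries.

## The synthetic-data generator

`truth_config()` fixes the study conditions; `simulate_experiment()`
produces every input with planted truth. Defaults: 2000 genes on one
synthetic chromosome, span lengths log-uniform 1–20 kb, 40% exonic, 10%
silenced genes with true folds log-uniform 2–100, 10% induced, promoter
deacetylation planted for 90% of silenced genes, sequencing depth 2×10⁶
reads per library, extra-Poisson count noise 0.1, probe noise 0.3 log2
units, TSS-proximal peak probability 0.9 for silenced vs 0.3 otherwise
(position SD 150 bp, replicate jitter SD 20 bp), motif insertion 0.8 vs
0.2.

Design choices the data do not dictate, made once and fixed:

* **Count noise.** Counts are Gamma-Poisson; `nb_dispersion` is the
  *extra-Poisson coefficient of variation* of the per-gene rate
  (`rnbinom` size `1/nb_dispersion^2`), reducing exactly to Poisson at 0.
  At the default 0.1 a 1000-read gene has ~15% total count CV, which is the
  regime in which a 2-fold cutoff separates cleanly.
* **Absolute scale.** The expected count of a gene is
  `rate x length x scale` with the scale calibrated on the *untreated*
  condition, so condition effects move absolute counts (an all-silenced
  4-fold experiment yields a quarter of the reads) instead of being
  renormalized away.
* **Induced folds.** Silenced folds span 2–100 (transcriptional arrest
  covers that range); induced folds default to 2–10. One hour into the
  response induction is still ramping, and bounding the induced mass keeps
  total transcriptional output roughly stable — an assumption per-library
  RPKM normalization leans on. Both ranges are configuration keys.
* **Expression levels.** Basal rates are log-uniform over 1–100 (the real
  distribution is unknown; the range is a knob).
* **Gene spacing.** Inter-gene gaps exceed two upstream window extents so
  each promoter window tiles only its own probes; promoter interference
  between neighbors is deliberately absent from the simulated design.
* **RNG streams.** Every output artifact draws from its own stream derived
  from the master seed by label hashing, so generating or skipping one
  artifact never changes another; identical configs give byte-identical
  outputs.

What the generator does *not* emulate: sequencing errors and quality
scores, paired-end geometry (positioned single reads stand in for aligned
pairs), junction-spanning reads, inter-array normalization artifacts,
GC/mappability bias, and promoters shared between neighboring genes.
Passing the recovery tests therefore demonstrates the pipeline's logic and
statistics, not robustness to every artifact of real array or sequencing
data.

## Problem sizes and numerical behavior

The test suite validates each operation against an independent brute-force
oracle (window enumeration for the caller, all-pairs containment for read
assignment, all-pairs overlap for replicate filtering, exhaustive
position-by-strand scan for motif scores) on instances where the oracle is
exact, and runs end-to-end recovery at the full study scale (2000 genes,
2×10⁶ reads per library) with reduced sizes (hundreds of genes, 10⁴–10⁵
reads) for the seeded property sweeps; the determinism check runs the whole
pipeline twice at 300 genes. One recovery bound sits on a knife edge by
construction: with 10% of genes induced at 2–10-fold, the LPS library
carries ~30% more genic mass, so per-library RPKM shifts every unchanged
gene's observed ratio to ~0.77 and the weakest-expressed tail of unchanged
genes crosses the 2-fold line at close to (and at some seeds just above)
2%. This is a property of plain per-library fold cutoffs under asymmetric
global change, not of the implementation; it is visible in the acceptance
report as `unchanged_mislabel_pct`.

## Known limitations

* The deacetylation caller encodes one specific, fully-documented window
  rule; it is not a reimplementation of any vendor peak caller, and
  percentages obtained on real arrays depend on that unpublished rule.
* Fold classification uses no statistical test (by design, matching the
  published cutoffs); there is no shrinkage or multiple-testing control.
* The two-proportion test in `compare_profiles()` and the normal-theory
  motif p-values are descriptive; gene-gene dependence is not modeled.
* Real-data headline numbers are out of reach without the original raw
  data and vendor parameters; all validation is planted-truth recovery.
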