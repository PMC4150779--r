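# silencescan

Rapid maturation-induced transcriptional silencing in dendritic cells, as
an integrative genomics pipeline.

When dendritic cells meet a maturation stimulus (e.g. LPS), hundreds of
genes are switched off within an hour. Steady-state mRNA profiling misses
this: mRNA half-lives buffer transcript levels long after transcription has
stopped. The silencing response is instead visible in two genome-wide
signals measured together — rapid histone-H4 deacetylation over promoters
(two-channel tiling-array ChIP) and a drop in transcription rate
(chromatin-bound nascent-transcript sequencing). `silencescan` implements
the full analysis that intersects them, for computational biologists who
want each stage as a tested, composable R function:

* **Deacetylation calling** — per-probe `log2(iDC/LPS1h)` ratios, a
  sliding 5-probe window rule (≥4 probes ≥1.0 log2 units, both directions,
  all thresholds exposed), TSS-relative peak offsets, replicate consensus.
* **Transcription-rate classification** — read filtering (repeat, multi-hit
  and rRNA rejection), strict containment assignment (nascent reads to gene
  spans, mRNA reads to single exons), RPKM
  (`count / (length_kb × library_millions)`), and fold tiers: a gene is
  *silenced* at tier *k* if `(rpkm_LPS1h + ε)/(rpkm_untreated + ε) < 1/k`
  (strict; ε = 0.1; tiers 2/3/5; 1-RPKM expression baseline).
* **Integration** — the deacetylated-silenced gene sets and the headline
  fractions (percent of deacetylated genes expressed; percent of those
  silenced >2-fold).
* **Peak occupancy** — narrowPeak significance (`p < 1e-5`) and
  replicate-overlap filtering, then percent of genes with ≥1 peak within
  windows centered on the TSS, per gene set against the all-genes baseline.
* **Motif enrichment** — Pscan-style best-hit PWM scores over the
  −450..+50 promoter window, min-max normalized, and
  `z = (mean_set − mean_bg)/(sd_bg/√n_set)` with significance at
  `p < 1e-3`.
* **A deterministic synthetic-data generator** with planted ground truth
  (`truth_config()`, `simulate_experiment()`), so the whole pipeline is
  testable end to end with no downloads.

## Worked example

Simulate a 300-gene experiment and run every stage:

```r
library(silencescan)

cfg <- truth_config(n_genes = 300, genome_length = 8e6, depth = 2e5,
                    gene_length_range = c(800, 6000), seed = 7)
res <- run_pipeline(cfg)
res
#> <silencing_pipeline>
#>   genes:  300
#> <silencing_integration>
#>   genes integrated:    300
#>   deacetylated:        29
#>   % deac. expressed:   100
#>   % expressed silenced(>2x): 100
```

29 of 300 promoters are called deacetylated (the generator planted
deacetylation on 90% of the ~10% silenced genes); all are expressed above
1 RPKM in untreated cells and all of those drop more than 2-fold in nascent
transcription — the deacetylated-silenced set. Peaks cluster at the TSSs of
exactly that set:

```r
dplyr::filter(res$occupancy_enrichment, window_bp == 1000)
#>                gene_set window_bp percent baseline_percent ratio  p_value
#> 1 deacetylated_silenced      1000    89.7             36.3 2.470 2.48e-08
#> 2               induced      1000    34.6             36.3 0.953 8.61e-01
#> 3             no_change      1000    31.6             36.3 0.868 2.66e-01
```

89.7% of deacetylated-silenced genes have a reproducible peak within ±500 bp
of the TSS versus 36.3% of all genes (ratio 2.47) — the planted 0.9-vs-0.3
site probabilities recovered. The planted ETS-like motif is enriched in the
same set and nowhere else:

```r
dplyr::filter(res$motif_enrichment, gene_set == "deacetylated_silenced_2")
#>      motif_id                gene_set n_set mean_set mean_bg  sd_bg     z        p significant
#> 1   ETS_SYNTH deacetylated_silenced_2    29    0.921   0.878 0.0665 3.480 0.000253        TRUE
#> 2  NFKB_SYNTH deacetylated_silenced_2    29    0.855   0.852 0.0584 0.201 0.420000       FALSE
#> 3 DECOY_SYNTH deacetylated_silenced_2    29    0.979   0.975 0.0221 0.877 0.190000       FALSE
```

`glance(res)` returns the one-row summary, `tidy(res$integration)` the
per-gene table, `write_pipeline(res, "out/")` all stage TSVs, gene-set
files and a markdown report, and `plot_occupancy()`, `plot_expression()`,
`plot_enrichment_heatmap()` the standard figures. See the methods vignette
(`vignettes/silencescan-methods.Rmd`) for the models, parameter choices and
limitations.

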