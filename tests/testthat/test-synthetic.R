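test_that("the generator is fully deterministic given the config", {
  cfg <- small_cfg()
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$genes, b$genes)
  expect_identical(a$truth, b$truth)
  expect_identical(a$probes, b$probes)
  expect_identical(a$reads, b$reads)
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$promoters, b$promoters)
  # and an artifact's stream does not depend on which stages are requested
  only_peaks <- simulate_experiment(cfg, stages = "peaks")
  expect_identical(only_peaks$peaks, a$peaks)
})

test_that("degenerate configs generate valid output", {
  ann0 <- generate_annotation(small_cfg(n_genes = 0))
  expect_equal(nrow(ann0$genes), 0)
  expect_equal(nrow(ann0$truth), 0)
  ann1 <- generate_annotation(small_cfg(exon_fraction = 1))
  expect_true(all(vapply(ann1$genes$exons, nrow, integer(1)) == 1))
  expect_equal(ann1$genes$exonic_length, ann1$genes$end - ann1$genes$start)
})

test_that("generated genes do not overlap and use both strands", {
  ann <- generate_annotation(small_cfg())
  g <- dplyr::arrange(ann$genes, start)
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  expect_setequal(unique(g$strand), c("+", "-"))
  expect_silent(validate_gene_models(ann$genes))
})

test_that("probe tiling matches the array design", {
  cfg <- small_cfg()
  ann <- generate_annotation(cfg)
  probes <- simulate_probe_table(cfg, ann$truth, ann$genes)
  per_gene <- table(sub("_p\\d+$", "", probes$probe_id))
  # window 3500 + 750 = 4250 bp, 50-bp probes every 10 bp -> 421 probes
  expect_true(all(per_gene == 421))
  expect_true(all(probes$end - probes$start == 50))
  one <- probes[sub("_p\\d+$", "", probes$probe_id) == ann$genes$gene_id[1], ]
  expect_equal(sort(unique(diff(sort(one$start)))), 10)
})

test_that("noiseless probes carry exactly the planted deacetylation delta", {
  cfg <- small_cfg(lognormal_sd = 0, deacetylation_delta = 1.5,
                   deacetylation_given_silenced = 1)
  ann <- generate_annotation(cfg)
  probes <- compute_ratio_track(simulate_probe_table(cfg, ann$truth, ann$genes))
  gene_of <- sub("_p\\d+$", "", probes$probe_id)
  mid <- (probes$start + probes$end) / 2
  tss <- ann$genes$tss[match(gene_of, ann$genes$gene_id)]
  deac <- ann$truth$deacetylated[match(gene_of, ann$truth$gene_id)]
  in_reg <- abs(mid - tss) <= cfg$deacetylation_halfwidth
  expect_equal(unique(probes$deacetylation[deac & in_reg]), 1.5)
  expect_equal(unique(probes$deacetylation[!(deac & in_reg)]), 0)
  # silenced genes all deacetylated under probability 1; others never
  expect_true(all(ann$truth$deacetylated[ann$truth$class == "silenced"]))
  expect_false(any(ann$truth$deacetylated[ann$truth$class != "silenced"]))
  # and with probability 0 no promoter has a planted delta
  cfg0 <- small_cfg(lognormal_sd = 0, deacetylation_given_silenced = 0)
  ann0 <- generate_annotation(cfg0)
  probes0 <- compute_ratio_track(simulate_probe_table(cfg0, ann0$truth,
                                                      ann0$genes))
  expect_equal(unique(probes0$deacetylation), 0)
})

test_that("mRNA reads never intersect intronic bases", {
  cfg <- small_cfg()
  ann <- generate_annotation(cfg)
  reads <- simulate_reads(cfg, ann$truth, ann$genes, "mRNA", "untreated")
  asn <- assign_reads(filter_reads(reads, ann$genes)$reads, ann$genes,
                      "mRNA")
  expect_equal(sum(asn$counts$count_intronic), 0)
  # exhaustive: every genic mRNA read is inside a single exon
  for (i in seq_len(nrow(ann$genes))) {
    ex <- ann$genes$exons[[i]]
    g <- ann$genes[i, ]
    inside_gene <- reads$start >= g$start & reads$end <= g$end
    rs <- reads[inside_gene & reads$chrom == g$chrom, ]
    if (nrow(rs) == 0) next
    in_exon <- vapply(seq_len(nrow(rs)), function(r) {
      any(rs$start[r] >= ex[, "start"] & rs$end[r] <= ex[, "end"])
    }, logical(1))
    # reads not in exons of this gene must be spikes placed elsewhere
    expect_true(all(in_exon | !is.na(rs$sequence)))
  }
})

test_that("class, rRNA and low-complexity fractions track the config", {
  cfg <- truth_config(n_genes = 600, genome_length = 1.2e7, depth = 1e5,
                      gene_length_range = c(800, 4000), seed = 55)
  ann <- generate_annotation(cfg)
  n <- nrow(ann$genes)
  binom3 <- function(p, n) 3 * sqrt(p * (1 - p) / n)
  for (cl in names(cfg$class_fractions)) {
    p <- cfg$class_fractions[[cl]]
    expect_lt(abs(mean(ann$truth$class == cl) - p), binom3(p, n) + 2 / n)
  }
  reads <- simulate_reads(cfg, ann$truth, ann$genes, "nascent", "untreated")
  lc <- sum(!is.na(reads$sequence))
  expect_lt(abs(lc / cfg$depth - cfg$lowcomplexity_fraction),
            binom3(cfg$lowcomplexity_fraction, cfg$depth) + 1e-5)
  flog <- filter_reads(reads, ann$genes)$log
  rr <- flog$n[flog$reason == "rRNA"]
  expect_lt(abs(rr / cfg$depth - cfg$rrna_fraction),
            binom3(cfg$rrna_fraction, cfg$depth) + 2e-4)
})

test_that("count ratios converge to the planted fold as dispersion -> 0", {
  cfg <- truth_config(n_genes = 40, genome_length = 1.5e6, depth = 1e6,
                      gene_length_range = c(2000, 8000),
                      class_fractions = c(silenced = 1, induced = 0,
                                          unchanged = 0),
                      fold_range = c(4, 4), nb_dispersion = 0,
                      rrna_fraction = 0, lowcomplexity_fraction = 0,
                      n_rrna_genes = 0, n_mirna_genes = 0, seed = 9)
  ann <- generate_annotation(cfg)
  unt <- assign_reads(simulate_reads(cfg, ann$truth, ann$genes, "nascent",
                                     "untreated"), ann$genes, "nascent")
  lps <- assign_reads(simulate_reads(cfg, ann$truth, ann$genes, "nascent",
                                     "LPS1h"), ann$genes, "nascent")
  ratio <- sum(lps$counts$count) / sum(unt$counts$count)
  expect_lt(abs(ratio - 0.25), 0.01)
})

test_that("peak replicates behave at the jitter and noise extremes", {
  cfg <- small_cfg(peak_jitter_sd = 0, noise_peak_rate = 0)
  ann <- generate_annotation(cfg)
  pk <- simulate_peak_replicates(cfg, ann$truth, ann$genes)
  expect_identical(dplyr::select(pk$rep1, -replicate_id),
                   dplyr::select(pk$rep2, -replicate_id))
  # noise-only config: the replicate-consistent filter retains ~ nothing
  cfg2 <- small_cfg(pu1_site_probability = c(silenced = 0, induced = 0,
                                             unchanged = 0),
                    noise_peak_rate = 0.5, genome_length = 1.6e6)
  ann2 <- generate_annotation(cfg2)
  pk2 <- simulate_peak_replicates(cfg2, ann2$truth, ann2$genes)
  kept <- reproducible_peaks(pk2$rep1, pk2$rep2)
  # ~30 random 200-bp peaks per replicate on 1.6 Mb: expected overlaps < 1
  expect_lte(nrow(kept), 3)
})

test_that("motif planting hits the configured classes and positions", {
  cfg <- small_cfg(motif_insert_probability = c(silenced = 1, induced = 0,
                                                unchanged = 0))
  ann <- generate_annotation(cfg)
  genome <- generate_genome(cfg)
  prom <- extract_promoters(ann$genes, genome)
  expect_true(all(nchar(prom$sequence) == 500))
  motifs <- read_jaspar(system.file("extdata", "motifs_synthetic.jaspar",
                                    package = "silencescan"))
  planted <- plant_motifs(cfg, ann$truth, prom, motifs[1, ])
  sil <- ann$truth$class == "silenced"
  expect_true(all(planted$planted$planted[sil]))
  expect_false(any(planted$planted$planted[!sil]))
  # untouched classes keep their sequence byte for byte
  expect_identical(planted$promoters$sequence[!sil], prom$sequence[!sil])
  # planted promoters score a near-consensus hit
  for (i in head(which(sil), 5)) {
    expect_gt(best_hit_score(motifs[1, ], planted$promoters$sequence[i]),
              best_hit_score(motifs[1, ], prom$sequence[i]) - 1e-9)
  }
  # probability 0 everywhere leaves everything unchanged
  cfg0 <- small_cfg(motif_insert_probability = c(silenced = 0, induced = 0,
                                                 unchanged = 0))
  pl0 <- plant_motifs(cfg0, ann$truth, prom, motifs[1, ])
  expect_identical(pl0$promoters$sequence, prom$sequence)
})

test_that("written simulation files parse back with standard readers", {
  cfg <- small_cfg(n_genes = 12, depth = 2000)
  sim <- simulate_experiment(cfg)
  out <- withr::local_tempdir()
  write_simulation(sim, out)
  g_gff <- read_gene_models(file.path(out, "genes.gff3"), "gff3")
  g_bed <- read_gene_models(file.path(out, "genes.bed12"), "bed12")
  expect_equal(g_gff$start, sim$genes$start)
  expect_equal(g_gff$tss, sim$genes$tss)
  expect_equal(g_bed$end, sim$genes$end)
  reads <- read_read_table(file.path(out, "reads_nascent_untreated.bed"))
  expect_equal(nrow(reads), nrow(sim$reads$nascent_untreated))
  expect_equal(reads$start, sim$reads$nascent_untreated$start)
  pk <- read_narrowpeak(file.path(out, "peaks_rep1.narrowPeak"))
  expect_equal(nrow(pk), nrow(sim$peaks$rep1))
  expect_equal(pk$start, sim$peaks$rep1$start)
  probes <- read_probe_table(file.path(out, "probes.tsv"))
  expect_equal(probes$iDC, sim$probes$iDC)
  cfg2 <- read_truth_config(file.path(out, "config.yaml"))
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(unclass(cfg2)$class_fractions, unclass(cfg)$class_fractions)
})
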