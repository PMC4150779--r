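test_that("significance filtering is strict at the threshold", {
  pk <- make_peaks(c(0, 100, 200), c(50, 150, 250),
                   p = c(1e-6, 1e-5, 2e-5))
  kept <- filter_significant(pk, alpha = 1e-5)
  expect_equal(kept$p_value, 1e-6)  # exactly 1e-5 is dropped
  expect_equal(nrow(filter_significant(pk[0, ])), 0)
  expect_equal(nrow(filter_significant(pk, alpha = 1)), 3)
  bad <- dplyr::mutate(pk, p_value = c(1e-6, NA, 1e-7))
  expect_error(filter_significant(bad), "p_value")
})

test_that("replicate reproducibility keeps >= min_overlap_nt overlaps", {
  a <- make_peaks(100, 200)
  b1 <- make_peaks(199, 300, rep_id = 2L)  # overlap exactly 1
  b2 <- make_peaks(200, 300, rep_id = 2L)  # abutting, overlap 0
  expect_equal(nrow(reproducible_peaks(a, b1, 1)), 1)
  expect_equal(nrow(reproducible_peaks(a, b2, 1)), 0)
  # retained peak carries the union interval of the pair
  m <- reproducible_peaks(a, b1, 1)
  expect_equal(c(m$start, m$end), c(100, 300))
  # identical replicates reproduce the input intervals
  self <- reproducible_peaks(a, dplyr::mutate(a, replicate_id = 2L))
  expect_equal(c(self$start, self$end), c(a$start, a$end))
})

test_that("reproducible_peaks equals the all-pairs brute force", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- 1000
      a <- make_peaks(starts <- sample(0:2e5, n), starts + sample(50:300, n,
                                                                  TRUE))
      b <- make_peaks(starts2 <- sample(0:2e5, n), starts2 + sample(50:300,
                                                                    n, TRUE),
                      rep_id = 2L)
      min_ov <- sample(1:5, 1)
      got <- reproducible_peaks(a, b, min_ov)
      ov <- outer(seq_len(n), seq_len(n), function(i, j) {
        pmax(0, pmin(a$end[i], b$end[j]) - pmax(a$start[i], b$start[j]))
      })
      keep <- which(apply(ov >= min_ov, 1, any))
      expect_equal(got$name, a$name[keep])
      if (length(keep) > 0) {
        exp_start <- vapply(keep, function(i) {
          min(a$start[i], b$start[ov[i, ] >= min_ov])
        }, numeric(1))
        exp_end <- vapply(keep, function(i) {
          max(a$end[i], b$end[ov[i, ] >= min_ov])
        }, numeric(1))
        expect_equal(got$start, exp_start)
        expect_equal(got$end, exp_end)
        expect_equal(got$n_support,
                     unname(apply(ov[keep, , drop = FALSE] >= min_ov, 1,
                                  sum)))
      }
    })
  }
})

test_that("narrowPeak files round-trip through read/write", {
  pk <- make_peaks(c(10, 500), c(210, 700), p = c(1e-8, 1e-3),
                   summit = c(100, NA))
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  write_narrowpeak(pk, f)
  back <- read_narrowpeak(f, replicate_id = 1L)
  expect_equal(back$start, pk$start)
  expect_equal(back$end, pk$end)
  expect_equal(back$p_value, pk$p_value, tolerance = 1e-12)
  expect_equal(back$summit_offset, pk$summit_offset)
})

test_that("occupancy percent matches a hand oracle and is monotone", {
  g <- gene1("G1", 10000, 12000)  # + strand, tss 10000
  pk <- make_peaks(10300, 10501, chrom = "chr1")  # midpoint 10400, +400
  prof <- occupancy_profiles(pk, g, list(set = "G1"),
                             window_sizes = c(500, 1000, 2000))
  wp <- prof$window_percent[prof$window_percent$gene_set == "set", ]
  expect_equal(wp$percent[wp$window_bp == 500], 0)    # 400 > 250
  expect_equal(wp$percent[wp$window_bp == 1000], 100) # 400 <= 500
  expect_equal(wp$percent[wp$window_bp == 2000], 100)
  expect_false(is.unsorted(wp$percent))
  # no peaks -> 0 everywhere
  empty <- occupancy_profiles(pk[0, ], g, list(set = "G1"),
                              window_sizes = c(500, 1000))
  expect_true(all(empty$window_percent$percent == 0))
  expect_error(occupancy_profiles(pk, g, list(set = character())), "empty")
})

test_that("minus-strand distances bin on the transcribed side", {
  # gene on -, tss 10000; a peak at genomic tss - 300 lies downstream (+300)
  g <- gene1("G1", 5000, 10001, strand = "-")
  pk <- make_peaks(9600, 9801, chrom = "chr1")  # midpoint 9700 = tss - 300
  prof <- occupancy_profiles(pk, g, list(set = "G1"), bin_bp = 100)
  db <- prof$distance_bins[prof$distance_bins$gene_set == "set", ]
  expect_equal(db$percent[db$bin_start == 300], 100)
  expect_true(all(db$percent[db$bin_start != 300] == 0))
})

test_that("profiles are invariant under genome reflection + strand flip", {
  L <- 1e6
  for (seed in 1:50) {
    withr::with_seed(seed, {
      n <- 20
      starts <- sort(sample(seq(5000, L - 10000, by = 4000), n))
      strands <- sample(c("+", "-"), n, TRUE)
      genes <- make_genes(tibble::tibble(
        gene_id = sprintf("g%02d", 1:n), chrom = "chrS", strand = strands,
        start = starts, end = starts + 2000,
        exons = lapply(starts, function(s) cbind(s, s + 2000))))
      npk <- 40
      ps <- sample(0:(L - 301), npk)
      pk <- make_peaks(ps, ps + 201)  # odd length: midpoint reflects exactly
      set <- list(set = sample(genes$gene_id, 8))
      prof <- occupancy_profiles(pk, genes, set)
      # reflect: position x -> L - 1 - x; interval [s,e) -> [L-e, L-s)
      genes_r <- genes
      genes_r$start <- L - genes$end
      genes_r$end <- L - genes$start
      genes_r$strand <- ifelse(strands == "+", "-", "+")
      genes_r$tss <- ifelse(genes_r$strand == "+", genes_r$start,
                            genes_r$end - 1)
      genes_r$exons <- lapply(genes$exons,
                              function(e) cbind(start = L - e[, "end"],
                                                end = L - e[, "start"]))
      genes_r$exonic_length <- genes$exonic_length
      pk_r <- pk
      pk_r$start <- L - pk$end
      pk_r$end <- L - pk$start
      prof_r <- occupancy_profiles(pk_r, genes_r, set)
      expect_equal(prof$window_percent$percent,
                   prof_r$window_percent$percent)
      expect_equal(prof$distance_bins$percent, prof_r$distance_bins$percent)
    })
  }
})

test_that("profile comparison reports ratios and degenerate baselines", {
  g <- dplyr::bind_rows(gene1("a", 10000, 12000), gene1("b", 50000, 52000))
  pk <- make_peaks(c(10000, 50000), c(10201, 50201), chrom = "chr1")
  prof <- occupancy_profiles(pk, g, list(set = c("a", "b")),
                             window_sizes = c(1000))
  cmpr <- compare_profiles(prof$window_percent)
  expect_equal(cmpr$ratio, 1)  # the set IS the baseline here
  expect_gt(cmpr$p_value, 0.99)
  # baseline zero -> NA ratio with a note
  prof0 <- occupancy_profiles(pk[0, ], g, list(set = "a"),
                              window_sizes = c(1000))
  expect_message(cmpr0 <- compare_profiles(prof0$window_percent), "NA")
  expect_true(is.na(cmpr0$ratio))
  expect_error(compare_profiles(prof$window_percent[
    prof$window_percent$gene_set == "set", ]), "baseline")
})

test_that("planted TSS-proximal sites are recovered as enrichment", {
  passes <- 0
  for (seed in 1:20) {
    cfg <- truth_config(n_genes = 400, genome_length = 8e6, depth = 1e4,
                        gene_length_range = c(800, 4000), seed = 1000 + seed)
    ann <- generate_annotation(cfg)
    pk <- simulate_peak_replicates(cfg, ann$truth, ann$genes)
    merged <- reproducible_peaks(filter_significant(pk$rep1),
                                 filter_significant(pk$rep2))
    sil <- ann$truth$gene_id[ann$truth$class == "silenced"]
    prof <- occupancy_profiles(merged, ann$genes, list(silenced = sil),
                               window_sizes = c(1000))
    cmpr <- compare_profiles(prof$window_percent)
    if (is.finite(cmpr$ratio) && cmpr$ratio >= 2) passes <- passes + 1
  }
  expect_gte(passes, 19)
})
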