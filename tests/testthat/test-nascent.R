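test_that("the read filter rejects repeats, multi-hits and rRNA reads", {
  rr_gene <- gene1("rrna1", 10000, 12000, biotype = "rRNA")
  reads <- make_reads(
    c(100, 200, 300, 400, 500, 10500),
    sequence = c(strrep("A", 50),              # mono repeat
                 strrep("AC", 25),             # di repeat
                 paste0(strrep("GT", 23), "GTCA"),  # 92% di-repeat covered
                 "ACGTN", NA, NA),
    n_genome_hits = c(1L, 1L, 1L, 1L, 3L, 1L))
  out <- filter_reads(reads, rr_gene)
  lg <- setNames(out$log$n, out$log$reason)
  expect_equal(unname(lg[c("mono_repeat", "di_repeat", "invalid_alphabet",
                           "multi_hit", "rRNA", "kept")]),
               c(1, 2, 1, 1, 1, 0))
  expect_equal(nrow(out$reads), 0)
})

test_that("random unique non-rRNA reads pass the filter untouched", {
  withr::with_seed(41, {
    reads <- make_reads(seq(0, by = 60, length.out = 1000),
                        sequence = random_seq(1000))
    out <- filter_reads(reads)
    expect_equal(nrow(out$reads), 1000)
    expect_equal(sum(out$log$n[out$log$reason != "kept"]), 0)
  })
})

test_that("containment assignment follows the fraction rules", {
  # gene with exons [1000,1500) and [2500,3000); intron between
  g <- gene1("G1", 1000, 3000, exons = cbind(c(1000, 2500), c(1500, 3000)))
  intron_read <- make_reads(1800)
  exon_read <- make_reads(1100)
  boundary_read <- make_reads(1480)  # spans exon/intron boundary
  nas <- function(r) assign_reads(r, g, "nascent")$counts$count
  mrna <- function(r) assign_reads(r, g, "mRNA")$counts$count
  expect_equal(nas(intron_read), 1)
  expect_equal(mrna(intron_read), 0)
  expect_equal(mrna(exon_read), 1)
  expect_equal(mrna(boundary_read), 0)
  expect_equal(nas(boundary_read), 1)
  # intronic/exonic split in nascent mode
  asn <- assign_reads(dplyr::bind_rows(make_reads(c(1800, 1850)), exon_read),
                      g, "nascent")
  expect_equal(asn$counts$count_intronic, 2)
  expect_equal(asn$counts$count_exonic, 1)
})

test_that("reads contained in two genes are ambiguous and dropped", {
  outer <- gene1("outer", 1000, 5000)
  inner <- gene1("inner", 2000, 3000)
  genes <- dplyr::bind_rows(outer, inner)
  asn <- assign_reads(make_reads(2400), genes, "nascent")
  expect_equal(sum(asn$counts$count), 0)
  expect_equal(asn$log$ambiguous, 1)
  # a read in the outer gene only is unambiguous
  asn2 <- assign_reads(make_reads(1200), genes, "nascent")
  expect_equal(asn2$counts$count[asn2$counts$gene_id == "outer"], 1)
})

test_that("assignment equals the quadratic all-pairs containment oracle", {
  withr::with_seed(42, {
    cfg <- small_cfg(n_genes = 30)
    ann <- generate_annotation(cfg)
    reads <- make_reads(sample(0:(1.5e6 - 50), 3000), chrom = "chrS")
    for (fraction in c("nascent", "mRNA")) {
      asn <- assign_reads(reads, ann$genes, fraction)
      brute <- rep(0, nrow(ann$genes))
      hit_genes <- lapply(seq_len(nrow(reads)), function(r) {
        hits <- integer(0)
        for (i in seq_len(nrow(ann$genes))) {
          if (fraction == "nascent") {
            ok <- reads$start[r] >= ann$genes$start[i] &&
              reads$end[r] <= ann$genes$end[i]
          } else {
            ex <- ann$genes$exons[[i]]
            ok <- any(reads$start[r] >= ex[, "start"] &
                        reads$end[r] <= ex[, "end"])
          }
          if (ok) hits <- c(hits, i)
        }
        hits
      })
      for (h in hit_genes) if (length(h) == 1) brute[h] <- brute[h] + 1
      expect_equal(asn$counts$count, brute)
      expect_equal(asn$log$ambiguous,
                   sum(vapply(hit_genes, length, integer(1)) > 1))
    }
  })
})

test_that("RPKM follows the hand formula and its invariances", {
  g <- gene1("G1", 0, 1000)
  counts <- tibble::tibble(gene_id = "G1", count = 100)
  r <- compute_rpkm(counts, g, "nascent", library_size = 1e6)
  expect_equal(r$rpkm, 100)
  g2 <- gene1("G2", 0, 2000)
  r2 <- compute_rpkm(tibble::tibble(gene_id = "G2", count = 50), g2,
                     "nascent", library_size = 5e5)
  expect_equal(r2$rpkm, 50)
  # doubling counts and library leaves RPKM unchanged
  r3 <- compute_rpkm(tibble::tibble(gene_id = "G1", count = 200), g,
                     "nascent", library_size = 2e6)
  expect_equal(r3$rpkm, r$rpkm)
  # mRNA mode uses the exonic length
  gx <- gene1("G3", 0, 4000, exons = cbind(c(0, 3000), c(500, 3500)))
  rx <- compute_rpkm(tibble::tibble(gene_id = "G3", count = 10), gx,
                     "mRNA", library_size = 1e6)
  expect_equal(rx$rpkm, 10 / (1 * 1))
  expect_error(compute_rpkm(counts, g, "nascent", library_size = 0),
               "positive")
})

test_that("RPKM matches the formula on randomized cases to 1e-9", {
  withr::with_seed(43, {
    n <- 1000
    lens <- sample(200:50000, n, replace = TRUE)
    genes <- make_genes(tibble::tibble(
      gene_id = sprintf("g%04d", 1:n), chrom = "chr1", strand = "+",
      start = cumsum(c(0, lens[-n] + 10)),
      end = cumsum(c(0, lens[-n] + 10)) + lens,
      exons = lapply(seq_len(n), function(i) {
        s <- cumsum(c(0, lens[-n] + 10))[i]
        cbind(s, s + lens[i])
      })))
    counts <- tibble::tibble(gene_id = genes$gene_id,
                             count = sample(0:5000, n, replace = TRUE))
    lib <- sum(counts$count)
    r <- compute_rpkm(counts, genes, "nascent")
    expect_equal(r$rpkm, counts$count / ((lens / 1000) * (lib / 1e6)),
                 tolerance = 1e-9)
  })
})

test_that("fold classification respects strict tier boundaries", {
  rec <- function(unt, lps) tibble::tibble(
    gene_id = "g", fraction = "nascent", count_untreated = 1,
    count_LPS1h = 1, rpkm_untreated = unt, rpkm_LPS1h = lps)
  # exact 5-fold drop is NOT silenced at the 5 tier under strict inequality
  x <- classify_change(rec(10, 2), epsilon = 0)
  expect_equal(x$label_2, "silenced")
  expect_equal(x$label_3, "silenced")
  expect_equal(x$label_5, "unchanged")
  expect_equal(x$fold, -5)
  y <- classify_change(rec(0.5, 0.8), epsilon = 0)
  expect_equal(y$label_2, "not_expressed")
  expect_equal(y$status, "not_expressed")
  z <- classify_change(rec(4, 4), epsilon = 0)
  expect_equal(unique(c(z$label_2, z$label_3, z$label_5)), "unchanged")
  # epsilon gives genes falling to zero a finite fold
  w <- classify_change(rec(10, 0), epsilon = 0.1)
  expect_true(is.finite(w$fold))
  expect_equal(w$label_2, "silenced")
})

test_that("tier labels partition, nest and are antisymmetric under swap", {
  withr::with_seed(44, {
    n <- 10000
    expr <- tibble::tibble(
      gene_id = sprintf("g%05d", 1:n), fraction = "nascent",
      count_untreated = 0, count_LPS1h = 0,
      rpkm_untreated = exp(runif(n, log(0.01), log(500))),
      rpkm_LPS1h = exp(runif(n, log(0.01), log(500))))
    cl <- classify_change(expr)
    for (k in c(2, 3, 5)) {
      lab <- cl[[paste0("label_", k)]]
      expect_true(all(lab %in% c("induced", "silenced", "unchanged",
                                 "not_expressed")))
      expect_equal(lab == "not_expressed", cl$status == "not_expressed")
    }
    # nesting: silenced@5 subset of @3 subset of @2, same for induced
    for (lab in c("silenced", "induced")) {
      expect_true(all(which(cl$label_5 == lab) %in% which(cl$label_3 == lab)))
      expect_true(all(which(cl$label_3 == lab) %in% which(cl$label_2 == lab)))
    }
    # swapping the two libraries maps silenced@k <-> induced@k exactly
    swapped <- classify_change(dplyr::mutate(
      expr, rpkm_untreated = expr$rpkm_LPS1h,
      rpkm_LPS1h = expr$rpkm_untreated))
    for (k in c(2, 3, 5)) {
      a <- cl[[paste0("label_", k)]]
      b <- swapped[[paste0("label_", k)]]
      expect_identical(a == "silenced", b == "induced")
      expect_identical(a == "induced", b == "silenced")
    }
  })
})

test_that("library QC reflects the generator's design", {
  cfg <- small_cfg(depth = 3e4)
  ann <- generate_annotation(cfg)
  sim <- simulate_experiment(cfg, stages = c("nascent", "mrna"))
  qn <- quantify_fraction(sim$reads$nascent_untreated,
                          sim$reads$nascent_LPS1h, sim$genes, "nascent")
  qm <- quantify_fraction(sim$reads$mrna_untreated, sim$reads$mrna_LPS1h,
                          sim$genes, "mRNA")
  qc <- nascent_qc(qn$counts$untreated, qm$counts$untreated,
                   qn$filter_logs$untreated, qm$filter_logs$untreated)
  expect_equal(qc$intronic_fraction[qc$library == "mRNA"], 0)
  # nascent intronic fraction tracks the genomic intron fraction
  intron_frac <- 1 - sum(sim$genes$exonic_length) /
    sum(sim$genes$end - sim$genes$start)
  expect_lt(abs(qc$intronic_fraction[qc$library == "nascent"] - intron_frac),
            0.1)
  expect_true(all(qc$intronic_check == "PASS"))
  expect_true(all(qc$rrna_depletion_ok))
})
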