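# Shared fixtures, built in code.

# a small, fast study configuration for unit tests
small_cfg <- function(...) {
  defaults <- list(
    n_genes = 60, genome_length = 1.6e6, gene_length_range = c(800, 4000),
    depth = 2e4, n_rrna_genes = 2, n_mirna_genes = 3, seed = 101)
  do.call(truth_config, utils::modifyList(defaults, list(...)))
}

# hand-built gene table: strand-aware, 0-based half-open, with exons
make_genes <- function(df) {
  rows <- lapply(seq_len(nrow(df)), function(i) {
    ex <- df$exons[[i]]
    exm <- cbind(start = as.numeric(ex[, 1]), end = as.numeric(ex[, 2]))
    tibble::tibble(
      gene_id = df$gene_id[i], chrom = df$chrom[i], strand = df$strand[i],
      start = as.numeric(df$start[i]), end = as.numeric(df$end[i]),
      tss = if (df$strand[i] == "+") as.numeric(df$start[i]) else
        as.numeric(df$end[i]) - 1,
      biotype = if ("biotype" %in% names(df)) df$biotype[i] else
        "protein_coding",
      exons = list(exm))
  })
  g <- dplyr::bind_rows(rows)
  g$exonic_length <- vapply(g$exons,
                            function(e) sum(e[, "end"] - e[, "start"]),
                            numeric(1))
  g
}

# single-exon gene helper
gene1 <- function(id, start, end, strand = "+", chrom = "chr1",
                  biotype = "protein_coding", exons = NULL) {
  make_genes(tibble::tibble(
    gene_id = id, chrom = chrom, strand = strand, start = start, end = end,
    biotype = biotype,
    exons = list(if (is.null(exons)) cbind(start, end) else exons)))
}

# minimal probe tibble over one promoter
make_probes <- function(deac_values, start0 = 1000, step = 10, len = 50,
                        chrom = "chr1", gene = "G1") {
  n <- length(deac_values)
  starts <- start0 + (seq_len(n) - 1) * step
  tibble::tibble(
    probe_id = paste0(gene, "_p", seq_len(n)), chrom = chrom,
    start = starts, end = starts + len,
    iDC = 100, LPS1h = 100 / 2^deac_values, input = 100)
}

# minimal read tibble
make_reads <- function(starts, len = 50, chrom = "chr1", strand = "+",
                       sequence = NA_character_, n_genome_hits = 1L) {
  tibble::tibble(
    read_id = seq_along(starts), chrom = chrom,
    start = as.numeric(starts), end = as.numeric(starts) + len,
    strand = strand, sequence = sequence, n_genome_hits = n_genome_hits)
}

# minimal peak tibble
make_peaks <- function(starts, ends, p = 1e-8, chrom = "chrS",
                       summit = NA_real_, rep_id = 1L) {
  tibble::tibble(
    chrom = chrom, start = as.numeric(starts), end = as.numeric(ends),
    name = paste0("pk", seq_along(starts)), score = 0L, strand = ".",
    signal_value = 1, p_value = rep_len(p, length(starts)),
    q_value = NA_real_, summit_offset = rep_len(summit, length(starts)),
    replicate_id = rep_id)
}

random_seq <- function(n, len = 50) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# brute-force sliding-window caller used as an independent oracle
brute_force_call <- function(x, mids, tss, strand, win = 5, min_above = 4,
                             t = 1.0) {
  n <- length(x)
  if (n < win) return(list(direction = "unchanged", score = NA_real_))
  best <- list(direction = "unchanged", score = NA_real_, offset = NA_real_)
  dec_means <- c(); dec_off <- c(); inc_means <- c(); inc_off <- c()
  for (i in seq_len(n - win + 1)) {
    w <- x[i:(i + win - 1)]
    wm <- mean(w)
    off <- (mids[i] + mids[i + win - 1]) / 2
    if (sum(w >= t) >= min_above) { dec_means <- c(dec_means, wm); dec_off <- c(dec_off, off) }
    if (sum(w <= -t) >= min_above) { inc_means <- c(inc_means, wm); inc_off <- c(inc_off, off) }
  }
  mk_off <- function(o) if (strand == "+") o - tss else tss - o
  if (length(dec_means) && (!length(inc_means) || max(dec_means) >= -min(inc_means))) {
    i <- which.max(dec_means)
    list(direction = "decreased", score = max(dec_means),
         offset = mk_off(dec_off[i]))
  } else if (length(inc_means)) {
    i <- which.min(inc_means)
    list(direction = "increased", score = min(inc_means),
         offset = mk_off(inc_off[i]))
  } else best
}

# independent brute-force motif scan: explicit position x strand enumeration
# with per-position log-odds sums computed from first principles
brute_best_hit <- function(counts, sequence, pf = 0.01, bg = rep(0.25, 4)) {
  L <- ncol(counts)
  n <- colSums(counts)
  lo <- log2(sweep(counts + matrix(bg, 4, L) * rep(pf * n, each = 4), 2,
                   n * (1 + pf), "/") / bg)
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]),
                                      collapse = ""))
  score_at <- function(s, i) {
    sum(vapply(seq_len(L), function(j) {
      b <- substr(s, i + j - 1, i + j - 1)
      if (b == "N") sum(bg * lo[, j]) else
        lo[match(b, c("A", "C", "G", "T")), j]
    }, numeric(1)))
  }
  best <- -Inf
  for (s in c(sequence, revcomp(sequence))) {
    for (i in seq_len(nchar(s) - L + 1)) best <- max(best, score_at(s, i))
  }
  (best - sum(apply(lo, 2, min))) / (sum(apply(lo, 2, max)) -
                                       sum(apply(lo, 2, min)))
}
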