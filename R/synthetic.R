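#' Generate a synthetic gene annotation with planted ground truth
#'
#' Places non-overlapping genes on both strands of a single synthetic
#' chromosome (`chrS`), with log-uniform span lengths, multi-exon structure,
#' and a planted per-gene truth: expression class (silenced / induced /
#' unchanged), true fold change, promoter-deacetylation flag, and a
#' TSS-proximal transcription-factor site flag and position. A few genes are
#' flagged as rRNA loci (targets of the read filter) and microRNA genes
#' (single-exon).
#'
#' @param cfg A [truth_config()].
#' @return A list with `genes` (gene tibble, see [validate_gene_models()])
#'   and `truth` (tibble: `gene_id`, `class`, `true_fold`, `deacetylated`,
#'   `expr_rate`, `has_pu1_site`, `pu1_site_pos`).
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "truth_config"))
  n <- cfg$n_genes
  if (n == 0) {
    genes <- tibble(gene_id = character(), chrom = character(),
                    strand = character(), start = numeric(), end = numeric(),
                    tss = numeric(), biotype = character(),
                    exons = list(), exonic_length = numeric())
    truth <- tibble(gene_id = character(), class = character(),
                    true_fold = numeric(), deacetylated = logical(),
                    expr_rate = numeric(), has_pu1_site = logical(),
                    pu1_site_pos = numeric())
    return(list(genes = genes, truth = truth))
  }
  with_stream(cfg$seed, "annotation", {
    lens <- round(exp(runif(n, log(cfg$gene_length_range[1]),
                            log(cfg$gene_length_range[2]))))
    lens <- pmax(lens, cfg$read_length * 2, cfg$promoter_down + 100)
    # gaps hold two facing promoter windows (a + gene's upstream arm and a
    # - neighbor's) without overlap, so each window tiles only its own probes
    gaps <- round(runif(n, 2 * cfg$promoter_up + 500,
                        2 * cfg$promoter_up + 2000))
    margin <- cfg$promoter_up + 200
    starts <- margin + cumsum(c(0, lens[-n] + gaps[-n]))
    ends <- starts + lens
    if (ends[n] + margin > cfg$genome_length) {
      abort(paste0("cannot place ", n, " genes in ", cfg$genome_length,
                   " bp; increase genome_length"))
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    biotype <- rep("protein_coding", n)
    special <- sample.int(n, min(n, cfg$n_rrna_genes + cfg$n_mirna_genes))
    rrna_idx <- head(special, min(cfg$n_rrna_genes, length(special)))
    mirna_idx <- setdiff(special, rrna_idx)
    biotype[rrna_idx] <- "rRNA"
    biotype[mirna_idx] <- "microRNA"

    exons <- purrr::map(seq_len(n), function(i) {
      if (biotype[i] != "protein_coding") {
        return(exon_matrix(starts[i], ends[i]))  # single-block gene
      }
      make_exon_blocks(starts[i], ends[i], cfg$exon_fraction)
    })

    genes <- tibble(
      gene_id = sprintf("G%04d", seq_len(n)),
      chrom = "chrS", strand = strand,
      start = as.numeric(starts), end = as.numeric(ends),
      tss = ifelse(strand == "+", as.numeric(starts), as.numeric(ends) - 1),
      biotype = biotype, exons = exons)
    genes <- add_exonic_length(genes)
    validate_gene_models(genes)

    cls <- sample(names(cfg$class_fractions), n, replace = TRUE,
                  prob = cfg$class_fractions)
    cls[biotype == "rRNA"] <- "unchanged"  # rRNA loci never carry a planted change
    fold <- rep(1, n)
    sil <- cls == "silenced"
    ind <- cls == "induced"
    fold[sil] <- exp(runif(sum(sil), log(cfg$fold_range[1]),
                           log(cfg$fold_range[2])))
    fold[ind] <- exp(runif(sum(ind), log(cfg$induced_fold_range[1]),
                           log(cfg$induced_fold_range[2])))
    deac <- rep(FALSE, n)
    deac[cls == "silenced"] <-
      runif(sum(cls == "silenced")) < cfg$deacetylation_given_silenced
    expr_rate <- exp(runif(n, log(cfg$expression_range[1]),
                           log(cfg$expression_range[2])))
    p_site <- unname(cfg$pu1_site_probability[cls])
    has_site <- runif(n) < p_site
    site_pos <- round(genes$tss + rnorm(n, 0, cfg$pu1_site_sd))
    site_pos[!has_site] <- NA_real_

    truth <- tibble(
      gene_id = genes$gene_id, class = cls, true_fold = fold,
      deacetylated = deac, expr_rate = expr_rate,
      has_pu1_site = has_site, pu1_site_pos = site_pos)
    list(genes = genes, truth = truth)
  })
}

# Alternating exon/intron blocks: first block is an exon at the span start,
# last exon ends at the span end when introns are present. Exons >= 100 bp so
# fixed-length reads can be fully contained in any exon.
make_exon_blocks <- function(start, end, exon_fraction, min_exon = 100,
                             min_intron = 60) {
  len <- end - start
  exonic <- round(len * exon_fraction)
  if (exon_fraction >= 1 || exonic >= len - min_intron) {
    return(exon_matrix(start, end))
  }
  exonic <- max(exonic, min_exon)
  n_ex <- max(2, min(floor(exonic / min_exon), 1 + rpois(1, len / 4000)))
  intronic <- len - exonic
  n_in <- n_ex - 1
  if (intronic < n_in * min_intron) {
    n_ex <- max(2, floor(intronic / min_intron) + 1)
    n_in <- n_ex - 1
    if (n_in < 1) return(exon_matrix(start, end))
  }
  split_lengths <- function(total, k, minimum) {
    u <- runif(k)
    v <- minimum + floor((total - k * minimum) * u / sum(u))
    v[k] <- total - sum(v[-k])
    v
  }
  ex_len <- split_lengths(exonic, n_ex, min_exon)
  in_len <- split_lengths(intronic, n_in, min_intron)
  block_len <- c(rbind(ex_len, c(in_len, NA)))
  block_len <- block_len[!is.na(block_len)]
  bounds <- start + cumsum(c(0, block_len))
  is_exon <- seq_along(block_len) %% 2 == 1
  exon_matrix(bounds[which(is_exon)], bounds[which(is_exon) + 1])
}

#' Generate the synthetic genome sequence
#'
#' I.i.d. uniform ACGT background over the configured chromosome length.
#' Deterministic given the config seed.
#'
#' @param cfg A [truth_config()].
#' @return A `Biostrings::DNAStringSet` with one sequence named `chrS`.
#' @export
generate_genome <- function(cfg) {
  with_stream(cfg$seed, "genome", {
    codes <- sample.int(4, cfg$genome_length, replace = TRUE)
    s <- intToUtf8(c(65L, 67L, 71L, 84L)[codes])
    Biostrings::DNAStringSet(stats::setNames(s, "chrS"))
  })
}

#' Simulate a two-channel tiling-array probe table
#'
#' Tiles each promoter window (`promoter_up`/`promoter_down` around the TSS)
#' with `probe_length`-bp probes whose 5' ends are `probe_step` bp apart, and
#' simulates three channels: `iDC` (immature-DC H4Ac ChIP), `LPS1h` (1 h
#' LPS-treated ChIP) and `input`. For a gene with planted deacetylation the
#' expected `log2(iDC/LPS1h)` equals `deacetylation_delta` over the
#' subregion within `deacetylation_halfwidth` of the TSS and 0 elsewhere;
#' multiplicative log-normal noise of `lognormal_sd` (log2 units) is applied
#' to every channel independently.
#'
#' @param cfg A [truth_config()].
#' @param truth,genes Output of [generate_annotation()].
#' @param replicate Replicate index (each replicate has its own RNG stream).
#' @return A probe tibble: `probe_id`, `chrom`, `start`, `end`, `iDC`,
#'   `LPS1h`, `input`.
#' @export
simulate_probe_table <- function(cfg, truth, genes, replicate = 1) {
  win <- promoter_window(genes, cfg$promoter_up, cfg$promoter_down)
  wlen <- win$end - win$start
  n_probes <- pmax(0, floor((wlen - cfg$probe_length) / cfg$probe_step) + 1)
  gi <- rep(seq_len(nrow(genes)), n_probes)
  k <- sequence(n_probes)
  start <- win$start[gi] + (k - 1) * cfg$probe_step
  end <- start + cfg$probe_length
  mid <- start + cfg$probe_length / 2
  deac_gene <- truth$deacetylated[match(genes$gene_id, truth$gene_id)]
  in_region <- abs(mid - genes$tss[gi]) <= cfg$deacetylation_halfwidth
  delta <- ifelse(deac_gene[gi] & in_region, cfg$deacetylation_delta, 0)

  with_stream(cfg$seed, paste0("probes_rep", replicate), {
    m <- length(start)
    b <- log2(500)
    acet <- 1  # promoters carry the H4Ac mark in immature cells
    noise <- function() rnorm(m, 0, cfg$lognormal_sd)
    tibble(
      probe_id = paste0(genes$gene_id[gi], "_p", k),
      chrom = genes$chrom[gi],
      start = start, end = end,
      iDC = 2^(b + acet + noise()),
      LPS1h = 2^(b + acet - delta + noise()),
      input = 2^(b + noise()))
  })
}

#' Simulate a positioned-read table for one library
#'
#' Draws per-gene read counts from a Gamma-Poisson model (mean proportional
#' to transcription rate times feature length, extra-Poisson CV
#' `nb_dispersion`), places nascent-fraction reads uniformly over the whole
#' gene span (introns + exons) and mRNA-fraction reads uniformly within
#' single exons, and spikes in residual rRNA-locus reads and mono-/
#' di-nucleotide repeat reads at the configured fractions. In the LPS1h
#' condition the rate of a silenced gene is divided by its true fold and that
#' of an induced gene multiplied by it; mRNA-fraction folds are attenuated to
#' `fold^mrna_attenuation`.
#'
#' @param cfg A [truth_config()].
#' @param truth,genes Output of [generate_annotation()].
#' @param fraction `"nascent"` or `"mRNA"`.
#' @param condition `"untreated"` or `"LPS1h"`.
#' @return A read tibble: `read_id` (integer), `chrom`, `start`, `end`,
#'   `strand`, `sequence` (`NA` except for spiked repeat reads),
#'   `n_genome_hits`.
#' @export
simulate_reads <- function(cfg, truth, genes,
                           fraction = c("nascent", "mRNA"),
                           condition = c("untreated", "LPS1h")) {
  fraction <- match.arg(fraction)
  condition <- match.arg(condition)
  rl <- cfg$read_length
  tr <- truth[match(genes$gene_id, truth$gene_id), ]
  rate <- tr$expr_rate
  if (condition == "LPS1h") {
    f <- tr$true_fold
    if (fraction == "mRNA") f <- f^cfg$mrna_attenuation
    rate <- ifelse(tr$class == "silenced", rate / f,
                   ifelse(tr$class == "induced", rate * f, rate))
  }
  len_eff <- if (fraction == "nascent") genes$end - genes$start else
    genes$exonic_length
  eligible <- genes$biotype != "rRNA" & len_eff >= rl
  w <- rate * len_eff * eligible
  n_spike_rrna <- round(cfg$depth * cfg$rrna_fraction)
  n_spike_lowc <- round(cfg$depth * cfg$lowcomplexity_fraction)
  target <- cfg$depth - n_spike_rrna - n_spike_lowc
  # the count scale is calibrated on the untreated condition, so LPS-induced
  # changes shift absolute counts instead of being renormalized away
  w_unt <- tr$expr_rate * len_eff * eligible
  mu <- if (sum(w_unt) > 0) w / sum(w_unt) * target else rep(0, length(w))

  with_stream(cfg$seed, paste("reads", fraction, condition, sep = "_"), {
    counts <- if (cfg$nb_dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion^2)
    } else {
      rpois(length(mu), mu)
    }
    counts[mu == 0] <- 0L
    gi <- rep(seq_len(nrow(genes)), counts)
    if (fraction == "nascent") {
      starts <- genes$start[gi] +
        floor(runif(length(gi)) * (len_eff[gi] - rl + 1))
    } else {
      starts <- place_in_exons(genes, counts, rl)
    }
    gene_reads <- tibble(chrom = if (length(gi)) genes$chrom[gi] else character(),
                         start = starts,
                         sequence = NA_character_)

    rr_idx <- which(genes$biotype == "rRNA")
    if (length(rr_idx) > 0 && n_spike_rrna > 0) {
      pick <- sample(rr_idx, n_spike_rrna, replace = TRUE,
                     prob = genes$end[rr_idx] - genes$start[rr_idx])
      rr <- tibble(
        chrom = genes$chrom[pick],
        start = genes$start[pick] +
          floor(runif(n_spike_rrna) * (genes$end[pick] - genes$start[pick] - rl + 1)),
        sequence = NA_character_)
    } else rr <- gene_reads[0, ]

    if (n_spike_lowc > 0) {
      units <- c("A", "C", "G", "T", "AC", "AG", "AT", "CA", "CG", "CT",
                 "GA", "GC", "GT", "TA", "TC", "TG")
      u <- sample(units, n_spike_lowc, replace = TRUE)
      lc <- tibble(
        chrom = "chrS",
        start = floor(runif(n_spike_lowc) * (cfg$genome_length - rl)),
        sequence = substr(strrep(u, rl), 1, rl))
    } else lc <- gene_reads[0, ]

    reads <- bind_rows(gene_reads, rr, lc)
    reads$strand <- sample(c("+", "-"), nrow(reads), replace = TRUE)
    tibble(
      read_id = seq_len(nrow(reads)),
      chrom = reads$chrom, start = reads$start, end = reads$start + rl,
      strand = reads$strand, sequence = reads$sequence,
      n_genome_hits = 1L)
  })
}

# uniform placement of fully-exon-contained reads; exons shorter than the
# read contribute nothing
place_in_exons <- function(genes, counts, rl) {
  out <- vector("list", nrow(genes))
  for (i in which(counts > 0)) {
    ex <- genes$exons[[i]]
    wt <- pmax(0, ex[, "end"] - ex[, "start"] - rl + 1)
    if (sum(wt) == 0) {
      out[[i]] <- numeric(0)
      next
    }
    ei <- sample.int(nrow(ex), counts[i], replace = TRUE, prob = wt)
    out[[i]] <- ex[ei, "start"] + floor(runif(counts[i]) * wt[ei])
  }
  unlist(out) %||% numeric(0)
}

#' Simulate two replicate narrowPeak call sets
#'
#' Genes with a planted TSS-proximal site contribute a true peak that appears
#' in both replicates with Gaussian positional jitter (`peak_jitter_sd`) and
#' a shared p-value below 1e-5. Replicate-specific noise peaks (expected
#' `noise_peak_rate` per gene per replicate) appear in only one file with
#' mixed p-values.
#'
#' @param cfg A [truth_config()].
#' @param truth,genes Output of [generate_annotation()].
#' @return A list of two peak tibbles (`rep1`, `rep2`); see
#'   [read_narrowpeak()] for columns.
#' @export
simulate_peak_replicates <- function(cfg, truth, genes) {
  with_stream(cfg$seed, "peaks", {
    site <- truth[!is.na(truth$pu1_site_pos) & truth$has_pu1_site, ]
    half <- 100
    n_true <- nrow(site)
    p_true <- 10^(-runif(n_true, 5.5, 9))  # shared across replicates
    one_rep <- function(r) {
      jit <- round(rnorm(n_true, 0, cfg$peak_jitter_sd))
      start <- pmax(0, site$pu1_site_pos - half + jit)
      true_pk <- tibble(
        chrom = "chrS", start = start, end = start + 2 * half,
        name = paste0(site$gene_id, "_pk"), score = 1000L, strand = ".",
        signal_value = 10, p_value = p_true, q_value = p_true * 10,
        summit_offset = half, replicate_id = r)
      n_noise <- rpois(1, cfg$n_genes * cfg$noise_peak_rate)
      if (n_noise > 0) {
        ns <- floor(runif(n_noise) * (cfg$genome_length - 2 * half))
        noise_pk <- tibble(
          chrom = "chrS", start = ns, end = ns + 2 * half,
          name = sprintf("noise_r%d_%d", r, seq_len(n_noise)),
          score = 200L, strand = ".", signal_value = 2,
          p_value = 10^(-runif(n_noise, 2, 8)),
          q_value = NA_real_, summit_offset = half, replicate_id = r)
      } else noise_pk <- true_pk[0, ]
      arrange(bind_rows(true_pk, noise_pk), start)
    }
    list(rep1 = one_rep(1L), rep2 = one_rep(2L))
  })
}

#' Extract promoter scan windows as sequences
#'
#' Returns, for each gene, the sequence of the window from `upstream_bp`
#' upstream to `downstream_bp` downstream of the TSS, oriented 5' to 3' on
#' the gene strand (so position `upstream_bp + 1` is the TSS base).
#' Positions falling off the chromosome are padded with `N`.
#'
#' @param genes A gene tibble.
#' @param genome A `Biostrings::DNAStringSet` holding the chromosomes.
#' @param upstream_bp,downstream_bp Window extents (defaults: the motif-scan
#'   window, 450 bp upstream to 50 bp downstream).
#' @return A tibble: `gene_id`, `sequence`.
#' @export
extract_promoters <- function(genes, genome, upstream_bp = 450,
                              downstream_bp = 50) {
  wlen <- upstream_bp + downstream_bp
  seqs <- vapply(seq_len(nrow(genes)), function(i) {
    chrom_seq <- genome[[genes$chrom[i]]]
    clen <- length(chrom_seq)
    if (genes$strand[i] == "+") {
      s <- genes$tss[i] - upstream_bp
      e <- genes$tss[i] + downstream_bp  # half-open [s, e)
    } else {
      s <- genes$tss[i] - downstream_bp + 1
      e <- genes$tss[i] + upstream_bp + 1
    }
    lo <- max(s, 0)
    hi <- min(e, clen)
    core <- if (hi > lo) {
      as.character(Biostrings::subseq(chrom_seq, lo + 1, hi))
    } else ""
    pad_l <- lo - s
    pad_r <- e - hi
    seq <- paste0(strrep("N", pad_l), core, strrep("N", pad_r))
    if (genes$strand[i] == "-") {
      seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    }
    seq
  }, character(1))
  stopifnot(all(nchar(seqs) == wlen))
  tibble(gene_id = genes$gene_id, sequence = seqs)
}

#' Plant motif instances into promoter sequences
#'
#' With a per-class probability, inserts one instance of the motif
#' (consensus-sampled column by column from the count matrix, random strand)
#' at a uniform position within each promoter window sequence.
#'
#' @param cfg A [truth_config()] (supplies `motif_insert_probability` and the
#'   seed).
#' @param truth Truth tibble from [generate_annotation()].
#' @param promoters Tibble `gene_id`, `sequence` from [extract_promoters()].
#' @param motif One row of a motif tibble from [read_jaspar()], or a 4 x L
#'   count matrix.
#' @return A list: `promoters` (tibble with planted instances) and `planted`
#'   (tibble: `gene_id`, `planted`, `position` 1-based within the window,
#'   `strand`).
#' @export
plant_motifs <- function(cfg, truth, promoters, motif) {
  counts <- if (is.matrix(motif)) motif else motif$counts[[1]]
  motif_id <- if (is.matrix(motif)) "motif" else motif$motif_id[1]
  L <- ncol(counts)
  if (any(nchar(promoters$sequence) <= L)) {
    abort("motif is not shorter than the promoter window")
  }
  cls <- truth$class[match(promoters$gene_id, truth$gene_id)]
  p_ins <- unname(cfg$motif_insert_probability[cls])
  p_ins[is.na(p_ins)] <- 0
  with_stream(cfg$seed, paste0("plant_", motif_id), {
    n <- nrow(promoters)
    do_ins <- runif(n) < p_ins
    pos <- rep(NA_integer_, n)
    strands <- rep(NA_character_, n)
    seqs <- promoters$sequence
    bases <- rownames(counts) %||% c("A", "C", "G", "T")
    for (i in which(do_ins)) {
      inst <- paste(vapply(seq_len(L), function(j) {
        sample(bases, 1, prob = counts[, j] + 1e-9)
      }, character(1)), collapse = "")
      strands[i] <- sample(c("+", "-"), 1)
      if (strands[i] == "-") {
        inst <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(inst)))
      }
      pos[i] <- sample.int(nchar(seqs[i]) - L + 1, 1)
      substr(seqs[i], pos[i], pos[i] + L - 1) <- inst
    }
    list(
      promoters = tibble(gene_id = promoters$gene_id, sequence = seqs),
      planted = tibble(gene_id = promoters$gene_id, planted = do_ins,
                       position = pos, strand = strands))
  })
}

#' Run the whole generator
#'
#' Produces every input the analysis consumes, with planted ground truth.
#' Each artifact draws from its own seed-derived RNG stream, so the set of
#' requested stages never changes the content of any one of them.
#'
#' @param cfg A [truth_config()].
#' @param stages Character vector of stages to generate, a subset of
#'   `c("probes", "nascent", "mrna", "peaks", "motifs")`. Annotation and
#'   truth are always generated; the genome sequence is generated when
#'   `"motifs"` is requested.
#' @return A list with elements `config`, `genes`, `truth`, and (per stage)
#'   `probes`, `reads` (named list `nascent_untreated`, `nascent_LPS1h`,
#'   `mrna_untreated`, `mrna_LPS1h`), `peaks` (`rep1`/`rep2`), `genome`,
#'   `promoters`, `motifs` (motif tibble), `planted_motif` (planting record).
#' @export
simulate_experiment <- function(cfg,
                                stages = c("probes", "nascent", "mrna",
                                           "peaks", "motifs")) {
  stages <- match.arg(stages, several.ok = TRUE)
  ann <- generate_annotation(cfg)
  sim <- list(config = cfg, genes = ann$genes, truth = ann$truth)
  if ("probes" %in% stages) {
    sim$probes <- simulate_probe_table(cfg, ann$truth, ann$genes)
  }
  reads <- list()
  if ("nascent" %in% stages) {
    reads$nascent_untreated <-
      simulate_reads(cfg, ann$truth, ann$genes, "nascent", "untreated")
    reads$nascent_LPS1h <-
      simulate_reads(cfg, ann$truth, ann$genes, "nascent", "LPS1h")
  }
  if ("mrna" %in% stages) {
    reads$mrna_untreated <-
      simulate_reads(cfg, ann$truth, ann$genes, "mRNA", "untreated")
    reads$mrna_LPS1h <-
      simulate_reads(cfg, ann$truth, ann$genes, "mRNA", "LPS1h")
  }
  if (length(reads)) sim$reads <- reads
  if ("peaks" %in% stages) {
    sim$peaks <- simulate_peak_replicates(cfg, ann$truth, ann$genes)
  }
  if ("motifs" %in% stages && nrow(ann$genes) > 0) {
    sim$genome <- generate_genome(cfg)
    sim$motifs <- read_jaspar(
      system.file("extdata", "motifs_synthetic.jaspar",
                  package = "silencescan"))
    prom <- extract_promoters(ann$genes, sim$genome)
    planted <- plant_motifs(cfg, ann$truth, prom, sim$motifs[1, ])
    sim$promoters <- planted$promoters
    sim$planted_motif <- planted$planted
  }
  sim
}

#' Write a simulated experiment to disk in standard formats
#'
#' Emits the genome FASTA (if generated), GFF3 + BED12 annotation, the probe
#' table TSV, BED6 read tables, two narrowPeak replicate files, the promoter
#' FASTA, the ground-truth TSV and the YAML config.
#'
#' @param sim Output of [simulate_experiment()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_truth_config(sim$config, p("config.yaml"))
  write_gff3(sim$genes, p("genes.gff3"))
  write_gene_models(sim$genes, p("genes.bed12"), "bed12")
  readr::write_tsv(sim$truth, p("truth.tsv"))
  if (!is.null(sim$genome)) {
    Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
  }
  if (!is.null(sim$probes)) readr::write_tsv(sim$probes, p("probes.tsv"))
  for (nm in names(sim$reads)) {
    write_read_table(sim$reads[[nm]], p(paste0("reads_", nm, ".bed")))
  }
  if (!is.null(sim$peaks)) {
    write_narrowpeak(sim$peaks$rep1, p("peaks_rep1.narrowPeak"))
    write_narrowpeak(sim$peaks$rep2, p("peaks_rep2.narrowPeak"))
  }
  if (!is.null(sim$promoters)) {
    writeLines(paste0(">", sim$promoters$gene_id, "\n",
                      sim$promoters$sequence),
               p("promoters.fa"))
  }
  invisible(outdir)
}

write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    lines <- c(lines, sprintf(
      "%s\tsilencescan\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_id=%s;biotype=%s",
      genes$chrom[i], as.integer(genes$start[i]) + 1L,
      as.integer(genes$end[i]), genes$strand[i],
      genes$gene_id[i], genes$gene_id[i], genes$biotype[i]))
    ex <- genes$exons[[i]]
    lines <- c(lines, sprintf(
      "%s\tsilencescan\texon\t%d\t%d\t.\t%s\t.\tParent=%s;gene_id=%s",
      genes$chrom[i], as.integer(ex[, "start"]) + 1L,
      as.integer(ex[, "end"]), genes$strand[i],
      genes$gene_id[i], genes$gene_id[i]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read/write positioned-read tables (BED6 + optional extras)
#'
#' Columns chrom, start, end, name, score, strand, then optional `sequence`
#' and `n_genome_hits`. The score field carries 0.
#'
#' @param reads A read tibble.
#' @param path File path.
#' @return `read_read_table()` returns a read tibble.
#' @export
write_read_table <- function(reads, path) {
  df <- tibble(
    chrom = reads$chrom, start = as.integer(reads$start),
    end = as.integer(reads$end),
    name = paste0("r", reads$read_id), score = 0L, strand = reads$strand,
    sequence = if (!is.null(reads$sequence)) {
      if_else(is.na(reads$sequence), ".", reads$sequence)
    } else ".",
    n_genome_hits = reads$n_genome_hits %||% 1L)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_read_table
#' @export
read_read_table <- function(path) {
  df <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand",
                  "sequence", "n_genome_hits"),
    col_types = "ciicicci", progress = FALSE)
  tibble(
    read_id = seq_len(nrow(df)), chrom = df$chrom,
    start = as.numeric(df$start), end = as.numeric(df$end),
    strand = df$strand,
    sequence = if_else(df$sequence == ".", NA_character_, df$sequence),
    n_genome_hits = df$n_genome_hits %||% 1L)
}

#' Read a probe table TSV
#'
#' Fixed leading columns `probe_id`, `chrom`, `start`, `end`, then one
#' numeric column per channel (channel names in the header).
#'
#' @param path TSV path.
#' @return A probe tibble.
#' @export
read_probe_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("probe_id", "chrom", "start", "end")
  if (!all(need %in% names(df))) {
    abort("probe table must have columns probe_id, chrom, start, end + channels")
  }
  as_tibble(df)
}
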