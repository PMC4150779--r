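#' Filter sequencing reads before gene assignment
#'
#' Rejects reads that (in priority order) contain non-ACGT characters, map
#' to more than one genomic location (`n_genome_hits > 1`), consist of a
#' mono- or di-nucleotide tandem repeat covering at least `repeat_cover` of
#' the read, or overlap an annotated rRNA gene (residual reads escaping
#' rRNA depletion). Reads with no sequence available (pre-counted or
#' position-only mode) skip the sequence checks with a warning.
#'
#' @param reads A read tibble (`read_id`, `chrom`, `start`, `end`, `strand`,
#'   optionally `sequence` and `n_genome_hits`).
#' @param genes Optional gene tibble; when given, reads overlapping `rRNA`
#'   biotype genes by >= 1 bp are rejected.
#' @param repeat_cover Fraction of the read that a single tandem repeat run
#'   must cover to reject it.
#' @return A list: `reads` (kept rows), `log` (tibble `reason`, `n` with
#'   reasons `kept`, `invalid_alphabet`, `multi_hit`, `mono_repeat`,
#'   `di_repeat`, `rRNA`).
#' @export
filter_reads <- function(reads, genes = NULL, repeat_cover = 0.9) {
  n <- nrow(reads)
  reason <- rep("kept", n)
  seqs <- reads$sequence %||% rep(NA_character_, n)
  if (n > 0 && all(is.na(seqs))) {
    warn("reads carry no sequences; repeat/alphabet filters skipped")
  }
  has_seq <- !is.na(seqs)
  bad_alpha <- has_seq & grepl("[^ACGT]", seqs)
  reason[bad_alpha] <- "invalid_alphabet"
  hits <- reads$n_genome_hits %||% rep(1L, n)
  multi <- reason == "kept" & hits > 1
  reason[multi] <- "multi_hit"

  check <- which(reason == "kept" & has_seq)
  if (length(check) > 0) {
    cover <- repeat_run_cover(seqs[check])
    lens <- nchar(seqs[check])
    mono <- cover$mono / lens >= repeat_cover
    di <- !mono & cover$di / lens >= repeat_cover
    reason[check[mono]] <- "mono_repeat"
    reason[check[di]] <- "di_repeat"
  }

  if (!is.null(genes)) {
    rr <- genes[genes$biotype == "rRNA", , drop = FALSE]
    if (nrow(rr) > 0) {
      idx <- which(reason == "kept")
      if (length(idx) > 0) {
        ov <- GenomicRanges::findOverlaps(
          intervals_to_granges(reads[idx, ]),
          genes_to_granges(rr), ignore.strand = TRUE)
        reason[idx[unique(S4Vectors::queryHits(ov))]] <- "rRNA"
      }
    }
  }

  reasons <- c("kept", "invalid_alphabet", "multi_hit", "mono_repeat",
               "di_repeat", "rRNA")
  reason_counts <- vapply(reasons, function(r) sum(reason == r), numeric(1))
  log <- tibble(reason = reasons, n = unname(reason_counts))
  list(reads = reads[reason == "kept", , drop = FALSE], log = log)
}

# longest tandem-repeat run per read, for 1-mer and (heterogeneous) 2-mer
# units; returns covered lengths in bases
repeat_run_cover <- function(seqs) {
  best_run <- function(unit) {
    m <- gregexpr(paste0("(?:", unit, ")+"), seqs, perl = TRUE)
    vapply(m, function(x) {
      ml <- attr(x, "match.length")
      if (length(ml) == 0 || ml[1] < 0) 0L else max(ml)
    }, integer(1))
  }
  mono_units <- c("A", "C", "G", "T")
  di_units <- c("AC", "AG", "AT", "CA", "CG", "CT",
                "GA", "GC", "GT", "TA", "TC", "TG")
  mono <- Reduce(pmax, lapply(mono_units, best_run))
  di <- Reduce(pmax, lapply(di_units, best_run))
  list(mono = mono, di = di)
}

#' Assign reads to genes by full containment
#'
#' In `nascent` mode a read counts for a gene when it is fully contained in
#' the gene span (introns and exons alike -- chromatin-bound primary
#' transcripts cover the whole transcription unit). In `mRNA` mode the read
#' must be fully contained in a single exon. Reads contained in more than
#' one gene are ambiguous and counted for none. Read strand is ignored.
#'
#' @param reads A filtered read tibble.
#' @param genes A gene tibble.
#' @param fraction `"nascent"` or `"mRNA"`.
#' @return A list: `counts` (tibble `gene_id`, `count`, `count_exonic`,
#'   `count_intronic`, one row per gene including zeros) and `log` (tibble
#'   with `assigned`, `ambiguous`, `unassigned` read counts).
#' @export
assign_reads <- function(reads, genes, fraction = c("nascent", "mRNA")) {
  fraction <- match.arg(fraction)
  n <- nrow(reads)
  counts0 <- tibble(gene_id = genes$gene_id, count = 0, count_exonic = 0,
                    count_intronic = 0)
  if (n == 0 || nrow(genes) == 0) {
    return(list(counts = counts0,
                log = tibble(assigned = 0, ambiguous = 0, unassigned = n)))
  }
  read_gr <- intervals_to_granges(reads)
  if (fraction == "nascent") {
    ov <- GenomicRanges::findOverlaps(read_gr, genes_to_granges(genes),
                                      type = "within", ignore.strand = TRUE)
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
  } else {
    ex_gr <- exons_to_granges(genes)
    gene_of_exon <- match(S4Vectors::mcols(ex_gr)$gene_id, genes$gene_id)
    ov <- GenomicRanges::findOverlaps(read_gr, ex_gr, type = "within",
                                      ignore.strand = TRUE)
    q <- S4Vectors::queryHits(ov)
    s <- gene_of_exon[S4Vectors::subjectHits(ov)]
    # a read nested in two exons of the same gene counts once
    dup <- duplicated(paste(q, s))
    q <- q[!dup]
    s <- s[!dup]
  }
  hits_per_read <- tabulate(q, nbins = n)
  n_ambiguous <- sum(hits_per_read > 1)
  keep <- hits_per_read[q] == 1
  q <- q[keep]
  s <- s[keep]
  cnt <- tabulate(s, nbins = nrow(genes))
  exonic <- rep(0L, nrow(genes))
  if (fraction == "nascent" && length(q) > 0) {
    ex_gr <- exons_to_granges(genes)
    gene_of_exon <- match(S4Vectors::mcols(ex_gr)$gene_id, genes$gene_id)
    ov2 <- GenomicRanges::findOverlaps(read_gr[q], ex_gr, type = "within",
                                       ignore.strand = TRUE)
    same_gene <- s[S4Vectors::queryHits(ov2)] ==
      gene_of_exon[S4Vectors::subjectHits(ov2)]
    qe <- unique(S4Vectors::queryHits(ov2)[same_gene])
    exonic <- tabulate(s[qe], nbins = nrow(genes))
  } else if (fraction == "mRNA") {
    exonic <- cnt
  }
  counts <- tibble(gene_id = genes$gene_id, count = as.numeric(cnt),
                   count_exonic = as.numeric(exonic),
                   count_intronic = as.numeric(cnt - exonic))
  list(counts = counts,
       log = tibble(assigned = length(q),
                    ambiguous = n_ambiguous,
                    unassigned = n - length(q) - n_ambiguous))
}

#' Reads per kilobase per million assigned reads
#'
#' `rpkm = count / (length_kb * library_size / 1e6)`. The length is the full
#' gene-span length for the nascent fraction and the exonic length for the
#' mRNA fraction; the library size defaults to the total assigned
#' (genic) reads in the table.
#'
#' @param counts Count tibble from [assign_reads()] (or any tibble with
#'   `gene_id`, `count`).
#' @param genes A gene tibble.
#' @param fraction `"nascent"` or `"mRNA"`.
#' @param library_size Optional explicit library size; must be > 0.
#' @return The count tibble with added `length_bp` and `rpkm`.
#' @export
compute_rpkm <- function(counts, genes, fraction = c("nascent", "mRNA"),
                         library_size = NULL) {
  fraction <- match.arg(fraction)
  library_size <- library_size %||% sum(counts$count)
  if (library_size <= 0) abort("library size must be positive")
  gi <- match(counts$gene_id, genes$gene_id)
  if (anyNA(gi)) abort("counts contain gene_ids absent from the annotation")
  len <- if (fraction == "nascent") genes$end[gi] - genes$start[gi] else
    genes$exonic_length[gi]
  mutate(counts, length_bp = len,
         rpkm = .data$count / ((len / 1000) * (library_size / 1e6)))
}

#' Quantify one fraction across the two conditions
#'
#' Convenience wrapper: filters and assigns both condition libraries,
#' computes RPKM per condition, and returns one expression record per gene.
#'
#' @param reads_untreated,reads_LPS1h Read tibbles for the two conditions.
#' @param genes A gene tibble.
#' @param fraction `"nascent"` or `"mRNA"`.
#' @param filter Apply [filter_reads()] first (default TRUE).
#' @return A list: `expression` (tibble `gene_id`, `fraction`,
#'   `count_untreated`, `count_LPS1h`, `rpkm_untreated`, `rpkm_LPS1h`),
#'   `assign_logs`, `filter_logs`, `counts` (per-condition count tables with
#'   intronic/exonic split).
#' @export
quantify_fraction <- function(reads_untreated, reads_LPS1h, genes,
                              fraction = c("nascent", "mRNA"),
                              filter = TRUE) {
  fraction <- match.arg(fraction)
  prep <- function(reads) {
    if (filter) filter_reads(reads, genes) else
      list(reads = reads, log = NULL)
  }
  f_unt <- prep(reads_untreated)
  f_lps <- prep(reads_LPS1h)
  a_unt <- assign_reads(f_unt$reads, genes, fraction)
  a_lps <- assign_reads(f_lps$reads, genes, fraction)
  r_unt <- compute_rpkm(a_unt$counts, genes, fraction)
  r_lps <- compute_rpkm(a_lps$counts, genes, fraction)
  expression <- tibble(
    gene_id = genes$gene_id, fraction = fraction,
    count_untreated = r_unt$count, count_LPS1h = r_lps$count,
    rpkm_untreated = r_unt$rpkm, rpkm_LPS1h = r_lps$rpkm)
  list(expression = expression,
       assign_logs = list(untreated = a_unt$log, LPS1h = a_lps$log),
       filter_logs = list(untreated = f_unt$log, LPS1h = f_lps$log),
       counts = list(untreated = a_unt$counts, LPS1h = a_lps$counts))
}

#' Classify fold changes into induced / silenced / unchanged tiers
#'
#' A gene is `not_expressed` when both conditions fall below the RPKM
#' baseline. Otherwise the ratio `r = (rpkm_LPS1h + epsilon) /
#' (rpkm_untreated + epsilon)` is thresholded with strict inequalities at
#' each fold tier: `induced` if `r > k`, `silenced` if `r < 1/k`,
#' `unchanged` otherwise. Labels are nested by construction
#' (silenced at 5-fold implies silenced at 3- and 2-fold). The signed fold
#' column is `r` when `r >= 1` and `-1/r` otherwise.
#'
#' @param expression Expression tibble from [quantify_fraction()] (needs
#'   `rpkm_untreated`, `rpkm_LPS1h`).
#' @param baseline Expression baseline in RPKM (default 1).
#' @param tiers Fold-change tiers (default 2, 3, 5).
#' @param epsilon Pseudo-RPKM added to both conditions before the ratio, so
#'   genes dropping to zero reads get a finite fold (default 0.1).
#' @return The input with added `expressed` (untreated RPKM >= baseline),
#'   `status` (`expressed`/`not_expressed`), `fold`, and one `label_<k>`
#'   column per tier with values in
#'   `induced`/`silenced`/`unchanged`/`not_expressed`.
#' @export
classify_change <- function(expression, baseline = 1, tiers = c(2, 3, 5),
                            epsilon = 0.1) {
  r <- (expression$rpkm_LPS1h + epsilon) / (expression$rpkm_untreated + epsilon)
  not_expr <- expression$rpkm_untreated < baseline &
    expression$rpkm_LPS1h < baseline
  out <- mutate(expression,
                expressed = .data$rpkm_untreated >= baseline,
                status = if_else(not_expr, "not_expressed", "expressed"),
                fold = if_else(r >= 1, r, -1 / r))
  for (k in tiers) {
    lab <- if_else(not_expr, "not_expressed",
                   if_else(r > k, "induced",
                           if_else(r < 1 / k, "silenced", "unchanged")))
    out[[paste0("label_", k)]] <- lab
  }
  out
}

#' Library-level quality control for the nascent/mRNA design
#'
#' Reports the intronic fraction of genic reads per library (nascent
#' libraries should be substantially intronic, mRNA libraries exon-only),
#' the pre-filter rRNA read fraction with a >= 95% depletion check, and
#' flags `FAIL` if an mRNA library looks more intronic than its matched
#' nascent library.
#'
#' @param nascent_counts,mrna_counts Count tibbles (with intronic/exonic
#'   split) from [assign_reads()] for matched libraries.
#' @param nascent_filter_log,mrna_filter_log Optional filter logs from
#'   [filter_reads()] for the same libraries (for the rRNA fraction).
#' @return A tibble with one row per library: `library`,
#'   `intronic_fraction`, `rrna_fraction`, `rrna_depletion_ok`,
#'   `intronic_check`.
#' @export
nascent_qc <- function(nascent_counts, mrna_counts,
                       nascent_filter_log = NULL, mrna_filter_log = NULL) {
  ifrac <- function(counts) {
    tot <- sum(counts$count)
    if (tot == 0) NA_real_ else sum(counts$count_intronic) / tot
  }
  rfrac <- function(log) {
    if (is.null(log)) return(NA_real_)
    sum(log$n[log$reason == "rRNA"]) / sum(log$n)
  }
  fi_n <- ifrac(nascent_counts)
  fi_m <- ifrac(mrna_counts)
  fail <- is.finite(fi_n) && is.finite(fi_m) && fi_m > fi_n
  tibble(
    library = c("nascent", "mRNA"),
    intronic_fraction = c(fi_n, fi_m),
    rrna_fraction = c(rfrac(nascent_filter_log), rfrac(mrna_filter_log)),
    rrna_depletion_ok = c(rfrac(nascent_filter_log), rfrac(mrna_filter_log)) <= 0.05,
    intronic_check = if_else(fail, "FAIL", "PASS"))
}
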