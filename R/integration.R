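#' Intersect deacetylation calls with expression classification
#'
#' Produces the deacetylated-silenced gene sets and the headline fractions:
#' (a) the percent of deacetylated genes expressed at or above the RPKM
#' baseline in untreated cells (nascent fraction), and (b) the percent of
#' those expressed genes whose transcription rate drops more than 2-fold
#' after 1 h of LPS. Gene sets at every fold tier are returned for the
#' downstream occupancy and motif analyses.
#'
#' @param calls Promoter calls from [call_promoters()] (or
#'   [consensus_calls()]).
#' @param nascent Classified nascent expression from [classify_change()].
#' @param mrna Optional classified mRNA expression (carried through for the
#'   paired export).
#' @param tiers Fold tiers (must match the classification).
#' @return An object of class `silencing_integration`: a list with `genes`
#'   (one row per gene: flags, labels, memberships), `summary` (one-row
#'   tibble of the headline fractions and set sizes), `sets` (named list of
#'   gene_id vectors: `deacetylated`, `deacetylated_silenced_<k>`,
#'   `induced_<k>`, `no_change`), and `log`.
#' @export
integrate_silencing <- function(calls, nascent, mrna = NULL,
                                tiers = c(2, 3, 5)) {
  lab_cols <- paste0("label_", tiers)
  if (!all(lab_cols %in% names(nascent))) {
    abort("nascent table lacks tier labels; run classify_change() first")
  }
  missing <- setdiff(calls$gene_id, nascent$gene_id)
  if (length(missing) > 0) {
    warn(paste0(length(missing),
                " gene(s) present in calls but absent from the expression",
                " table; excluded"))
  }
  genes <- inner_join(
    select(calls, "gene_id", "direction", dplyr::any_of(c("score", "peak_offset"))),
    select(nascent, "gene_id", "rpkm_untreated", "rpkm_LPS1h", "expressed",
           "fold", dplyr::all_of(lab_cols)),
    by = "gene_id")
  if (!is.null(mrna)) {
    genes <- left_join(
      genes,
      select(mrna, "gene_id", mrna_fold = "fold",
             mrna_label_2 = dplyr::any_of("label_2")),
      by = "gene_id")
  }
  genes <- mutate(genes, deacetylated = .data$direction == "decreased")
  for (k in tiers) {
    genes[[paste0("deacetylated_silenced_", k)]] <-
      genes$deacetylated & genes$expressed &
      genes[[paste0("label_", k)]] == "silenced"
  }
  n_deac <- sum(genes$deacetylated)
  n_deac_expr <- sum(genes$deacetylated & genes$expressed)
  n_ds2 <- sum(genes[[paste0("deacetylated_silenced_", tiers[1])]])
  if (n_deac == 0) {
    inform("no deacetylated genes; headline fractions reported as NA")
  }
  summary <- tibble(
    n_genes = nrow(genes),
    n_deacetylated = n_deac,
    pct_deacetylated_expressed =
      if (n_deac > 0) 100 * n_deac_expr / n_deac else NA_real_,
    pct_expressed_silenced =
      if (n_deac_expr > 0) 100 * n_ds2 / n_deac_expr else NA_real_)
  for (k in tiers) {
    summary[[paste0("n_deacetylated_silenced_", k)]] <-
      sum(genes[[paste0("deacetylated_silenced_", k)]])
    summary[[paste0("n_induced_", k)]] <-
      sum(genes[[paste0("label_", k)]] == "induced")
  }

  sets <- list(deacetylated = genes$gene_id[genes$deacetylated])
  for (k in tiers) {
    sets[[paste0("deacetylated_silenced_", k)]] <-
      genes$gene_id[genes[[paste0("deacetylated_silenced_", k)]]]
    sets[[paste0("induced_", k)]] <-
      genes$gene_id[genes[[paste0("label_", k)]] == "induced"]
  }
  sets$no_change <- genes$gene_id[
    genes[[paste0("label_", tiers[1])]] == "unchanged" & !genes$deacetylated]

  # dot-plot export: genes ordered by their change in nascent transcription
  dotplot <- arrange(
    select(filter(genes, .data$deacetylated), "gene_id", "fold",
           dplyr::any_of("mrna_fold")),
    .data$fold)

  out <- list(genes = genes, summary = summary, sets = sets,
              dotplot = dotplot,
              log = tibble(excluded_from_calls = length(missing)),
              tiers = tiers)
  class(out) <- "silencing_integration"
  out
}

#' @export
print.silencing_integration <- function(x, ...) {
  cat("<silencing_integration>\n")
  cat("  genes integrated:   ", x$summary$n_genes, "\n")
  cat("  deacetylated:       ", x$summary$n_deacetylated, "\n")
  cat("  % deac. expressed:  ",
      format(x$summary$pct_deacetylated_expressed, digits = 3), "\n")
  cat("  % expressed silenced(>", x$tiers[1], "x): ",
      format(x$summary$pct_expressed_silenced, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname integrate_silencing
#' @param x A `silencing_integration` object.
#' @param ... Unused.
#' @export
tidy.silencing_integration <- function(x, ...) as_tibble(x$genes)

#' @rdname integrate_silencing
#' @export
glance.silencing_integration <- function(x, ...) x$summary

#' Paired nascent vs mRNA fold-change comparison
#'
#' Per-gene pairs of nascent and mRNA fold changes, with the count of genes
#' silenced at the given tier in each fraction. After only 1 h of
#' stimulation, steady-state mRNA lags transcription, so substantially more
#' genes drop at the nascent level.
#'
#' @param nascent,mrna Classified expression tibbles from
#'   [classify_change()] over the same genes.
#' @param tier Fold tier to count at (default 2).
#' @return A list: `pairs` (tibble `gene_id`, `nascent_fold`, `mrna_fold`,
#'   `nascent_label`, `mrna_label`) and `counts` (tibble `fraction`,
#'   `n_silenced`, `n_induced`).
#' @export
compare_transcription_vs_mrna <- function(nascent, mrna, tier = 2) {
  lab <- paste0("label_", tier)
  if (!setequal(nascent$gene_id, mrna$gene_id)) {
    abort("nascent and mRNA tables must cover the same genes")
  }
  m <- mrna[match(nascent$gene_id, mrna$gene_id), ]
  pairs <- tibble(
    gene_id = nascent$gene_id,
    nascent_fold = nascent$fold, mrna_fold = m$fold,
    nascent_label = nascent[[lab]], mrna_label = m[[lab]])
  counts <- tibble(
    fraction = c("nascent", "mRNA"),
    n_silenced = c(sum(pairs$nascent_label == "silenced"),
                   sum(pairs$mrna_label == "silenced")),
    n_induced = c(sum(pairs$nascent_label == "induced"),
                  sum(pairs$mrna_label == "induced")))
  list(pairs = pairs, counts = counts)
}

#' Run the full silencing pipeline on a synthetic experiment
#'
#' Orchestrates every stage: generates the configured synthetic experiment,
#' computes ratio tracks and promoter deacetylation calls, quantifies and
#' classifies nascent and mRNA expression, integrates the two into the
#' deacetylated-silenced gene sets, filters and reproducibility-merges the
#' peak replicates and profiles TSS occupancy per gene set, and scores
#' promoter motif enrichment per gene set. Deterministic given the config.
#'
#' @param config A [truth_config()], a YAML path, or a list of
#'   [truth_config()] arguments.
#' @param stages Stages to run (see [simulate_experiment()]).
#' @return An object of class `silencing_pipeline`: a list with `sim`,
#'   `calls`, `array_summary`, `tss_histogram`, `nascent`, `mrna`, `qc`,
#'   `integration`, `fold_comparison`, `peaks` (merged), `occupancy`,
#'   `occupancy_enrichment`, `motif_scores`, `motif_enrichment`,
#'   `motif_heatmap`.
#' @export
run_pipeline <- function(config = truth_config(),
                         stages = c("probes", "nascent", "mrna", "peaks",
                                    "motifs")) {
  cfg <- if (inherits(config, "truth_config")) config
         else if (is.character(config)) read_truth_config(config)
         else do.call(truth_config, config)
  stages <- match.arg(stages, several.ok = TRUE)
  sim <- simulate_experiment(cfg, stages)
  res <- list(config = cfg, sim = sim)

  if (!is.null(sim$probes)) {
    track <- compute_ratio_track(sim$probes)
    res$calls <- call_promoters(track, sim$genes,
                                upstream_bp = cfg$promoter_up,
                                downstream_bp = cfg$promoter_down)
    res$array_summary <- classify_array(res$calls)
    res$tss_histogram <- tss_offset_histogram(
      res$calls, upstream_bp = cfg$promoter_up,
      downstream_bp = cfg$promoter_down)
  }
  if (!is.null(sim$reads$nascent_untreated)) {
    qn <- quantify_fraction(sim$reads$nascent_untreated,
                            sim$reads$nascent_LPS1h, sim$genes, "nascent")
    res$nascent <- classify_change(qn$expression)
    res$nascent_quant <- qn
  }
  if (!is.null(sim$reads$mrna_untreated)) {
    qm <- quantify_fraction(sim$reads$mrna_untreated,
                            sim$reads$mrna_LPS1h, sim$genes, "mRNA")
    res$mrna <- classify_change(qm$expression)
    res$mrna_quant <- qm
  }
  if (!is.null(res$nascent) && !is.null(res$mrna)) {
    res$qc <- nascent_qc(res$nascent_quant$counts$untreated,
                         res$mrna_quant$counts$untreated,
                         res$nascent_quant$filter_logs$untreated,
                         res$mrna_quant$filter_logs$untreated)
    res$fold_comparison <- compare_transcription_vs_mrna(res$nascent,
                                                         res$mrna)
  }
  if (!is.null(res$calls) && !is.null(res$nascent)) {
    res$integration <- integrate_silencing(res$calls, res$nascent, res$mrna)
  }
  if (!is.null(sim$peaks) && !is.null(res$integration)) {
    sig1 <- filter_significant(sim$peaks$rep1)
    sig2 <- filter_significant(sim$peaks$rep2)
    res$peaks <- reproducible_peaks(sig1, sig2)
    sets <- res$integration$sets
    occ_sets <- list(
      deacetylated_silenced = sets$deacetylated_silenced_2,
      induced = sets$induced_2,
      no_change = sets$no_change)
    occ_sets <- occ_sets[vapply(occ_sets, length, integer(1)) > 0]
    if (length(occ_sets) > 0) {
      res$occupancy <- occupancy_profiles(res$peaks, sim$genes, occ_sets)
      res$occupancy_enrichment <- compare_profiles(res$occupancy$window_percent)
    }
  }
  if (!is.null(sim$promoters) && !is.null(res$integration)) {
    res$motif_scores <- score_promoters(sim$motifs, sim$promoters)
    tiers <- res$integration$tiers
    set_names <- c(paste0("induced_", tiers),
                   paste0("deacetylated_silenced_", tiers), "no_change")
    enr <- purrr::map(set_names, function(nm) {
      ids <- res$integration$sets[[nm]]
      if (length(ids) < 2) return(NULL)
      set_enrichment(res$motif_scores, ids, set_label = nm)
    })
    res$motif_enrichment <- bind_rows(enr)
    if (nrow(res$motif_enrichment) > 0) {
      res$motif_heatmap <- enrichment_heatmap(res$motif_enrichment)
    }
  }
  class(res) <- "silencing_pipeline"
  res
}

#' @export
print.silencing_pipeline <- function(x, ...) {
  cat("<silencing_pipeline>\n")
  cat("  genes: ", nrow(x$sim$genes), "\n")
  if (!is.null(x$integration)) print(x$integration)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `silencing_pipeline` object.
#' @param ... Unused.
#' @export
glance.silencing_pipeline <- function(x, ...) {
  out <- tibble(n_genes = nrow(x$sim$genes))
  if (!is.null(x$integration)) out <- bind_cols(select(x$integration$summary, -"n_genes"), out)
  if (!is.null(x$array_summary)) {
    s <- x$array_summary$summary
    out$pct_promoters_decreased <- s$percent[s$direction == "decreased"]
    out$pct_promoters_increased <- s$percent[s$direction == "increased"]
  }
  if (!is.null(x$fold_comparison)) {
    out$n_silenced_nascent <- x$fold_comparison$counts$n_silenced[1]
    out$n_silenced_mrna <- x$fold_comparison$counts$n_silenced[2]
  }
  out
}

#' Write the pipeline's stage artifacts and summary report
#'
#' Emits TSVs for every computed table, gene-set files (one gene_id per
#' line), and a plain-markdown report of the summary tables. Output is
#' byte-deterministic given the pipeline object.
#'
#' @param res A `silencing_pipeline` from [run_pipeline()].
#' @param outdir Output directory.
#' @return `outdir`, invisibly.
#' @export
write_pipeline <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  num <- function(df) mutate(df, across(dplyr::where(is.numeric),
                                        ~ signif(.x, 10)))
  if (!is.null(res$calls)) readr::write_tsv(num(res$calls), p("promoter_calls.tsv"))
  if (!is.null(res$array_summary)) {
    readr::write_tsv(num(res$array_summary$summary), p("array_summary.tsv"))
  }
  if (!is.null(res$tss_histogram)) {
    readr::write_tsv(num(res$tss_histogram), p("tss_offset_histogram.tsv"))
  }
  for (fr in c("nascent", "mrna")) {
    if (!is.null(res[[fr]])) {
      readr::write_tsv(num(res[[fr]]), p(paste0("expression_", fr, ".tsv")))
    }
  }
  if (!is.null(res$integration)) {
    readr::write_tsv(num(res$integration$genes), p("integrated_genes.tsv"))
    readr::write_tsv(num(res$integration$summary), p("integration_summary.tsv"))
    readr::write_tsv(num(res$integration$dotplot), p("dotplot_data.tsv"))
    dir.create(p("gene_sets"), showWarnings = FALSE)
    for (nm in names(res$integration$sets)) {
      writeLines(res$integration$sets[[nm]],
                 p(file.path("gene_sets", paste0(nm, ".txt"))))
    }
  }
  if (!is.null(res$fold_comparison)) {
    readr::write_tsv(num(res$fold_comparison$pairs), p("fold_pairs.tsv"))
    readr::write_tsv(num(res$fold_comparison$counts), p("fold_counts.tsv"))
  }
  if (!is.null(res$qc)) readr::write_tsv(num(res$qc), p("library_qc.tsv"))
  if (!is.null(res$peaks)) write_narrowpeak(res$peaks, p("peaks_merged.narrowPeak"))
  if (!is.null(res$occupancy)) {
    readr::write_tsv(num(res$occupancy$window_percent), p("occupancy_window.tsv"))
    readr::write_tsv(num(res$occupancy$distance_bins), p("occupancy_distance.tsv"))
    hm <- res$occupancy$heatmap[[1]]
    readr::write_tsv(as_tibble(hm, rownames = "gene_id"), p("occupancy_heatmap.tsv"))
  }
  if (!is.null(res$occupancy_enrichment)) {
    readr::write_tsv(num(res$occupancy_enrichment), p("occupancy_enrichment.tsv"))
  }
  if (!is.null(res$motif_enrichment)) {
    readr::write_tsv(num(res$motif_enrichment), p("motif_enrichment.tsv"))
  }
  if (!is.null(res$motif_heatmap)) {
    readr::write_tsv(as_tibble(signif(res$motif_heatmap, 10),
                               rownames = "motif_id"),
                     p("motif_heatmap.tsv"))
  }
  writeLines(pipeline_report_lines(res), p("report.md"))
  invisible(outdir)
}

pipeline_report_lines <- function(res) {
  fmt_tbl <- function(df) {
    c(paste(names(df), collapse = "\t"),
      apply(df, 1, function(r) paste(trimws(format(r, digits = 6)),
                                     collapse = "\t")))
  }
  lines <- c("# silencescan pipeline report", "",
             paste0("genes: ", nrow(res$sim$genes)))
  if (!is.null(res$array_summary)) {
    lines <- c(lines, "", "## Promoter H4-deacetylation calls", "",
               fmt_tbl(res$array_summary$summary))
  }
  if (!is.null(res$integration)) {
    lines <- c(lines, "", "## Integration summary", "",
               fmt_tbl(res$integration$summary))
  }
  if (!is.null(res$fold_comparison)) {
    lines <- c(lines, "", "## Nascent vs mRNA silencing", "",
               fmt_tbl(res$fold_comparison$counts))
  }
  if (!is.null(res$occupancy_enrichment)) {
    lines <- c(lines, "", "## TSS occupancy enrichment", "",
               fmt_tbl(res$occupancy_enrichment))
  }
  if (!is.null(res$motif_enrichment)) {
    lines <- c(lines, "", "## Motif enrichment", "",
               fmt_tbl(select(res$motif_enrichment, "motif_id", "gene_set",
                              "z", "p", "significant")))
  }
  lines
}
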