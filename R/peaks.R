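#' Read / write ENCODE narrowPeak files
#'
#' Ten tab-separated columns: chrom, chromStart, chromEnd, name, score,
#' strand, signalValue, pValue (-log10), qValue (-log10, -1 if absent),
#' peak (summit offset from chromStart, -1 if absent). Internally p- and
#' q-values are carried on the linear scale and the summit offset as `NA`
#' when absent.
#'
#' @param path File path.
#' @param peaks A peak tibble (`chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `signal_value`, `p_value`, `q_value`, `summit_offset`,
#'   optionally `replicate_id`).
#' @param replicate_id Replicate label attached to every peak on read.
#' @return `read_narrowpeak()` returns a peak tibble.
#' @export
read_narrowpeak <- function(path, replicate_id = NA_integer_) {
  df <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand",
                  "signalValue", "pValue", "qValue", "peak"),
    col_types = "ciicicdddi", progress = FALSE)
  tibble(
    chrom = df$chrom, start = as.numeric(df$start), end = as.numeric(df$end),
    name = df$name, score = df$score, strand = df$strand,
    signal_value = df$signalValue,
    p_value = 10^(-df$pValue),
    q_value = if_else(df$qValue < 0, NA_real_, 10^(-df$qValue)),
    summit_offset = if_else(df$peak < 0, NA_real_, as.numeric(df$peak)),
    replicate_id = replicate_id)
}

#' @rdname read_narrowpeak
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- tibble(
    chrom = peaks$chrom, start = as.integer(peaks$start),
    end = as.integer(peaks$end),
    name = peaks$name %||% sprintf("peak_%d", seq_len(nrow(peaks))),
    score = as.integer(peaks$score %||% 0L),
    strand = peaks$strand %||% ".",
    signalValue = peaks$signal_value %||% 0,
    pValue = -log10(peaks$p_value),
    qValue = if_else(is.na(peaks$q_value %||% rep(NA_real_, nrow(peaks))),
                     -1, -log10(peaks$q_value %||% rep(NA_real_, nrow(peaks)))),
    peak = if_else(is.na(peaks$summit_offset %||% rep(NA_real_, nrow(peaks))),
                   -1L, as.integer(peaks$summit_offset %||% -1)))
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Keep peaks below a p-value threshold
#'
#' Strict inequality: a peak at exactly `alpha` is dropped.
#'
#' @param peaks A peak tibble.
#' @param alpha Significance threshold on the linear p-value scale.
#' @return The retained rows.
#' @export
filter_significant <- function(peaks, alpha = 1e-5) {
  if (!"p_value" %in% names(peaks) || anyNA(peaks$p_value)) {
    abort("peaks must carry a complete p_value column")
  }
  peaks[peaks$p_value < alpha, , drop = FALSE]
}

#' Replicate-consistent peaks
#'
#' A replicate-A peak is retained iff some replicate-B peak overlaps it by
#' at least `min_overlap_nt` bases; the retained record carries the union
#' interval of the A peak and all its overlapping B peaks. Both inputs
#' should already be significance-filtered.
#'
#' @param rep_a,rep_b Peak tibbles for the two biological replicates.
#' @param min_overlap_nt Minimum overlap in bases (default 1).
#' @return A peak tibble of retained A peaks with union intervals and an
#'   added `n_support` column (number of overlapping B peaks).
#' @export
reproducible_peaks <- function(rep_a, rep_b, min_overlap_nt = 1) {
  if (nrow(rep_a) == 0 || nrow(rep_b) == 0) {
    return(mutate(rep_a[0, ], n_support = integer()))
  }
  ov <- GenomicRanges::findOverlaps(
    intervals_to_granges(rep_a), intervals_to_granges(rep_b),
    minoverlap = min_overlap_nt)
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  if (length(q) == 0) return(mutate(rep_a[0, ], n_support = integer()))
  keep <- sort(unique(q))
  out <- rep_a[keep, , drop = FALSE]
  min_b <- vapply(keep, function(i) min(rep_b$start[s[q == i]]), numeric(1))
  max_b <- vapply(keep, function(i) max(rep_b$end[s[q == i]]), numeric(1))
  # the summit offset is kept relative to the (possibly extended) start
  if ("summit_offset" %in% names(out)) {
    out$summit_offset <- out$summit_offset + out$start - pmin(out$start, min_b)
  }
  out$start <- pmin(out$start, min_b)
  out$end <- pmax(out$end, max_b)
  out$n_support <- as.integer(tabulate(q, nbins = nrow(rep_a))[keep])
  out
}

peak_positions <- function(peaks) {
  so <- peaks$summit_offset %||% rep(NA_real_, nrow(peaks))
  if_else(is.na(so), floor((peaks$start + peaks$end) / 2), peaks$start + so)
}

#' TSS-centered peak occupancy profiles for gene sets
#'
#' For each gene set (and always the all-genes baseline), computes the
#' percent of genes having at least one peak position within a window of
#' each given size centered on the TSS, plus strand-aware signed-distance
#' bins (upstream negative) and a per-gene binary occupancy heat-map matrix
#' over +-`heatmap_halfwidth` bp. Peak position is the summit when present,
#' otherwise the interval midpoint.
#'
#' @param peaks A peak tibble (typically from [reproducible_peaks()]).
#' @param genes A gene tibble.
#' @param gene_sets Named list of gene_id vectors; each must be a non-empty
#'   subset of `genes$gene_id`.
#' @param window_sizes Window sizes (full widths, bp) for the percent curve.
#' @param bin_bp Bin width for the distance profile and heat map.
#' @param heatmap_halfwidth Half-width of the heat-map window around the TSS.
#' @return A list: `window_percent` (tibble `gene_set`, `window_bp`,
#'   `n_genes`, `n_with_peak`, `percent`), `distance_bins` (tibble
#'   `gene_set`, `bin_start`, `bin_end`, `percent`), `heatmap` (named list
#'   of gene x bin 0/1 matrices).
#' @export
occupancy_profiles <- function(peaks, genes, gene_sets = list(),
                               window_sizes = c(200, 500, 1000, 2000, 4000),
                               bin_bp = 100, heatmap_halfwidth = 2000) {
  for (nm in names(gene_sets)) {
    if (length(gene_sets[[nm]]) == 0) {
      abort(paste0("gene set '", nm, "' is empty"))
    }
    if (!all(gene_sets[[nm]] %in% genes$gene_id)) {
      abort(paste0("gene set '", nm, "' contains unknown gene_ids"))
    }
  }
  sets <- c(gene_sets, list(baseline = genes$gene_id))
  pos <- peak_positions(peaks)
  max_half <- max(c(window_sizes / 2, heatmap_halfwidth))

  # signed strand-aware distances of all peaks within the widest window
  dist_by_gene <- vector("list", nrow(genes))
  if (nrow(peaks) > 0) {
    tss_gr <- GenomicRanges::GRanges(
      genes$chrom,
      IRanges::IRanges(start = pmax(genes$tss - max_half, 0) + 1,
                       end = genes$tss + max_half + 1))
    pk_gr <- GenomicRanges::GRanges(peaks$chrom,
                                    IRanges::IRanges(pos + 1, width = 1))
    ov <- GenomicRanges::findOverlaps(pk_gr, tss_gr)
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
    d <- (pos[q] - genes$tss[s]) * if_else(genes$strand[s] == "+", 1, -1)
    dist_by_gene <- split(d, factor(s, levels = seq_len(nrow(genes))))
  } else {
    dist_by_gene <- rep(list(numeric(0)), nrow(genes))
  }
  names(dist_by_gene) <- genes$gene_id
  min_abs <- vapply(dist_by_gene, function(d) {
    if (length(d) == 0) Inf else min(abs(d))
  }, numeric(1))

  window_percent <- bind_rows(lapply(names(sets), function(nm) {
    ids <- sets[[nm]]
    ma <- min_abs[ids]
    tibble(gene_set = nm, window_bp = sort(window_sizes),
           n_genes = length(ids),
           n_with_peak = vapply(sort(window_sizes),
                                function(w) sum(ma <= w / 2), numeric(1)),
           percent = 100 * vapply(sort(window_sizes),
                                  function(w) mean(ma <= w / 2), numeric(1)))
  }))
  # occupancy must grow with the window; guaranteed by construction, asserted
  stopifnot(all(vapply(split(window_percent$percent,
                             window_percent$gene_set),
                       function(p) !is.unsorted(p), logical(1))))

  edges <- seq(-heatmap_halfwidth, heatmap_halfwidth, by = bin_bp)
  distance_bins <- bind_rows(lapply(names(sets), function(nm) {
    ids <- sets[[nm]]
    dl <- dist_by_gene[ids]
    hit <- vapply(seq_len(length(edges) - 1), function(b) {
      mean(vapply(dl, function(d) {
        any(d >= edges[b] & d < edges[b + 1])
      }, logical(1)))
    }, numeric(1))
    tibble(gene_set = nm, bin_start = edges[-length(edges)],
           bin_end = edges[-1], percent = 100 * hit)
  }))

  heatmap <- lapply(sets, function(ids) {
    m <- t(vapply(dist_by_gene[ids], function(d) {
      as.integer(vapply(seq_len(length(edges) - 1), function(b) {
        any(d >= edges[b] & d < edges[b + 1])
      }, logical(1)))
    }, integer(length(edges) - 1)))
    rownames(m) <- ids
    colnames(m) <- paste0("bin_", edges[-length(edges)])
    m
  })

  list(window_percent = window_percent, distance_bins = distance_bins,
       heatmap = heatmap)
}

#' Compare occupancy profiles against the all-genes baseline
#'
#' Per gene set and window size: the ratio of the set's percent occupancy to
#' the baseline's, and a descriptive two-proportion z-test p-value (no
#' continuity correction). The ratio is `NA` when the baseline percent is 0.
#'
#' @param window_percent The `window_percent` tibble from
#'   [occupancy_profiles()] (must include the `baseline` set).
#' @return A tibble `gene_set`, `window_bp`, `percent`, `baseline_percent`,
#'   `ratio`, `p_value`.
#' @export
compare_profiles <- function(window_percent) {
  if (!"baseline" %in% window_percent$gene_set) {
    abort("window_percent must include the baseline profile")
  }
  base <- window_percent[window_percent$gene_set == "baseline", ]
  rest <- window_percent[window_percent$gene_set != "baseline", ]
  if (nrow(rest) == 0) abort("need at least one gene set besides baseline")
  bi <- match(rest$window_bp, base$window_bp)
  ratio <- if_else(base$percent[bi] > 0, rest$percent / base$percent[bi],
                   NA_real_)
  if (anyNA(ratio)) {
    inform("baseline occupancy is 0 for some window; ratio reported as NA")
  }
  pv <- vapply(seq_len(nrow(rest)), function(i) {
    x <- c(rest$n_with_peak[i], base$n_with_peak[bi[i]])
    n <- c(rest$n_genes[i], base$n_genes[bi[i]])
    if (any(n == 0) || all(x == 0) || all(x == n)) return(1)
    suppressWarnings(prop.test(x, n, correct = FALSE)$p.value)
  }, numeric(1))
  tibble(gene_set = rest$gene_set, window_bp = rest$window_bp,
         percent = rest$percent, baseline_percent = base$percent[bi],
         ratio = ratio, p_value = pv)
}
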