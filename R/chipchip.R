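#' Per-probe log2 ratio tracks from a two-channel probe table
#'
#' Computes, for every probe, the acetylation signal `log2(iDC/input)` and
#' the deacetylation signal `log2(iDC/LPS1h)`. Positive deacetylation means
#' the H4Ac mark was lost upon LPS treatment. Intensities are floored at 1.0
#' before taking ratios; a non-positive intensity is an error (it cannot be
#' floored meaningfully).
#'
#' @param probes A probe tibble with columns `probe_id`, `chrom`, `start`,
#'   `end`, `iDC`, `LPS1h`, `input`.
#' @return The input tibble with added columns `acetylation` and
#'   `deacetylation`, in the input probe order.
#' @export
compute_ratio_track <- function(probes) {
  need <- c("probe_id", "chrom", "start", "end", "iDC", "LPS1h", "input")
  missing <- setdiff(need, names(probes))
  if (length(missing) > 0) {
    abort(paste0("probe table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (ch in c("iDC", "LPS1h", "input")) {
    bad <- which(!is.finite(probes[[ch]]) | probes[[ch]] <= 0)
    if (length(bad) > 0) {
      abort(paste0("non-positive ", ch, " intensity for probe ",
                   probes$probe_id[bad[1]]))
    }
  }
  floor1 <- function(x) pmax(x, 1)
  mutate(probes,
         acetylation = log2(floor1(.data$iDC) / floor1(.data$input)),
         deacetylation = log2(floor1(.data$iDC) / floor1(.data$LPS1h)))
}

#' Call promoter H4-deacetylation with a sliding probe window
#'
#' For each gene, probes whose midpoints fall inside the promoter window are
#' sorted by position and a window of `win_probes` consecutive probes is
#' slid across them. The call is `decreased` if any window holds at least
#' `min_probes_above` probes with deacetylation >= `threshold_t` (the mark
#' was lost), `increased` by the mirrored rule on the negated signal, and
#' `unchanged` otherwise. The score is the extremal qualifying window mean
#' (maximum for `decreased`, minimum for `increased`); `peak_offset` is the
#' signed, strand-aware distance of that window's midpoint from the TSS
#' (upstream negative). If both directions qualify, the one with the larger
#' absolute window mean wins (ties go to `decreased`). Promoters with fewer
#' than `win_probes` probes are returned `unchanged` with status
#' `insufficient_probes`.
#'
#' @param track A ratio track from [compute_ratio_track()].
#' @param genes A gene tibble.
#' @param upstream_bp,downstream_bp Promoter window extents around the TSS
#'   (defaults match the tiling design: 3500 up, 750 down).
#' @param win_probes Probes per sliding window.
#' @param min_probes_above Probes in a window that must clear the threshold.
#' @param threshold_t Per-probe log2 threshold.
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `start`,
#'   `end` (promoter interval), `direction`, `score`, `peak_offset`,
#'   `n_probes`, `status`.
#' @export
call_promoters <- function(track, genes, upstream_bp = 3500,
                           downstream_bp = 750, win_probes = 5,
                           min_probes_above = 4, threshold_t = 1.0) {
  if (!"deacetylation" %in% names(track)) {
    abort("track must carry a deacetylation column; see compute_ratio_track()")
  }
  win <- promoter_window(genes, upstream_bp, downstream_bp)
  mid <- (track$start + track$end) / 2
  # assign probes to promoter windows by midpoint
  probe_gr <- GenomicRanges::GRanges(
    track$chrom, IRanges::IRanges(start = floor(mid) + 1, width = 1))
  win_gr <- GenomicRanges::GRanges(
    win$chrom %||% genes$chrom,
    IRanges::IRanges(start = win$start + 1,
                     end = pmax(win$end, win$start + 1)))
  hits <- GenomicRanges::findOverlaps(probe_gr, win_gr)
  by_gene <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))

  rows <- purrr::map(seq_len(nrow(genes)), function(g) {
    pi <- by_gene[[as.character(g)]]
    base <- tibble(gene_id = genes$gene_id[g], chrom = genes$chrom[g],
                   start = win$start[g], end = win$end[g])
    if (is.null(pi) || length(pi) < win_probes) {
      return(mutate(base, direction = "unchanged", score = NA_real_,
                    peak_offset = NA_real_,
                    n_probes = length(pi %||% integer()),
                    status = "insufficient_probes"))
    }
    pi <- pi[order(mid[pi])]
    x <- track$deacetylation[pi]
    m <- mid[pi]
    sw <- slide_windows(x, win_probes, threshold_t)
    dec_ok <- sw$n_hi >= min_probes_above
    inc_ok <- sw$n_lo >= min_probes_above
    direction <- "unchanged"
    score <- NA_real_
    offs <- NA_real_
    pick <- NA_integer_
    if (any(dec_ok) || any(inc_ok)) {
      best_dec <- if (any(dec_ok)) max(sw$mean[dec_ok]) else -Inf
      best_inc <- if (any(inc_ok)) min(sw$mean[inc_ok]) else Inf
      if (any(dec_ok) && (!any(inc_ok) || best_dec >= -best_inc)) {
        direction <- "decreased"
        score <- best_dec
        pick <- which(dec_ok & sw$mean == best_dec)[1]
      } else {
        direction <- "increased"
        score <- best_inc
        pick <- which(inc_ok & sw$mean == best_inc)[1]
      }
      wmid <- (m[pick] + m[pick + win_probes - 1]) / 2
      offs <- if (genes$strand[g] == "+") wmid - genes$tss[g]
              else genes$tss[g] - wmid
    }
    mutate(base, direction = direction, score = score, peak_offset = offs,
           n_probes = length(pi), status = "ok")
  })
  bind_rows(rows)
}

# windowed counts above/below +-t and running means, via cumulative sums
slide_windows <- function(x, k, t) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  hi <- cumsum(c(0, x >= t))
  lo <- cumsum(c(0, x <= -t))
  i <- seq_len(n - k + 1)
  list(mean = (cs[i + k] - cs[i]) / k,
       n_hi = hi[i + k] - hi[i],
       n_lo = lo[i + k] - lo[i])
}

#' Summarize an array of promoter calls
#'
#' @param calls Output of [call_promoters()], one row per gene.
#' @return A list with `summary` (tibble: `direction`, `n`, `percent`, with
#'   all three directions always present, percentages summing to 100) and
#'   `genes` (named list of gene_id vectors per direction).
#' @export
classify_array <- function(calls) {
  if (anyDuplicated(calls$gene_id) > 0) {
    abort("duplicate gene_id in calls; one call per gene expected")
  }
  dirs <- c("decreased", "increased", "unchanged")
  n <- unname(vapply(dirs, function(d) sum(calls$direction == d),
                     numeric(1)))
  summary <- tibble(direction = dirs, n = n,
                    percent = if (sum(n) > 0) 100 * n / sum(n) else rep(0, 3))
  genes <- lapply(dirs, function(d) calls$gene_id[calls$direction == d])
  names(genes) <- dirs
  list(summary = summary, genes = genes)
}

#' Histogram of deacetylation peak offsets relative to the TSS
#'
#' Bins the strand-aware `peak_offset` of all `decreased` calls over the
#' promoter window (upstream negative). An empty decreased set yields an
#' all-zero histogram.
#'
#' @param calls Output of [call_promoters()].
#' @param bin_bp Bin width, bp.
#' @param upstream_bp,downstream_bp Window extents the offsets live in.
#' @return A tibble: `bin_start`, `bin_end`, `n`, covering
#'   `[-upstream_bp, downstream_bp]`; `sum(n)` equals the number of
#'   decreased calls with a finite offset.
#' @export
tss_offset_histogram <- function(calls, bin_bp = 250, upstream_bp = 3500,
                                 downstream_bp = 750) {
  offs <- calls$peak_offset[calls$direction == "decreased"]
  offs <- offs[is.finite(offs)]
  edges <- seq(-upstream_bp, downstream_bp + bin_bp, by = bin_bp)
  counts <- vapply(seq_len(length(edges) - 1), function(i) {
    sum(offs >= edges[i] & offs < edges[i + 1])
  }, numeric(1))
  tibble(bin_start = edges[-length(edges)], bin_end = edges[-1], n = counts)
}

#' Replicate-consistent consensus of promoter calls
#'
#' A gene is called `decreased` (or `increased`) only if at least
#' `min_replicates` replicate call sets agree on that direction; otherwise
#' `unchanged`. This encodes the requirement that deacetylation be strong
#' and reproducible across biological replicates.
#'
#' @param call_list A list of call tibbles from [call_promoters()], one per
#'   replicate, over the same genes.
#' @param min_replicates Minimum number of agreeing replicates.
#' @return A call tibble with consensus `direction` and, per gene, the mean
#'   `score` and `peak_offset` over the agreeing replicates.
#' @export
consensus_calls <- function(call_list, min_replicates = 2) {
  stopifnot(length(call_list) >= 1)
  ids <- call_list[[1]]$gene_id
  for (cl in call_list) {
    if (!identical(sort(cl$gene_id), sort(ids))) {
      abort("replicate call sets cover different genes")
    }
  }
  aligned <- lapply(call_list, function(cl) cl[match(ids, cl$gene_id), ])
  dirs <- vapply(aligned, function(cl) cl$direction, character(length(ids)))
  dirs <- matrix(dirs, nrow = length(ids))
  pick_dir <- function(i) {
    for (d in c("decreased", "increased")) {
      if (sum(dirs[i, ] == d) >= min_replicates) return(d)
    }
    "unchanged"
  }
  direction <- vapply(seq_along(ids), pick_dir, character(1))
  agree_stat <- function(i, col) {
    if (direction[i] == "unchanged") return(NA_real_)
    v <- vapply(aligned, function(cl) cl[[col]][i], numeric(1))
    mean(v[dirs[i, ] == direction[i]])
  }
  tibble(
    gene_id = ids,
    chrom = aligned[[1]]$chrom,
    start = aligned[[1]]$start, end = aligned[[1]]$end,
    direction = direction,
    score = vapply(seq_along(ids), agree_stat, numeric(1), col = "score"),
    peak_offset = vapply(seq_along(ids), agree_stat, numeric(1),
                         col = "peak_offset"),
    n_probes = aligned[[1]]$n_probes,
    status = aligned[[1]]$status)
}
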