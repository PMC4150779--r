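#' Read JASPAR-style count matrices
#'
#' Parses the JASPAR 2014 text format: a `>ID name` header followed by four
#' rows, either `A [ 4 19 0 ... ]` or four bare whitespace-separated count
#' rows in A, C, G, T order.
#'
#' @param path Path to the motif file.
#' @return A motif tibble: `motif_id`, `name`, `length`, `counts`
#'   (list-column of 4 x L matrices with rownames A, C, G, T).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  idx <- grep("^>", lines)
  if (length(idx) == 0) abort(paste0("no '>' headers found in ", path))
  rows <- purrr::map(seq_along(idx), function(i) {
    from <- idx[i] + 1
    to <- if (i < length(idx)) idx[i + 1] - 1 else length(lines)
    header <- sub("^>\\s*", "", lines[idx[i]])
    parts <- strsplit(header, "\\s+")[[1]]
    body <- lines[from:to]
    if (length(body) < 4) abort(paste0("motif ", parts[1], ": expected 4 rows"))
    parse_row <- function(ln) {
      ln <- sub("^\\s*[ACGTacgt]\\s*", "", ln)
      ln <- gsub("[][]", " ", ln)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    }
    m <- do.call(rbind, lapply(body[1:4], parse_row))
    if (any(is.na(m)) || nrow(m) != 4) {
      abort(paste0("motif ", parts[1], ": malformed count rows"))
    }
    rownames(m) <- c("A", "C", "G", "T")
    if (ncol(m) < 4) abort(paste0("motif ", parts[1], ": length must be >= 4"))
    if (any(colSums(m) <= 0)) {
      abort(paste0("motif ", parts[1], ": zero column sum"))
    }
    tibble(motif_id = parts[1],
           name = if (length(parts) > 1) parts[2] else parts[1],
           length = ncol(m), counts = list(m))
  })
  out <- bind_rows(rows)
  if (anyDuplicated(out$motif_id) > 0) abort("duplicate motif ids")
  out
}

#' Log-odds scoring matrix from a count matrix
#'
#' Column-wise probabilities with a pseudocount of `pseudocount_frac` times
#' the column sum, apportioned by the background composition, scored as
#' `log2(p / background)`. Also returns the attainable per-position score
#' extremes used for min-max normalization, and the expected column scores
#' used for `N` bases.
#'
#' @param counts A 4 x L count matrix (rows A, C, G, T).
#' @param background Base composition (length-4, sums to 1).
#' @param pseudocount_frac Pseudocount as a fraction of each column sum.
#' @return A list: `lo` (4 x L log-odds), `s_min`, `s_max`, `expected`
#'   (length-L expected score under the background).
#' @export
motif_logodds <- function(counts, background = rep(0.25, 4),
                          pseudocount_frac = 0.01) {
  stopifnot(nrow(counts) == 4, all(background > 0),
            abs(sum(background) - 1) < 1e-8)
  n <- colSums(counts)
  pc <- matrix(background, 4, ncol(counts)) *
    rep(pseudocount_frac * n, each = 4)
  p <- (counts + pc) / rep(n * (1 + pseudocount_frac), each = 4)
  lo <- log2(p / background)
  list(lo = lo,
       s_min = sum(apply(lo, 2, min)),
       s_max = sum(apply(lo, 2, max)),
       expected = colSums(lo * background))
}

encode_dna <- function(seqs) {
  # A,C,G,T -> 1..4; anything else (N) -> 5
  lapply(strsplit(toupper(seqs), ""), function(ch) {
    code <- match(ch, c("A", "C", "G", "T"))
    code[is.na(code)] <- 5L
    code
  })
}

revcomp_logodds <- function(m) {
  # scoring the reverse strand == scoring the reverse-complemented matrix
  lo <- m$lo[4:1, ncol(m$lo):1, drop = FALSE]
  rownames(lo) <- c("A", "C", "G", "T")
  list(lo = lo, s_min = m$s_min, s_max = m$s_max,
       expected = rev(m$expected))
}

scan_one_strand <- function(code, m) {
  L <- ncol(m$lo)
  np <- length(code) - L + 1
  if (np < 1) return(numeric(0))
  s <- numeric(np)
  for (j in seq_len(L)) {
    col <- c(m$lo[, j], m$expected[j])  # 5th entry scores N at background
    s <- s + col[code[j:(j + np - 1)]]
  }
  s
}

#' Best min-max-normalized motif hit in a sequence
#'
#' Scores every position on both strands with the motif's log-odds matrix,
#' takes the maximum, and normalizes it to `[0, 1]` by the motif's
#' attainable extremes: `(s - s_min) / (s_max - s_min)`. `N` bases score at
#' the background expectation.
#'
#' @param motif One row of a motif tibble from [read_jaspar()], a 4 x L
#'   count matrix, or a prebuilt [motif_logodds()] object.
#' @param sequence A single character sequence, length >= motif length.
#' @param background,pseudocount_frac Passed to [motif_logodds()] when
#'   `motif` is a count matrix.
#' @return The normalized best-hit score in `[0, 1]`.
#' @export
best_hit_score <- function(motif, sequence, background = rep(0.25, 4),
                           pseudocount_frac = 0.01) {
  m <- as_logodds(motif, background, pseudocount_frac)
  L <- ncol(m$lo)
  if (nchar(sequence) < L) {
    abort("sequence is shorter than the motif")
  }
  code <- encode_dna(sequence)[[1]]
  s <- max(scan_one_strand(code, m),
           scan_one_strand(code, revcomp_logodds(m)))
  (s - m$s_min) / (m$s_max - m$s_min)
}

as_logodds <- function(motif, background, pseudocount_frac) {
  if (is.list(motif) && !is.data.frame(motif) && all(c("lo", "s_min") %in% names(motif))) {
    return(motif)
  }
  counts <- if (is.matrix(motif)) motif else motif$counts[[1]]
  motif_logodds(counts, background, pseudocount_frac)
}

#' Score every promoter with every motif
#'
#' Dense gene x motif matrix of normalized best-hit scores over the promoter
#' scan windows (both strands). When all promoter sequences share one length
#' the scan is vectorized across genes.
#'
#' @param motifs Motif tibble from [read_jaspar()].
#' @param promoters Tibble `gene_id`, `sequence` (the scan windows, e.g.
#'   450 bp upstream to 50 bp downstream of the TSS).
#' @param background,pseudocount_frac Passed to [motif_logodds()].
#' @return A numeric matrix, rownames gene_ids, colnames motif_ids.
#' @export
score_promoters <- function(motifs, promoters, background = rep(0.25, 4),
                            pseudocount_frac = 0.01) {
  if (anyDuplicated(promoters$gene_id) > 0) {
    abort("duplicate gene_id among promoter sequences")
  }
  lens <- nchar(promoters$sequence)
  codes <- encode_dna(promoters$sequence)
  out <- matrix(NA_real_, nrow(promoters), nrow(motifs),
                dimnames = list(promoters$gene_id, motifs$motif_id))
  equal_len <- length(unique(lens)) == 1
  code_mat <- if (equal_len && nrow(promoters) > 0) {
    matrix(unlist(codes), nrow = nrow(promoters), byrow = TRUE)
  } else NULL
  for (k in seq_len(nrow(motifs))) {
    m <- motif_logodds(motifs$counts[[k]], background, pseudocount_frac)
    L <- ncol(m$lo)
    if (any(lens < L)) abort("a promoter sequence is shorter than a motif")
    if (equal_len && nrow(promoters) > 0) {
      best <- pmax(scan_matrix(code_mat, m), scan_matrix(code_mat, revcomp_logodds(m)))
    } else {
      best <- vapply(codes, function(code) {
        max(scan_one_strand(code, m),
            scan_one_strand(code, revcomp_logodds(m)))
      }, numeric(1))
    }
    out[, k] <- (best - m$s_min) / (m$s_max - m$s_min)
  }
  out
}

# all genes at once: rowwise max over positions for one strand
scan_matrix <- function(code_mat, m) {
  L <- ncol(m$lo)
  np <- ncol(code_mat) - L + 1
  s <- matrix(0, nrow(code_mat), np)
  for (j in seq_len(L)) {
    col <- c(m$lo[, j], m$expected[j])
    block <- code_mat[, j:(j + np - 1), drop = FALSE]
    s <- s + matrix(col[block], nrow(code_mat))
  }
  apply(s, 1, max)
}

#' Pscan-style gene-set motif enrichment
#'
#' For each motif, compares the mean normalized best-hit score of the gene
#' set against the all-genes background:
#' `z = (mean_set - mean_bg) / (sd_bg / sqrt(n_set))`, with a one-sided
#' upper-tail normal p-value. A motif is significant at `p < alpha`
#' (default 1e-3, no multiplicity correction -- the threshold semantics are
#' deliberate).
#'
#' @param scores Score matrix from [score_promoters()].
#' @param gene_set Character vector of gene_ids (>= 2, all present among the
#'   score rows).
#' @param set_label Label carried into the result.
#' @param alpha Significance threshold on the one-sided p-value.
#' @return A tibble: `motif_id`, `gene_set`, `n_set`, `mean_set`, `mean_bg`,
#'   `sd_bg`, `z`, `p`, `significant`. When `sd_bg == 0` the z and p are
#'   `NA` and `significant` is `FALSE` (flagged, not an error).
#' @export
set_enrichment <- function(scores, gene_set, set_label = "set",
                           alpha = 1e-3) {
  if (length(gene_set) < 2) abort("gene_set must contain at least 2 genes")
  if (!all(gene_set %in% rownames(scores))) {
    abort("gene_set contains genes absent from the score matrix")
  }
  sub <- scores[gene_set, , drop = FALSE]
  mean_set <- colMeans(sub)
  mean_bg <- colMeans(scores)
  sd_bg <- apply(scores, 2, sd)
  z <- if_else(sd_bg > 0,
               (mean_set - mean_bg) / (sd_bg / sqrt(length(gene_set))),
               NA_real_)
  p <- pnorm(z, lower.tail = FALSE)
  n_genes_in_set <- length(gene_set)
  tibble(motif_id = colnames(scores), gene_set = set_label,
         n_set = n_genes_in_set, mean_set = unname(mean_set),
         mean_bg = unname(mean_bg), sd_bg = unname(sd_bg),
         z = unname(z), p = unname(p),
         significant = !is.na(p) & p < alpha)
}

#' z-score heat-map matrix over gene sets
#'
#' Stacks [set_enrichment()] results for several gene sets and keeps the
#' motifs significant in at least one of them.
#'
#' @param results A list or bind of enrichment tibbles (one per gene set).
#' @return A motifs x gene-sets matrix of z-scores (possibly 0-row).
#' @export
enrichment_heatmap <- function(results) {
  df <- if (is.data.frame(results)) results else bind_rows(results)
  keep <- unique(df$motif_id[df$significant])
  df <- df[df$motif_id %in% keep, , drop = FALSE]
  sets <- unique(df$gene_set)
  m <- matrix(NA_real_, length(keep), length(sets),
              dimnames = list(keep, sets))
  for (i in seq_len(nrow(df))) {
    m[df$motif_id[i], df$gene_set[i]] <- df$z[i]
  }
  m
}
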