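#' Gene models as a tibble
#'
#' All of silencescan works on a flat, strand-aware gene table. One row per
#' gene; coordinates are 0-based half-open (BED convention) everywhere inside
#' the package, and are converted only when reading or writing 1-based formats
#' (GFF3/GTF). The transcription start site (TSS) anchors every downstream
#' window: `tss == start` on the `+` strand and `tss == end - 1` on the `-`
#' strand.
#'
#' @details Columns: `gene_id`, `chrom`, `strand` (`"+"`/`"-"`), `start`,
#'   `end` (half-open span), `tss`, `biotype`
#'   (`protein_coding`/`microRNA`/`rRNA`/`other`), `exons` (list-column of
#'   two-column matrices `start`,`end`, sorted, non-overlapping, contained in
#'   the span) and `exonic_length`.
#'
#' @param genes A gene tibble, as returned by [read_gene_models()] or
#'   [generate_annotation()].
#' @return `validate_gene_models()` returns its input invisibly, or aborts
#'   with an informative message.
#' @export
validate_gene_models <- function(genes) {
  need <- c("gene_id", "chrom", "strand", "start", "end", "tss",
            "biotype", "exons")
  missing <- setdiff(need, names(genes))
  if (length(missing) > 0) {
    abort(paste0("gene table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(genes$gene_id) > 0) {
    dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
    abort(paste0("duplicate gene_id(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  if (any(genes$end <= genes$start)) abort("gene span must be non-empty")
  tss_expect <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  if (!all(genes$tss == tss_expect)) {
    abort("tss must equal start (+ strand) or end - 1 (- strand)")
  }
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    if (is.null(ex) || nrow(ex) == 0) {
      abort(paste0("gene ", genes$gene_id[i], " has no exons"))
    }
    if (any(ex[, "end"] <= ex[, "start"])) {
      abort(paste0("gene ", genes$gene_id[i], " has an empty exon"))
    }
    if (is.unsorted(ex[, "start"], strictly = FALSE)) {
      abort(paste0("gene ", genes$gene_id[i], " exons are not sorted"))
    }
    if (nrow(ex) > 1 && any(ex[-1, "start"] < ex[-nrow(ex), "end"])) {
      abort(paste0("gene ", genes$gene_id[i], " exons overlap"))
    }
    if (ex[1, "start"] < genes$start[i] || ex[nrow(ex), "end"] > genes$end[i]) {
      abort(paste0("gene ", genes$gene_id[i], " exon outside gene span"))
    }
  }
  invisible(genes)
}

exon_matrix <- function(starts, ends) {
  m <- cbind(start = as.numeric(starts), end = as.numeric(ends))
  m[order(m[, "start"]), , drop = FALSE]
}

add_exonic_length <- function(genes) {
  genes$exonic_length <- vapply(
    genes$exons, function(ex) sum(ex[, "end"] - ex[, "start"]), numeric(1))
  genes
}

#' Read gene models from GFF3, GTF or BED12
#'
#' Parses a standard annotation file and collapses it to one record per gene:
#' the union of all exons and the 5'-most TSS on the gene strand. Coordinates
#' are converted to 0-based half-open on the way in.
#'
#' @param path Path to an annotation file.
#' @param dialect One of `"gff3"`, `"gtf"`, `"bed12"`.
#' @return A gene tibble (see [validate_gene_models()]).
#' @export
read_gene_models <- function(path, dialect = c("gff3", "gtf", "bed12")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (dialect == "bed12") {
    gr <- tryCatch(
      rtracklayer::import(path, format = "BED"),
      error = function(e) abort(paste0("failed to parse ", path, ": ",
                                       conditionMessage(e))))
    return(bed12_to_genes(gr))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (dialect == "gtf") "GTF" else "GFF3"),
    error = function(e) abort(paste0("failed to parse ", path, ": ",
                                     conditionMessage(e))))
  gff_to_genes(gr, path)
}

gff_to_genes <- function(gr, path) {
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  gid <- as.character(md$gene_id %||% md$ID %||% md$Name)
  if (all(is.na(gid))) abort(paste0("no gene_id attribute found in ", path))
  is_gene <- type %in% c("gene", "ncRNA_gene", "pseudogene")
  is_exon <- type == "exon"
  if (!any(is_gene)) is_gene <- type %in% c("transcript", "mRNA")
  if (!any(is_exon)) is_exon <- is_gene  # exonless dialects: exon == span
  # exon rows in GFF3 often carry Parent rather than gene_id
  if ("Parent" %in% names(md)) {
    par <- vapply(md$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
                  character(1))
    gid[is_exon & is.na(gid)] <- par[is_exon & is.na(gid)]
  }
  gstart <- GenomicRanges::start(gr) - 1L  # 1-based closed -> 0-based half-open
  gend <- GenomicRanges::end(gr)
  gchrom <- as.character(GenomicRanges::seqnames(gr))
  gstrand <- as.character(GenomicRanges::strand(gr))
  biot <- as.character(md$biotype %||% md$gene_biotype %||%
                         rep("protein_coding", length(gr)))
  biot[is.na(biot)] <- "protein_coding"

  genes_idx <- which(is_gene)
  ids <- gid[genes_idx]
  if (anyDuplicated(ids) > 0) {
    abort(paste0("duplicate gene_id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  exon_by_gene <- split(which(is_exon), gid[is_exon])
  rows <- purrr::map(genes_idx, function(i) {
    id <- gid[i]
    ei <- exon_by_gene[[id]]
    if (is.null(ei)) ei <- i
    ex <- IRanges::reduce(IRanges::IRanges(gstart[ei] + 1L, gend[ei]))
    exm <- exon_matrix(IRanges::start(ex) - 1L, IRanges::end(ex))
    if (exm[1, "start"] < gstart[i] || exm[nrow(exm), "end"] > gend[i]) {
      abort(paste0("gene ", id, ": exon outside gene span"))
    }
    tibble(
      gene_id = id, chrom = gchrom[i], strand = gstrand[i],
      start = as.numeric(gstart[i]), end = as.numeric(gend[i]),
      tss = if (gstrand[i] == "+") as.numeric(gstart[i]) else gend[i] - 1,
      biotype = normalize_biotype(biot[i]),
      exons = list(exm))
  })
  out <- add_exonic_length(bind_rows(rows))
  validate_gene_models(out)
  out
}

normalize_biotype <- function(x) {
  ifelse(x %in% c("protein_coding", "microRNA", "rRNA"), x,
         ifelse(x %in% c("miRNA"), "microRNA", "other"))
}

bed12_to_genes <- function(gr) {
  ids <- as.character(S4Vectors::mcols(gr)$name)
  if (anyDuplicated(ids) > 0) {
    abort(paste0("duplicate gene_id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  blocks <- S4Vectors::mcols(gr)$blocks  # relative 1-based within span
  rows <- purrr::map(seq_along(gr), function(i) {
    st <- GenomicRanges::start(gr)[i] - 1
    en <- GenomicRanges::end(gr)[i]
    strand_i <- as.character(GenomicRanges::strand(gr))[i]
    if (!is.null(blocks) && length(blocks[[i]]) > 0) {
      b <- blocks[[i]]
      exm <- exon_matrix(st + IRanges::start(b) - 1, st + IRanges::end(b))
    } else {
      exm <- exon_matrix(st, en)
    }
    tibble(
      gene_id = ids[i], chrom = as.character(GenomicRanges::seqnames(gr))[i],
      strand = strand_i, start = st, end = en,
      tss = if (strand_i == "+") st else en - 1,
      biotype = "protein_coding", exons = list(exm))
  })
  out <- add_exonic_length(bind_rows(rows))
  validate_gene_models(out)
  out
}

#' Write gene models to BED12 or BED6
#'
#' Emits BED-convention (0-based half-open) intervals. BED12 preserves the
#' exon structure as blocks; BED6 writes only the gene span.
#'
#' @param genes A gene tibble.
#' @param path Output path.
#' @param format `"bed12"` or `"bed6"`.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path, format = c("bed12", "bed6")) {
  format <- match.arg(format)
  validate_gene_models(genes)
  if (format == "bed6") {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     genes$chrom, as.integer(genes$start),
                     as.integer(genes$end), genes$gene_id, genes$strand)
  } else {
    lines <- vapply(seq_len(nrow(genes)), function(i) {
      ex <- genes$exons[[i]]
      sizes <- paste0(paste(as.integer(ex[, "end"] - ex[, "start"]),
                            collapse = ","), ",")
      starts <- paste0(paste(as.integer(ex[, "start"] - genes$start[i]),
                             collapse = ","), ",")
      sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
              genes$chrom[i], as.integer(genes$start[i]),
              as.integer(genes$end[i]), genes$gene_id[i], genes$strand[i],
              as.integer(genes$start[i]), as.integer(genes$end[i]),
              nrow(ex), sizes, starts)
    }, character(1))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Strand-aware promoter window around the TSS
#'
#' Materializes the half-open genomic interval covering `upstream_bp` bases
#' upstream and `downstream_bp` bases downstream of each TSS (the TSS base
#' itself is the first downstream base). Upstream of a `-` strand gene lies at
#' larger genomic coordinates, so windows on the two strands are exact mirror
#' images. Windows are clipped at coordinate 0.
#'
#' @param genes A gene tibble (only `tss` and `strand` are used); or a tibble
#'   with columns `tss` and `strand`.
#' @param upstream_bp,downstream_bp Non-negative window extents in bp. The
#'   array design in this pipeline tiles ~3500 bp upstream to ~750 bp
#'   downstream of the TSS; the motif scan uses 450/50.
#' @return A tibble with columns `gene_id` (if present), `chrom` (if
#'   present), `start`, `end` (half-open). Length is
#'   `upstream_bp + downstream_bp` unless clipped at 0; a zero-by-zero window
#'   is empty (`start == end`).
#' @export
promoter_window <- function(genes, upstream_bp, downstream_bp) {
  if (length(upstream_bp) != 1 || length(downstream_bp) != 1 ||
      is.na(upstream_bp) || is.na(downstream_bp) ||
      upstream_bp < 0 || downstream_bp < 0) {
    abort("upstream_bp and downstream_bp must be single non-negative numbers")
  }
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream_bp, genes$tss - downstream_bp + 1)
  end <- ifelse(plus, genes$tss + downstream_bp, genes$tss + upstream_bp + 1)
  if (upstream_bp + downstream_bp == 0) {  # degenerate: empty window at tss
    start <- genes$tss
    end <- genes$tss
  }
  start <- pmax(start, 0)
  end <- pmax(end, start)
  out <- tibble(start = as.numeric(start), end = as.numeric(end))
  if ("chrom" %in% names(genes)) out <- bind_cols(tibble(chrom = genes$chrom), out)
  if ("gene_id" %in% names(genes)) out <- bind_cols(tibble(gene_id = genes$gene_id), out)
  out
}

#' Overlap between two half-open intervals, in bp
#'
#' `max(0, min(a_end, b_end) - max(a_start, b_start))`, vectorized. Intervals
#' on different chromosomes overlap by 0 (not an error). Abutting half-open
#' intervals overlap by 0.
#'
#' @param a_start,a_end,b_start,b_end Interval bounds (half-open).
#' @param a_chrom,b_chrom Optional chromosome names; if given, overlap is 0
#'   whenever they differ.
#' @return Integer-valued numeric vector of overlap widths.
#' @export
overlap_bp <- function(a_start, a_end, b_start, b_end,
                       a_chrom = NULL, b_chrom = NULL) {
  ov <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  if (!is.null(a_chrom) && !is.null(b_chrom)) {
    ov[a_chrom != b_chrom] <- 0
  }
  ov
}

# GRanges helpers: internal 0-based half-open <-> 1-based closed
genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end),
    strand = genes$strand, gene_id = genes$gene_id)
}

exons_to_granges <- function(genes) {
  nex <- vapply(genes$exons, nrow, integer(1))
  allex <- do.call(rbind, genes$exons)
  GenomicRanges::GRanges(
    seqnames = rep(genes$chrom, nex),
    ranges = IRanges::IRanges(start = allex[, "start"] + 1,
                              end = allex[, "end"]),
    strand = rep(genes$strand, nex),
    gene_id = rep(genes$gene_id, nex))
}

intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
}
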