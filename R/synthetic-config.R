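#' Configuration for the synthetic silencing experiment
#'
#' Bundles every knob of the ground-truth generator. The defaults describe
#' the study conditions the pipeline is validated under: 2000 genes, 10%
#' silenced with true fold changes log-uniform between 2 and 100, 10%
#' induced, promoter deacetylation planted for 90% of silenced genes,
#' sequencing depth 2e6 reads per library, and a TSS-proximal
#' transcription-factor site planted at probability 0.9 for silenced genes
#' versus 0.3 elsewhere.
#'
#' @param n_genes Number of genes to place.
#' @param genome_length Length of the single synthetic chromosome, bp.
#' @param gene_length_range Log-uniform range of gene span lengths, bp.
#' @param exon_fraction Fraction of each gene span that is exonic.
#' @param class_fractions Named fractions (`silenced`, `induced`,
#'   `unchanged`) summing to 1.
#' @param fold_range Log-uniform range of true fold changes for silenced
#'   genes (transcriptional arrest spans roughly 2- to 100-fold).
#' @param induced_fold_range Log-uniform range for induced genes. Kept more
#'   modest by default: after only 1 h of stimulation induction is still
#'   ramping up, and bounded induced folds keep total transcriptional output
#'   roughly stable, which the per-library RPKM normalization implicitly
#'   assumes.
#' @param expression_range Log-uniform range of per-gene basal transcription
#'   rates (arbitrary units); the study gives no distribution for this, so it
#'   is an explicit knob.
#' @param deacetylation_given_silenced Probability that a silenced gene's
#'   promoter carries planted H4 deacetylation.
#' @param deacetylation_delta Planted log2 drop of the LPS1h channel over the
#'   deacetylated subregion.
#' @param deacetylation_halfwidth Half-width (bp) of the deacetylated
#'   subregion, centered on the TSS.
#' @param pu1_site_probability Named per-class probabilities of a planted
#'   TSS-proximal peak.
#' @param pu1_site_sd SD (bp) of the planted site's distance from the TSS.
#' @param motif_insert_probability Named per-class probabilities that one
#'   motif instance is inserted into the promoter scan window.
#' @param nb_dispersion Extra-Poisson coefficient of variation of the
#'   per-gene read count (Gamma-Poisson with Gamma shape `1/nb_dispersion^2`);
#'   0 gives pure Poisson counts.
#' @param lognormal_sd SD, in log2 units, of the multiplicative noise applied
#'   to each tiling-array channel.
#' @param peak_jitter_sd SD (bp) of the per-replicate positional jitter of
#'   planted peaks.
#' @param noise_peak_rate Expected number of replicate-specific noise peaks
#'   per gene, per replicate.
#' @param depth Reads per sequencing library.
#' @param rrna_fraction Fraction of each library drawn from rRNA loci
#'   (residual after depletion).
#' @param lowcomplexity_fraction Fraction of each library that is mono- or
#'   di-nucleotide repeat reads.
#' @param mrna_attenuation Exponent attenuating fold changes at the mRNA
#'   level (`fold^mrna_attenuation`); 1 means mRNA tracks transcription
#'   instantly, values < 1 emulate the 1-h lag of steady-state mRNA.
#' @param read_length Read length, nt.
#' @param promoter_up,promoter_down Tiling-array promoter window, bp up- and
#'   downstream of the TSS.
#' @param probe_length,probe_step Probe length and 5'-end spacing, bp.
#' @param n_rrna_genes,n_mirna_genes Number of rRNA / microRNA genes among
#'   `n_genes`.
#' @param seed Master seed; every output artifact draws from its own RNG
#'   stream derived from this seed by label hashing, so adding an artifact
#'   never perturbs existing ones.
#' @return A validated `truth_config` list.
#' @export
truth_config <- function(n_genes = 2000,
                         genome_length = 4e7,
                         gene_length_range = c(1000, 20000),
                         exon_fraction = 0.4,
                         class_fractions = c(silenced = 0.1, induced = 0.1,
                                             unchanged = 0.8),
                         fold_range = c(2, 100),
                         induced_fold_range = c(2, 10),
                         expression_range = c(1, 100),
                         deacetylation_given_silenced = 0.9,
                         deacetylation_delta = 1.5,
                         deacetylation_halfwidth = 500,
                         pu1_site_probability = c(silenced = 0.9,
                                                  induced = 0.3,
                                                  unchanged = 0.3),
                         pu1_site_sd = 150,
                         motif_insert_probability = c(silenced = 0.8,
                                                      induced = 0.2,
                                                      unchanged = 0.2),
                         nb_dispersion = 0.1,
                         lognormal_sd = 0.3,
                         peak_jitter_sd = 20,
                         noise_peak_rate = 0.2,
                         depth = 2e6,
                         rrna_fraction = 0.02,
                         lowcomplexity_fraction = 0.01,
                         mrna_attenuation = 0.3,
                         read_length = 50,
                         promoter_up = 3500,
                         promoter_down = 750,
                         probe_length = 50,
                         probe_step = 10,
                         n_rrna_genes = 4,
                         n_mirna_genes = 10,
                         seed = 42) {
  cfg <- as.list(environment())
  class(cfg) <- "truth_config"
  validate_truth_config(cfg)
  cfg
}

validate_truth_config <- function(cfg) {
  frac_ok <- function(x) all(x >= 0 & x <= 1)
  if (cfg$n_genes < 0) abort("n_genes must be non-negative")
  if (!frac_ok(cfg$class_fractions) ||
      abs(sum(cfg$class_fractions) - 1) > 1e-8) {
    abort("class_fractions must lie in [0,1] and sum to 1")
  }
  if (!setequal(names(cfg$class_fractions),
                c("silenced", "induced", "unchanged"))) {
    abort("class_fractions must be named silenced/induced/unchanged")
  }
  for (f in c("deacetylation_given_silenced", "rrna_fraction",
              "lowcomplexity_fraction", "exon_fraction")) {
    if (!frac_ok(cfg[[f]])) abort(paste0(f, " must lie in [0,1]"))
  }
  if (!frac_ok(cfg$pu1_site_probability) ||
      !frac_ok(cfg$motif_insert_probability)) {
    abort("site/motif probabilities must lie in [0,1]")
  }
  if (cfg$fold_range[1] < 1 || cfg$induced_fold_range[1] < 1) {
    abort("fold ranges must start at >= 1")
  }
  if (cfg$depth < 0) abort("depth must be non-negative")
  if (cfg$nb_dispersion < 0) abort("nb_dispersion must be non-negative")
  if (cfg$seed != round(cfg$seed)) abort("seed must be an integer")
  invisible(cfg)
}

#' Read or write a `truth_config` as YAML
#'
#' @param path YAML file path.
#' @return `read_truth_config()` returns a `truth_config`;
#'   `write_truth_config()` returns `path` invisibly.
#' @export
read_truth_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("class_fractions", "pu1_site_probability",
               "motif_insert_probability")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(truth_config, raw)
}

#' @rdname read_truth_config
#' @param cfg A `truth_config`.
#' @export
write_truth_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$class_fractions <- as.list(x$class_fractions)
  x$pu1_site_probability <- as.list(x$pu1_site_probability)
  x$motif_insert_probability <- as.list(x$motif_insert_probability)
  yaml::write_yaml(x, path)
  invisible(path)
}

# Deterministic per-artifact RNG stream: hash (seed, label) into [1, 2^31-2].
# A plain polynomial rolling hash keeps every artifact's stream independent of
# the order in which artifacts are generated.
stream_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483629
  as.integer((h + (seed %% 2147483629) * 48271) %% 2147483629 + 1)
}

with_stream <- function(seed, label, code) {
  withr::with_seed(stream_seed(seed, label), code)
}
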