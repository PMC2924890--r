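#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. The defaults emulate
#' the study design the downstream analysis assumes: per-treatment effects on
#' mRNA and protein with a controlled sign-concordance rate, four replicate
#' arrays per treatment hybridized against a common reference pool (the fourth
#' a dye reversal), and multi-spectrum iTRAQ peptide evidence per protein with
#' lognormal reporter noise plus reversed-sequence decoy contaminants.
#'
#' All randomness downstream derives from `seed`: each output table uses its
#' own RNG stream at a fixed offset from the master seed, so e.g. adding
#' arrays never perturbs the PSM simulation.
#'
#' @param n_genes Number of genes (ESTs printed on the array; each gene also
#'   has a protein product).
#' @param frac_de_mrna Fraction of genes differentially expressed at the mRNA
#'   level, per treatment.
#' @param frac_de_protein Fraction of genes differentially expressed at the
#'   protein level, per treatment.
#' @param concordance_rate Probability that a gene DE in both layers carries
#'   the same effect sign on mRNA and protein.
#' @param overlap_rate Fraction of DE-protein genes drawn from the DE-mRNA set
#'   (where possible); controls how many genes are DE in both layers.
#' @param effect_size_log2 Magnitude of every nonzero effect, in log2 units;
#'   signs are random.
#' @param n_arrays_per_treatment Replicate arrays per treatment; the last one
#'   is flagged as a dye reversal.
#' @param spectra_per_protein Mean of the Poisson spectral count per protein.
#'   The default (14) reflects the spectral density of hypothalamic iTRAQ
#'   experiments of this design (~8.6k spectra over ~620 proteins).
#' @param reporter_cv Lognormal noise scale (sd of log2 intensity) for iTRAQ
#'   reporter channels.
#' @param array_sd Lognormal noise scale (sd of log2 intensity) for microarray
#'   channels.
#' @param decoy_fraction Expected fraction of PSMs that are reversed-sequence
#'   decoys.
#' @param min_peptide_len,max_peptide_len Tryptic peptide length window
#'   (residues) retained by the in-silico digest.
#' @param seed Integer master seed; fully determines all outputs.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 50, seed = 1)
#' cfg$concordance_rate
#' @export
sim_config <- function(n_genes = 500,
                       frac_de_mrna = 0.3,
                       frac_de_protein = 0.3,
                       concordance_rate = 0.5,
                       overlap_rate = 0.5,
                       effect_size_log2 = 1,
                       n_arrays_per_treatment = 4,
                       spectra_per_protein = 14,
                       reporter_cv = 0.25,
                       array_sd = 0.2,
                       decoy_fraction = 0.1,
                       min_peptide_len = 6,
                       max_peptide_len = 30,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    frac_de_mrna = frac_de_mrna,
    frac_de_protein = frac_de_protein,
    concordance_rate = concordance_rate,
    overlap_rate = overlap_rate,
    effect_size_log2 = effect_size_log2,
    n_arrays_per_treatment = as.integer(n_arrays_per_treatment),
    spectra_per_protein = spectra_per_protein,
    reporter_cv = reporter_cv,
    array_sd = array_sd,
    decoy_fraction = decoy_fraction,
    min_peptide_len = as.integer(min_peptide_len),
    max_peptide_len = as.integer(max_peptide_len),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  fracs <- c("frac_de_mrna", "frac_de_protein", "concordance_rate",
             "overlap_rate", "decoy_fraction")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("sim_config: `", f, "` must be a single number in [0, 1]",
           call. = FALSE)
    }
  }
  if (cfg$n_genes < 1L) stop("sim_config: `n_genes` must be >= 1", call. = FALSE)
  if (cfg$effect_size_log2 <= 0) {
    stop("sim_config: `effect_size_log2` must be positive", call. = FALSE)
  }
  if (cfg$reporter_cv < 0 || cfg$array_sd < 0) {
    stop("sim_config: noise scales must be non-negative", call. = FALSE)
  }
  if (cfg$n_arrays_per_treatment < 2L) {
    stop("sim_config: need >= 2 arrays per treatment", call. = FALSE)
  }
  if (cfg$min_peptide_len < 1L || cfg$max_peptide_len < cfg$min_peptide_len) {
    stop("sim_config: bad peptide length window", call. = FALSE)
  }
  if (is.na(cfg$seed)) stop("sim_config: `seed` must be an integer", call. = FALSE)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_genes, " genes, ",
      "DE mRNA ", x$frac_de_mrna, " / protein ", x$frac_de_protein,
      ", concordance ", x$concordance_rate,
      ", effect ", x$effect_size_log2, " log2, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Treatments are fixed by the iTRAQ plex layout: 114 = control,
# 115 = LY (D2 agonist), 117 = SKF (D1 agonist).
TREATMENTS <- c("SKF", "LY")

# fixed RNG stream offsets, one per output table
.stream <- c(truth = 0L, arrays = 1000L, psms = 2000L)
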