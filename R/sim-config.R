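#' Configuration for the synthetic diel-expression generator
#'
#' Bundles every tunable of the synthetic data generator: the sampling grid,
#' the AR(1) observation-noise model, the population distributions of cycling
#' parameters (phase, half-amplitude, protein damping, protein-after-mRNA
#' lag), the peptide peak-scatter and CV model, per-timepoint mixing biases,
#' outlier injection rates, and the strand-specific coverage model.
#'
#' Defaults emulate a synchronized 24-h light-dark experiment sampled every
#' 2 h over 26 h (14 timepoints, t = 0 at local midnight): mRNA log2
#' abundances carry a 24-h sinusoid for cycling genes plus AR(1) noise;
#' protein series follow the mRNA with a gene-specific lag and damped
#' amplitude. Peptide-level peaks scatter lognormally around the true protein
#' ratio with heteroscedastic reported CVs calibrated so the 80th CV
#' percentile falls near 41%.
#'
#' @param n_genes number of genes to simulate.
#' @param times sampling times in hours since experiment start (t = 0 at
#'   local midnight); strictly increasing.
#' @param ar1_phi AR(1) coefficient of the observation noise, in (-1, 1).
#' @param innovation_sd innovation standard deviation of the AR(1) noise
#'   on mRNA series (log2 units).
#' @param innovation_sd_protein innovation sd of protein-level noise;
#'   default half the mRNA value, because the slow synthesis/turnover
#'   dynamics that damp protein-level signal low-pass filter biological
#'   noise along with it.
#' @param fraction_cyclers proportion of genes given a 24-h signal; the
#'   realized count is `round(n_genes * fraction_cyclers)`.
#' @param phase_dist,halfamp_dist,lag_dist,damping_dist distribution specs
#'   (see [dist_point()] and friends) for mRNA peak phase (hours, wrapped to
#'   \[0, 24)), mRNA half-amplitude (log2 units), protein-after-mRNA lag
#'   (hours), and the mRNA:protein half-amplitude damping ratio.
#' @param damping_clamp if `TRUE`, damping ratios below 1 are clamped to 1 so
#'   protein half-amplitude never exceeds the mRNA's. Default `FALSE`: a
#'   minority of genes may amplify at the protein level.
#' @param baseline_dist_mrna,baseline_dist_protein distribution specs for
#'   gene baselines (log2 units; protein baselines are log2 sample:standard
#'   ratios, centred near 0 for a near 1:1 mix).
#' @param peaks_per_timepoint_dist count distribution of quantified peaks
#'   per protein per timepoint (default shifted Poisson, minimum 1, mean 8).
#' @param peak_sigma mean per-peak log2 dispersion of peptide peak ratios.
#' @param cv_shape gamma shape of the per-peak dispersion mixture; together
#'   with `peak_sigma` this sets the reported-CV distribution
#'   (CV = sqrt(exp((sigma * ln 2)^2) - 1)).
#' @param mixing_bias per-timepoint log2 offsets applied to all peak ratios
#'   at that timepoint (length `length(times)`), or `NULL` to draw them
#'   from `N(0, mixing_bias_sd)`.
#' @param mixing_bias_sd sd of drawn mixing biases (log2 units).
#' @param outlier_peak_rate proportion of peaks displaced as outliers.
#' @param outlier_peak_shift displacement magnitude of outlier peaks, in
#'   multiples of `peak_sigma` (sign random).
#' @param outlier_timepoint_rate proportion of protein-timepoints whose peaks
#'   are all shifted (a bad-injection style artifact).
#' @param outlier_timepoint_shift magnitude of the timepoint shift (log2).
#' @param antisense_detect_prob probability a gene carries any antisense
#'   transcription.
#' @param antisense_ratio_mean mean antisense:sense abundance ratio among
#'   antisense-carrying genes (per-gene ratios drawn Gamma with this mean).
#' @param depth mean per-base sense coverage at an average-abundance gene.
#' @param gene_length,gene_gap gene body length and intergenic gap (bp) of
#'   the synthetic single-chromosome gene models.
#' @param seed master seed; all randomness at every stage flows from it
#'   through per-gene, per-level substreams.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 20, seed = 1)
#' truth <- generate_diel_truth(cfg)
#' @export
sim_config <- function(n_genes = 500,
                       times = seq(0, 26, by = 2),
                       ar1_phi = 0.3,
                       innovation_sd = 0.25,
                       innovation_sd_protein = innovation_sd / 2,
                       fraction_cyclers = 0.87,
                       phase_dist = dist_mixture(
                         list(dist_normal(3.5, 1.3), dist_normal(18, 1.5),
                              dist_uniform(0, 24)),
                         c(0.35, 0.33, 0.32)),
                       halfamp_dist = dist_lognormal(log(0.75), 0.6),
                       lag_dist = dist_gamma(shape = 1.8, rate = 0.35),
                       damping_dist = dist_lognormal(log(4.9), 1.02),
                       damping_clamp = FALSE,
                       baseline_dist_mrna = dist_normal(3, 1.5),
                       baseline_dist_protein = dist_normal(0, 0.5),
                       peaks_per_timepoint_dist = dist_shifted_poisson(8),
                       peak_sigma = 0.395,
                       cv_shape = 2.78,
                       mixing_bias = NULL,
                       mixing_bias_sd = 0.1,
                       outlier_peak_rate = 0.05,
                       outlier_peak_shift = 5,
                       outlier_timepoint_rate = 0.01,
                       outlier_timepoint_shift = 3,
                       antisense_detect_prob = 0.73,
                       antisense_ratio_mean = 0.354,
                       depth = 20,
                       gene_length = 900,
                       gene_gap = 100,
                       seed = 1) {
  cfg <- list(
    n_genes = n_genes, times = times, ar1_phi = ar1_phi,
    innovation_sd = innovation_sd,
    innovation_sd_protein = innovation_sd_protein,
    fraction_cyclers = fraction_cyclers,
    phase_dist = phase_dist, halfamp_dist = halfamp_dist,
    lag_dist = lag_dist, damping_dist = damping_dist,
    damping_clamp = damping_clamp,
    baseline_dist_mrna = baseline_dist_mrna,
    baseline_dist_protein = baseline_dist_protein,
    peaks_per_timepoint_dist = peaks_per_timepoint_dist,
    peak_sigma = peak_sigma, cv_shape = cv_shape,
    mixing_bias = mixing_bias, mixing_bias_sd = mixing_bias_sd,
    outlier_peak_rate = outlier_peak_rate,
    outlier_peak_shift = outlier_peak_shift,
    outlier_timepoint_rate = outlier_timepoint_rate,
    outlier_timepoint_shift = outlier_timepoint_shift,
    antisense_detect_prob = antisense_detect_prob,
    antisense_ratio_mean = antisense_ratio_mean,
    depth = depth, gene_length = gene_length, gene_gap = gene_gap,
    seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(paste0("Invalid sim_config: ", msg))
  chk(is.numeric(cfg$n_genes) && cfg$n_genes > 0, "`n_genes` must be > 0.")
  chk(all(diff(cfg$times) > 0), "`times` must be strictly increasing.")
  chk(abs(cfg$ar1_phi) < 1, "`ar1_phi` must lie in (-1, 1).")
  chk(cfg$innovation_sd >= 0, "`innovation_sd` must be >= 0.")
  chk(cfg$innovation_sd_protein >= 0, "`innovation_sd_protein` must be >= 0.")
  for (fld in c("fraction_cyclers", "outlier_peak_rate",
                "outlier_timepoint_rate", "antisense_detect_prob")) {
    chk(cfg[[fld]] >= 0 && cfg[[fld]] <= 1,
        paste0("`", fld, "` must lie in [0, 1]."))
  }
  chk(cfg$peak_sigma >= 0, "`peak_sigma` must be >= 0.")
  chk(cfg$depth > 0, "`depth` must be > 0.")
  if (!is.null(cfg$mixing_bias)) {
    chk(length(cfg$mixing_bias) == length(cfg$times),
        "`mixing_bias` must have one offset per timepoint.")
  }
  # surface bad distribution names at configuration time, not mid-simulation
  for (fld in c("phase_dist", "halfamp_dist", "lag_dist", "damping_dist",
                "baseline_dist_mrna", "baseline_dist_protein",
                "peaks_per_timepoint_dist")) {
    withr::with_seed(1L, draw_dist(cfg[[fld]], 1L, field = fld))
  }
  cfg
}
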