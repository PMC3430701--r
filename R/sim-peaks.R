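#' Simulate a peptide peak-ratio table from protein timecourses
#'
#' Emulates the peak-level input of isotope-ratio protein quantification:
#' for every protein at every timepoint a count of quantified peaks is drawn,
#' each peak's log2 ratio scatters normally (lognormal on the linear scale)
#' around the true protein log2 ratio with a peak-specific dispersion, a
#' per-timepoint mixing bias is added to every ratio at that timepoint, and
#' a fraction of peaks and of whole protein-timepoints are displaced as
#' outliers. Reported CVs are a deterministic function of the per-peak
#' dispersion (`sqrt(exp((sigma*ln2)^2) - 1)`), so noisier peaks report
#' larger CVs.
#'
#' @param protein_tc protein rows of [simulate_timecourses()] output (the
#'   `level == "protein"` subset; other levels are ignored).
#' @param config the matching [sim_config()].
#' @return A list:
#'   * `peaks`: tibble `peak_id`, `protein_id`, `timepoint_index`, `time_h`,
#'     `ratio` (linear sample:standard), `cv`;
#'   * `peak_truth`: per-peak bookkeeping (`true_log2`, `sigma`,
#'     `is_outlier_peak`, `in_outlier_timepoint`);
#'   * `mixing_bias`: tibble of the per-timepoint log2 offsets used.
#' @export
simulate_peak_table <- function(protein_tc, config) {
  stopifnot(inherits(config, "sim_config"))
  tc <- protein_tc
  if ("level" %in% names(tc)) tc <- dplyr::filter(tc, .data$level == "protein")
  nt <- length(config$times)
  b <- config$mixing_bias
  if (is.null(b)) {
    b <- with_stream(config$seed, "mixbias",
                     code = rnorm(nt, 0, config$mixing_bias_sd))
  }
  ids <- unique(tc$gene_id)
  rows <- purrr::map_dfr(seq_along(ids), function(i) {
    g <- tc[tc$gene_id == ids[i], ]
    with_stream(config$seed, "peaks", ids[i], code = {
      nk <- as.integer(draw_dist(config$peaks_per_timepoint_dist, nrow(g),
                                 "peaks_per_timepoint_dist"))
      tp_out <- runif(nrow(g)) < config$outlier_timepoint_rate
      purrr::map_dfr(seq_len(nrow(g)), function(k) {
        n <- nk[k]
        sigma <- rgamma(n, shape = config$cv_shape,
                        rate = config$cv_shape / max(config$peak_sigma, 1e-12))
        if (config$peak_sigma == 0) sigma <- rep(0, n)
        out_pk <- runif(n) < config$outlier_peak_rate
        true_l2 <- g$log2_abundance[k]
        l2 <- true_l2 + b[g$timepoint_index[k] + 1L] + rnorm(n, 0, sigma) +
          ifelse(out_pk,
                 sample(c(-1, 1), n, replace = TRUE) *
                   config$outlier_peak_shift * config$peak_sigma,
                 0) +
          if (tp_out[k]) config$outlier_timepoint_shift else 0
        tibble(
          protein_id = ids[i],
          timepoint_index = g$timepoint_index[k],
          time_h = g$time_h[k],
          ratio = 2^l2,
          cv = sqrt(exp((sigma * log(2))^2) - 1),
          true_log2 = true_l2,
          sigma = sigma,
          is_outlier_peak = out_pk,
          in_outlier_timepoint = tp_out[k])
      })
    })
  })
  rows$peak_id <- sprintf("pk%07d", seq_len(nrow(rows)))
  peaks <- dplyr::select(rows, "peak_id", "protein_id", "timepoint_index",
                         "time_h", "ratio", "cv")
  peak_truth <- dplyr::select(rows, "peak_id", "protein_id",
                              "timepoint_index", "true_log2", "sigma",
                              "is_outlier_peak", "in_outlier_timepoint")
  list(peaks = peaks,
       peak_truth = peak_truth,
       mixing_bias = tibble(timepoint_index = seq_len(nt) - 1L,
                            time_h = config$times, bias_log2 = b))
}
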