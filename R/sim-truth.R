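#' Draw gene-level ground truth for a synthetic diel experiment
#'
#' Assigns each gene a cycling status and, for cyclers, an mRNA peak phase,
#' mRNA half-amplitude, a protein half-amplitude (mRNA half-amplitude divided
#' by a drawn damping ratio) and a protein-after-mRNA lag, plus baselines for
#' both levels. Non-cyclers get half-amplitude 0 at both levels. The number
#' of cyclers is exactly `round(n_genes * fraction_cyclers)`.
#'
#' @param config a [sim_config()].
#' @return A tibble with one row per gene: `gene_id`, `is_cycler`,
#'   `mrna_phase` (hours in \[0,24)), `mrna_halfamp`, `protein_halfamp`
#'   (log2 units), `lag` (hours; protein phase = (mrna_phase + lag) mod 24),
#'   `protein_phase`, `mrna_baseline`, `protein_baseline`,
#'   `antisense_present`, `antisense_ratio`.
#' @export
generate_diel_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- as.integer(config$n_genes)
  n_cyc <- as.integer(round(n * config$fraction_cyclers))
  with_stream(config$seed, "truth", code = {
    gene_id <- sprintf("g%05d", seq_len(n))
    is_cycler <- rep(FALSE, n)
    is_cycler[sample.int(n, n_cyc)] <- TRUE
    phase <- draw_dist(config$phase_dist, n, "phase_dist") %% 24
    hamp <- abs(draw_dist(config$halfamp_dist, n, "halfamp_dist"))
    damp <- draw_dist(config$damping_dist, n, "damping_dist")
    if (isTRUE(config$damping_clamp)) damp <- pmax(damp, 1)
    lag <- draw_dist(config$lag_dist, n, "lag_dist")
    phase[!is_cycler] <- NA_real_
    lag[!is_cycler] <- NA_real_
    hamp[!is_cycler] <- 0
    p_hamp <- hamp / damp
    anti <- runif(n) < config$antisense_detect_prob
    anti_ratio <- ifelse(
      anti,
      rgamma(n, shape = 4, rate = 4 / config$antisense_ratio_mean),
      0)
    tibble(
      gene_id = gene_id,
      is_cycler = is_cycler,
      mrna_phase = phase,
      mrna_halfamp = hamp,
      protein_halfamp = p_hamp,
      lag = lag,
      protein_phase = (phase + lag) %% 24,
      mrna_baseline = draw_dist(config$baseline_dist_mrna, n,
                                "baseline_dist_mrna"),
      protein_baseline = draw_dist(config$baseline_dist_protein, n,
                                   "baseline_dist_protein"),
      antisense_present = anti,
      antisense_ratio = anti_ratio)
  })
}

# stationary AR(1): e_1 ~ N(0, sd^2/(1-phi^2)), e_t = phi e_{t-1} + N(0, sd^2)
# Matrix form: one column per series. Stationary initialization avoids
# burn-in artifacts on short series.
ar1_noise <- function(n, n_series, phi, sd) {
  out <- matrix(0, n, n_series)
  if (sd == 0) return(out)
  out[1, ] <- rnorm(n_series, 0, sd / sqrt(1 - phi^2))
  if (n > 1) {
    for (i in 2:n) out[i, ] <- phi * out[i - 1, ] + rnorm(n_series, 0, sd)
  }
  out
}

#' Simulate mRNA and protein log2-abundance timecourses from truth
#'
#' Each series is `baseline + H * cos(2*pi*(t - phase)/24) + e(t)` with `e`
#' a stationary AR(1) process. Protein phases are the mRNA phase plus the
#' gene's lag. Every gene and level has its own reproducible noise stream
#' derived from the master seed, so adding genes never perturbs existing
#' series.
#'
#' @param truth tibble from [generate_diel_truth()].
#' @param config the matching [sim_config()].
#' @return A tibble with columns `gene_id`, `level` ("mRNA"/"protein"),
#'   `timepoint_index` (0-based), `time_h`, `log2_abundance`.
#' @export
simulate_timecourses <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  t <- config$times
  nt <- length(t)
  w <- 2 * pi / 24
  per_level <- function(level) {
    phase <- if (level == "mRNA") truth$mrna_phase else truth$protein_phase
    hamp <- if (level == "mRNA") truth$mrna_halfamp else truth$protein_halfamp
    base <- if (level == "mRNA") truth$mrna_baseline else truth$protein_baseline
    purrr::map_dfr(seq_len(nrow(truth)), function(i) {
      sig <- if (truth$is_cycler[i]) {
        hamp[i] * cos(w * (t - phase[i]))
      } else rep(0, nt)
      sd_lvl <- if (level == "protein") {
        config$innovation_sd_protein %||% config$innovation_sd
      } else config$innovation_sd
      e <- with_stream(config$seed, "tc", i, level, code = {
        ar1_noise(nt, 1L, config$ar1_phi, sd_lvl)[, 1]
      })
      tibble(gene_id = truth$gene_id[i], level = level,
             timepoint_index = seq_len(nt) - 1L, time_h = t,
             log2_abundance = base[i] + sig + e)
    })
  }
  bind_rows(per_level("mRNA"), per_level("protein"))
}
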