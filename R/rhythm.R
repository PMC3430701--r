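# Harmonic regression design pieces for a fixed time grid. Cached per grid
# because every series in a collection usually shares the sampling design.
harmonic_design <- function(times, period = 24) {
  w <- 2 * pi / period
  X <- cbind(mesor = 1, cosw = cos(w * times), sinw = sin(w * times))
  XtXi <- solve(crossprod(X))
  Hm <- XtXi %*% t(X)       # coefficient operator
  G <- diag(length(times)) - X %*% Hm # residual projector
  list(times = times, period = period, X = X, Hm = Hm, G = G)
}

design_cache <- new.env(parent = emptyenv())
get_design <- function(times, period = 24) {
  if (length(times) > 100) return(harmonic_design(times, period))
  key <- paste(c(period, signif(times, 10)), collapse = ",")
  d <- design_cache[[key]]
  if (is.null(d)) {
    d <- harmonic_design(times, period)
    design_cache[[key]] <- d
  }
  d
}

#' Fit a fixed-period sinusoid to a timecourse
#'
#' Ordinary least squares of `y = m + a*cos(2*pi*t/T) + b*sin(2*pi*t/T)`
#' with period `T = 24` h. The half-amplitude is `H = sqrt(a^2 + b^2)`
#' (log2 units), the phase is the time of the fitted maximum
#' `(T/2/pi) * atan2(b, a) mod T`, and the peak-to-trough fold change is
#' `2^(2H)`. Constant series give `H = 0` with an undefined phase.
#'
#' @param times sampling times (hours); must span at least half a period.
#' @param values log2 abundances.
#' @param period oscillation period in hours (default 24).
#' @param min_points minimum observations required (default 8); fewer
#'   returns an error.
#' @param weights optional nonnegative observation weights (weighted least
#'   squares); default unweighted.
#' @return object of class `sinusoid_fit`: mesor, cos/sin coefficients,
#'   `halfamp`, `phase` (NA when undefined), `fold_change`, `residual_sd`,
#'   plus the data and fitted values.
#' @examples
#' t <- seq(0, 26, 2)
#' f <- fit_sinusoid_24h(t, 2 + cos(2 * pi * (t - 6) / 24))
#' c(f$mesor, f$halfamp, f$phase)
#' @export
fit_sinusoid_24h <- function(times, values, period = 24, min_points = 8,
                             weights = NULL) {
  keep <- is.finite(values) & is.finite(times)
  times <- times[keep]; values <- values[keep]
  n <- length(values)
  if (n < min_points) {
    abort(paste0("fit_sinusoid_24h(): ", n, " usable points < min_points (",
                 min_points, "); series unresolvable."))
  }
  if (diff(range(times)) < period / 2) {
    abort("fit_sinusoid_24h(): times must span at least half a period.")
  }
  if (is.null(weights)) {
    d <- get_design(times, period)
    cf <- drop(d$Hm %*% values)
    fitted <- drop(d$X %*% cf)
  } else {
    w <- 2 * pi / period
    X <- cbind(1, cos(w * times), sin(w * times))
    fit <- stats::lm.wfit(X, values, weights)
    cf <- fit$coefficients
    fitted <- drop(X %*% cf)
  }
  a <- cf[2]; b <- cf[3]
  H <- sqrt(a^2 + b^2)
  # numerically flat series: amplitude indistinguishable from 0
  if (H < 1e-9 * max(1, abs(cf[1]))) H <- 0
  phase <- if (H > 0) (period / (2 * pi)) * atan2(b, a) %% (2 * pi) else NA_real_
  rss <- sum((values - fitted)^2)
  structure(list(
    mesor = unname(cf[1]), cos_coef = unname(a), sin_coef = unname(b),
    halfamp = unname(H),
    phase = if (is.na(phase)) NA_real_ else unname(phase %% period),
    fold_change = unname(2^(2 * H)),
    residual_sd = sqrt(rss / max(n - 3, 1)),
    rss = rss, n = n, period = period,
    times = times, values = values, fitted = fitted),
    class = "sinusoid_fit")
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sinusoid_fit> period %g h | mesor %.3f | half-amplitude %.3f log2 (%.2f-fold) | phase %s h\n",
    x$period, x$mesor, x$halfamp, x$fold_change,
    if (is.na(x$phase)) "undefined" else sprintf("%.2f", x$phase)))
  invisible(x)
}

#' Fourier score of a harmonic fit
#'
#' The magnitude of the 24-h harmonic component of the timecourse,
#' `F = sqrt(a^2 + b^2)` from the least-squares fit — identical to the
#' fitted half-amplitude, invariant to mesor shifts, and linear in the data
#' scale. On an evenly sampled whole-period grid it coincides with the
#' discrete-Fourier 24-h component magnitude.
#'
#' @param fit a `sinusoid_fit`.
#' @return the score (log2 units).
#' @export
fourier_score <- function(fit) {
  stopifnot(inherits(fit, "sinusoid_fit"))
  fit$halfamp
}

# ---- AR(1) noise model -----------------------------------------------------

# Theoretical lag-1 autocorrelation of harmonic-fit residuals and the trace
# of the projected AR(1) correlation matrix: detrending a short series
# biases the residual autocorrelation, and these exact (finite-n) values let
# a moment estimator undo that bias.
resid_acf1_theory <- function(phi, design, ratio_bias = FALSE) {
  n <- nrow(design$G)
  M <- design$G %*% toeplitz(phi^(0:(n - 1))) %*% design$G
  tr <- sum(diag(M))
  a1 <- sum(M[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)]) / tr
  if (ratio_bias) {
    # second-order expectation of the ratio statistic r'Ar / r'r (normal
    # quadratic forms): E[N/D] ~ a - Cov(N,D)/E[D]^2 + a Var(D)/E[D]^2
    A <- matrix(0, n, n)
    A[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- 0.5
    A <- A + t(A)
    AM <- A %*% M
    a1 <- a1 + (-2 * sum(AM * t(M)) + a1 * 2 * sum(M * t(M))) / tr^2
  }
  list(a1 = a1, tr = tr)
}

# delta-method sampling variance of the residual lag-1 autocorrelation at a
# given phi (normal theory, quadratic-form traces); used to set the
# empirical-Bayes shrinkage weight for per-series phi estimates.
resid_acf1_var <- function(phi, design) {
  n <- nrow(design$G)
  S <- design$G %*% toeplitz(phi^(0:(n - 1))) %*% design$G
  A <- matrix(0, n, n)
  A[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- 0.5
  A <- A + t(A)
  AS <- A %*% S
  trS <- sum(diag(S))
  a <- sum(diag(AS)) / trS
  varN <- 2 * sum(AS * t(AS))
  varD <- 2 * sum(S * t(S))
  covND <- 2 * sum(AS * t(S))
  var_a1 <- (varN - 2 * a * covND + a^2 * varD) / trS^2
  h <- 1e-3
  da <- (resid_acf1_theory(min(phi + h, 0.995), design)$a1 -
           resid_acf1_theory(max(phi - h, -0.995), design)$a1) / (2 * h)
  var_a1 / max(da^2, 1e-12)
}

#' Fit an AR(1) noise model to a timecourse
#'
#' Estimates the AR(1) coefficient and innovation sd of the observation
#' noise. By default the 24-h harmonic is removed first and the estimate is
#' a moment match on the residuals: phi solves
#' `observed residual lag-1 autocorrelation = its theoretical value under
#' AR(1) noise after the same projection`, and the stationary variance is
#' `RSS / tr((I-P) R(phi))` — both corrections matter on short series,
#' where naive residual autocorrelations are strongly biased. For series
#' longer than ~60 points the projection effect is negligible and the plain
#' residual autocorrelation is used. `detrend = FALSE` uses the
#' mean-subtracted series directly (appropriate only when no periodic
#' signal is present).
#'
#' @param times sampling times (hours).
#' @param values log2 abundances.
#' @param period harmonic period removed when detrending (default 24).
#' @param detrend remove the fitted harmonic before estimating (default
#'   TRUE).
#' @param phi_max clamp bound for |phi| (default 0.99, with a warning when
#'   hit).
#' @return list of class `ar1_null`: `phi`, `innovation_sd`, `gamma0`
#'   (stationary variance), `rss`, `n`, `degenerate`.
#' @export
fit_ar1 <- function(times, values, period = 24, detrend = TRUE,
                    phi_max = 0.99, quiet = FALSE) {
  keep <- is.finite(values) & is.finite(times)
  times <- times[keep]; values <- values[keep]
  n <- length(values)
  if (n < 8) abort("fit_ar1(): need at least 8 points.")
  if (detrend) {
    d <- get_design(times, period)
    r <- drop(d$G %*% values)
  } else {
    r <- values - mean(values)
    d <- NULL
  }
  rss <- sum(r^2)
  if (rss < 1e-24) {
    return(structure(list(phi = 0, innovation_sd = 0, gamma0 = 0, rss = 0,
                          n = n, degenerate = TRUE), class = "ar1_null"))
  }
  a1_obs <- sum(r[-1] * r[-n]) / rss
  if (detrend && n <= 60) {
    f <- function(p) resid_acf1_theory(p, d, ratio_bias = TRUE)$a1 - a1_obs
    lo <- -phi_max; hi <- phi_max
    flo <- f(lo); fhi <- f(hi)
    phi <- if (flo * fhi > 0) {
      if (!quiet) warn("fit_ar1(): phi estimate at clamp boundary.")
      if (abs(flo) < abs(fhi)) lo else hi
    } else uniroot(f, c(lo, hi), tol = 1e-5)$root
    gamma0 <- rss / resid_acf1_theory(phi, d)$tr
  } else {
    phi <- a1_obs
    if (abs(phi) >= phi_max) {
      if (!quiet) warn("fit_ar1(): phi estimate clamped.")
      phi <- sign(phi) * phi_max
    }
    dof <- if (detrend) n - 3 else n - 1
    gamma0 <- rss / dof
  }
  structure(list(phi = phi,
                 innovation_sd = sqrt(max(0, (1 - phi^2) * gamma0)),
                 gamma0 = gamma0, rss = rss, n = n, degenerate = FALSE),
            class = "ar1_null")
}

# studentized harmonic score for a matrix of series (columns):
# F / sqrt(RSS / tr), where tr = tr((I-P) R(phi)) makes RSS/tr an unbiased
# stationary-variance estimate. Pivotal given phi, so per-series noise-scale
# estimation error cancels between observed and simulated series.
studentized_scores <- function(Y, design, tr_resid) {
  cf <- design$Hm %*% Y
  Fv <- sqrt(cf[2, ]^2 + cf[3, ]^2)
  rss <- colSums((Y - design$X %*% cf)^2)
  g0 <- rss / tr_resid
  stat <- ifelse(g0 > 1e-24, Fv / sqrt(g0), ifelse(Fv > 1e-12, Inf, 0))
  list(F = Fv, stat = stat)
}

#' Simulate the null score distribution for one series
#'
#' Generates `n_sims` stationary AR(1) series on the observed time grid with
#' the fitted noise parameters, fits the 24-h harmonic to each, and returns
#' both the raw Fourier scores and the variance-studentized scores used for
#' p-value comparison.
#'
#' @param null an `ar1_null` (see [fit_ar1()]); `phi`/`gamma0` may be
#'   overridden.
#' @param times the observed time grid.
#' @param n_sims number of simulated series (default 1000).
#' @param seed integer seed for this series' stream.
#' @param period harmonic period (default 24).
#' @return tibble with columns `F` and `stat`, one row per simulation.
#' @export
simulate_null_scores <- function(null, times, n_sims = 1000, seed = 1,
                                 period = 24) {
  d <- get_design(times, period)
  n <- length(times)
  tr <- if (null$gamma0 > 0) resid_acf1_theory(null$phi, d)$tr else n - 3
  withr::with_seed(as.integer(seed), {
    Y <- ar1_noise(n, n_sims, null$phi, null$innovation_sd)
    sc <- studentized_scores(Y, d, tr)
    tibble(F = sc$F, stat = sc$stat)
  })
}

#' Empirical p-value for a cycling score
#'
#' Add-one empirical comparison: `p = (1 + #{null >= observed}) / (B + 1)`,
#' bounded below by `1/(B+1)` so downstream multiple-testing machinery is
#' well defined.
#'
#' @param stat_obs observed score.
#' @param null_stats numeric vector of simulated null scores.
#' @return the p-value.
#' @export
cycling_pvalue <- function(stat_obs, null_stats) {
  B <- length(null_stats)
  if (B == 0) abort("cycling_pvalue(): empty null distribution.")
  (1 + sum(null_stats >= stat_obs)) / (B + 1)
}

#' q-values with polynomial pi0 estimation
#'
#' Storey-style false-discovery-rate q-values: `pi0(lambda) =
#' #\{p > lambda\} / (m (1 - lambda))` on a lambda grid, smoothed by a cubic
#' polynomial and evaluated at the grid maximum (clamped to (0, 1]); then
#' step-up q-values `q_i = min_\{p_j >= p_i\} pi0 m p_j / rank(p_j)`, with
#' the robust variant dividing by `1 - (1 - p_j)^m` (guards small
#' collections), clamped to \[0, 1\] and monotone in p.
#'
#' @param pvals p-values in (0, 1].
#' @param lambda_grid grid for pi0 estimation (default 0, 0.05, ..., 0.90).
#' @param pi0_method `"polynomial"` (cubic fit) or `"fixed"` (use `pi0`).
#' @param pi0 fixed pi0 when `pi0_method = "fixed"`.
#' @param robust use the robust q-value modifier (default TRUE).
#' @return list: `qvalues` (same order as `pvals`), `pi0`, `summary`
#'   (one-row tibble: pi0, method, lambda max, m).
#' @export
estimate_qvalues <- function(pvals, lambda_grid = seq(0, 0.90, by = 0.05),
                             pi0_method = c("polynomial", "fixed"),
                             pi0 = NULL, robust = TRUE) {
  pi0_method <- match.arg(pi0_method)
  m <- length(pvals)
  if (m == 0) abort("estimate_qvalues(): no p-values supplied.")
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1)) {
    abort("estimate_qvalues(): p-values must lie in (0, 1].")
  }
  if (pi0_method == "fixed") {
    stopifnot(!is.null(pi0), pi0 > 0, pi0 <= 1)
    pi0_hat <- pi0
  } else {
    pl <- vapply(lambda_grid, function(l) mean(pvals > l) / (1 - l),
                 numeric(1))
    cf <- stats::lm(pl ~ stats::poly(lambda_grid, degree = 3, raw = TRUE))
    pi0_hat <- unname(stats::predict(cf,
      newdata = data.frame(lambda_grid = max(lambda_grid))))
    pi0_hat <- min(max(pi0_hat, 1 / m), 1)
  }
  o <- order(pvals)
  ps <- pvals[o]
  denom <- seq_len(m)
  q_raw <- pi0_hat * m * ps / denom
  if (robust) q_raw <- q_raw / (1 - (1 - ps)^m)
  q_sorted <- rev(cummin(rev(pmin(q_raw, 1))))
  q <- numeric(m)
  q[o] <- q_sorted
  list(qvalues = q, pi0 = pi0_hat,
       summary = tibble(pi0 = pi0_hat, method = pi0_method,
                        lambda_max = max(lambda_grid), m = m,
                        robust = robust))
}

#' Detect 24-h rhythmicity in a collection of timecourses
#'
#' For every series: fits the 24-h harmonic ([fit_sinusoid_24h()]), fits an
#' AR(1) noise model to the residuals ([fit_ar1()]), simulates a per-series
#' null score distribution ([simulate_null_scores()]) and derives an
#' empirical p-value, then computes q-values across the collection
#' ([estimate_qvalues()]). Per-series AR(1) coefficients are moderated by
#' empirical-Bayes shrinkage toward the collection's pooled value (the
#' per-series estimate from ~14 points is noisy; its delta-method sampling
#' variance and the observed cross-series spread set the shrinkage weight).
#' Series with fewer than `min_points` retained points are reported
#' unresolvable.
#'
#' @param timecourses tibble with columns `gene_id` (or `id`), `time_h`,
#'   `log2_abundance`, optional `level` and logical `mask` (FALSE drops a
#'   point) and optional `weight`.
#' @param n_sims simulated null series per gene (default 1000).
#' @param seed master seed; per-series streams are derived from it and the
#'   series id.
#' @param q_cutoff significance cutoff on q (default 0.05).
#' @param min_points minimum retained points to fit (default 8).
#' @param moderate_phi shrink per-series phi toward the pooled value
#'   (default TRUE).
#' @param period oscillation period (default 24 h).
#' @return object of class `diel_cycling`: `results` tibble (per series:
#'   `gene_id`, `level`, `n_points`, `mesor`, `halfamp`, `fold_change`,
#'   `phase`, `F`, `stat`, `phi`, `p`, `q`, `significant`, `resolvable`),
#'   `pi0`, `phi_pooled`, `q_cutoff`, `n_sims`, `seed`.
#' @export
detect_cycling <- function(timecourses, n_sims = 1000, seed = 1,
                           q_cutoff = 0.05, min_points = 8,
                           moderate_phi = TRUE, period = 24) {
  tc <- as_tibble(timecourses)
  if (!"gene_id" %in% names(tc) && "id" %in% names(tc)) {
    tc <- rename(tc, gene_id = "id")
  }
  if (!"level" %in% names(tc)) tc$level <- "other"
  if ("mask" %in% names(tc)) tc <- dplyr::filter(tc, .data$mask)
  if (dplyr::n_distinct(tc$level) > 1) {
    abort("detect_cycling(): supply one expression level at a time.")
  }
  nested <- tc |>
    arrange(.data$gene_id, .data$time_h) |>
    tidyr::nest(.by = c("gene_id", "level"))

  per <- purrr::map(nested$data, function(df) {
    keep <- is.finite(df$log2_abundance)
    t <- df$time_h[keep]; y <- df$log2_abundance[keep]
    if (length(y) < min_points) return(NULL)
    fit <- fit_sinusoid_24h(t, y, period = period, min_points = min_points)
    nullm <- fit_ar1(t, y, period = period, detrend = TRUE, quiet = TRUE)
    list(fit = fit, null = nullm, times = t, values = y)
  })
  ok <- !purrr::map_lgl(per, is.null)

  phis <- purrr::map_dbl(per[ok], ~ .x$null$phi)
  phi_pooled <- if (length(phis)) median(phis) else 0
  if (moderate_phi && sum(ok) > 1) {
    # shrinkage weight from delta-method sampling variance at the pooled phi
    d0 <- get_design(per[ok][[1]]$times, period)
    v_s <- resid_acf1_var(phi_pooled, d0)
    tau2 <- max(0, var(phis) - v_s)
    wgt <- tau2 / (tau2 + v_s)
  } else {
    wgt <- 1
  }

  res <- purrr::map_dfr(seq_len(nrow(nested)), function(i) {
    base <- tibble(gene_id = nested$gene_id[i], level = nested$level[i])
    x <- per[[i]]
    if (is.null(x)) {
      return(mutate(base, n_points = sum(is.finite(nested$data[[i]]$log2_abundance)),
                    mesor = NA_real_, halfamp = NA_real_,
                    fold_change = NA_real_, phase = NA_real_, F = NA_real_,
                    stat = NA_real_, phi = NA_real_, p = NA_real_,
                    resolvable = FALSE))
    }
    phi_i <- phi_pooled + wgt * (x$null$phi - phi_pooled)
    d <- get_design(x$times, period)
    tr <- resid_acf1_theory(phi_i, d)$tr
    gamma0 <- x$null$rss / tr
    sc_obs <- studentized_scores(matrix(x$values), d, tr)
    nulli <- structure(list(phi = phi_i,
                            innovation_sd = sqrt(max(0, (1 - phi_i^2) * gamma0)),
                            gamma0 = gamma0, rss = x$null$rss,
                            n = length(x$values), degenerate = gamma0 <= 0),
                       class = "ar1_null")
    nsc <- simulate_null_scores(nulli, x$times, n_sims = n_sims,
                                seed = derive_seed(seed, "null",
                                                   nested$gene_id[i]),
                                period = period)
    mutate(base, n_points = length(x$values), mesor = x$fit$mesor,
           halfamp = x$fit$halfamp, fold_change = x$fit$fold_change,
           phase = x$fit$phase, F = fourier_score(x$fit),
           stat = sc_obs$stat[1], phi = phi_i,
           p = cycling_pvalue(sc_obs$stat[1], nsc$stat),
           resolvable = TRUE)
  })

  qv <- estimate_qvalues(res$p[res$resolvable])
  res$q <- NA_real_
  res$q[res$resolvable] <- qv$qvalues
  res$significant <- !is.na(res$q) & res$q <= q_cutoff
  structure(list(results = res, pi0 = qv$pi0, phi_pooled = phi_pooled,
                 phi_shrinkage = wgt, q_cutoff = q_cutoff,
                 n_sims = n_sims, seed = seed,
                 multiple_testing = qv$summary),
            class = "diel_cycling")
}

#' @export
print.diel_cycling <- function(x, ...) {
  r <- x$results
  cat("<diel_cycling>\n")
  cat(sprintf("  %d series (%d resolvable); %d significant at q <= %g; pi0 = %.3f; pooled phi = %.3f\n",
              nrow(r), sum(r$resolvable), sum(r$significant), x$q_cutoff,
              x$pi0, x$phi_pooled))
  invisible(x)
}

#' Sensitivity/specificity-corrected cycling proportion
#'
#' Corrects an observed significant-call rate for the test's operating
#' characteristics: `pi = (observed_rate + specificity - 1) /
#' (sensitivity + specificity - 1)`, clamped to \[0, 1\]; the corrected
#' count is `round(pi * n_total)`.
#'
#' @param n_significant number of significant calls.
#' @param n_total number of tested series.
#' @param sensitivity,specificity operating characteristics (their sum must
#'   exceed 1; see [estimate_operating_characteristics()]).
#' @return tibble: `corrected_proportion`, `corrected_count`,
#'   `observed_rate`.
#' @examples
#' estimate_cycling_proportion(680, 1000, 0.80, 0.95)
#' @export
estimate_cycling_proportion <- function(n_significant, n_total,
                                        sensitivity, specificity) {
  if (sensitivity + specificity <= 1) {
    abort("estimate_cycling_proportion(): sensitivity + specificity must exceed 1 (non-informative test).")
  }
  rate <- n_significant / n_total
  pi_hat <- (rate + specificity - 1) / (sensitivity + specificity - 1)
  pi_hat <- min(max(pi_hat, 0), 1)
  tibble(corrected_proportion = pi_hat,
         corrected_count = round(pi_hat * n_total),
         observed_rate = rate)
}

#' Estimate the cycling test's sensitivity and specificity
#'
#' Simulates the test's operating point at the realized significance
#' threshold (the largest p among significant calls): sensitivity from
#' synthetic cyclers whose half-amplitudes and noise levels are resampled
#' from the significant fits, specificity from synthetic AR(1) null series
#' with noise resampled from all resolvable fits.
#'
#' @param cycling a `diel_cycling` object.
#' @param times the sampling grid the series share.
#' @param n_rep simulated series per arm (default 200).
#' @param n_sims nulls per simulated series (default `cycling$n_sims`).
#' @param seed stream seed.
#' @return tibble: `sensitivity`, `specificity`, `p_threshold`.
#' @export
estimate_operating_characteristics <- function(cycling, times, n_rep = 200,
                                               n_sims = NULL, seed = 1) {
  stopifnot(inherits(cycling, "diel_cycling"))
  r <- dplyr::filter(cycling$results, .data$resolvable)
  sig <- dplyr::filter(r, .data$significant)
  if (nrow(sig) == 0 || nrow(sig) == nrow(r)) {
    return(tibble(sensitivity = NA_real_, specificity = NA_real_,
                  p_threshold = NA_real_))
  }
  n_sims <- n_sims %||% cycling$n_sims
  p_cut <- max(sig$p)
  phi <- cycling$phi_pooled
  d <- get_design(times)
  tr <- resid_acf1_theory(phi, d)$tr
  # residual stationary variance implied by each fit's studentized score
  g0_all <- (r$F / r$stat)^2
  g0_all[!is.finite(g0_all)] <- median(g0_all[is.finite(g0_all)])
  g0_sig <- g0_all[r$significant]
  run_arm <- function(gen, key) {
    hits <- withr::with_seed(derive_seed(seed, key), {
      draws <- gen()
      vapply(seq_len(n_rep), function(j) {
        y <- draws$signal[, j] +
          ar1_noise(length(times), 1, phi,
                    sqrt((1 - phi^2) * draws$g0[j]))[, 1]
        so <- studentized_scores(matrix(y), d, tr)$stat[1]
        ns <- studentized_scores(
          ar1_noise(length(times), n_sims, phi,
                    sqrt((1 - phi^2) * draws$g0[j])), d, tr)$stat
        cycling_pvalue(so, ns) <= p_cut
      }, logical(1))
    })
    mean(hits)
  }
  sens <- run_arm(function() {
    idx <- sample.int(nrow(sig), n_rep, replace = TRUE)
    ph <- runif(n_rep, 0, 24)
    sigm <- vapply(seq_len(n_rep), function(j) {
      sig$halfamp[idx[j]] * cos(2 * pi / 24 * (times - ph[j]))
    }, numeric(length(times)))
    list(signal = sigm, g0 = g0_sig[idx])
  }, "sens")
  spec <- 1 - run_arm(function() {
    idx <- sample.int(length(g0_all), n_rep, replace = TRUE)
    list(signal = matrix(0, length(times), n_rep), g0 = g0_all[idx])
  }, "spec")
  tibble(sensitivity = sens, specificity = spec, p_threshold = p_cut)
}
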