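#' Orient peak ratios to sample:standard
#'
#' Isotope-labelling designs report heavy:light or light:heavy ratios
#' depending on the integration software; downstream code works on the
#' sample:standard orientation (here the unlabelled sample over the labelled
#' standard, i.e. light:heavy). Ratios are reciprocal-flipped when needed;
#' nonpositive ratios cannot be oriented and are rejected.
#'
#' @param peaks tibble with at least `peak_id` and `ratio` columns.
#' @param orientation orientation of the *input* ratios.
#' @return The peaks tibble in sample:standard orientation, with rejected
#'   rows removed; the rejected rows are attached as attribute `"rejected"`.
#' @examples
#' pk <- tibble::tibble(peak_id = "p1", ratio = 2, cv = 0.1)
#' orient_ratios(pk, "heavy_over_light")$ratio # 0.5
#' @export
orient_ratios <- function(peaks,
                          orientation = c("light_over_heavy",
                                          "heavy_over_light")) {
  orientation <- match.arg(orientation)
  bad <- !is.finite(peaks$ratio) | peaks$ratio <= 0
  rejected <- peaks[bad, , drop = FALSE]
  out <- peaks[!bad, , drop = FALSE]
  if (orientation == "heavy_over_light") out$ratio <- 1 / out$ratio
  attr(out, "rejected") <- rejected
  out
}

#' Filter peaks by CV percentile
#'
#' Marks peaks whose reported CV strictly exceeds the configured percentile
#' of the pooled CV distribution (linear-interpolation percentile, one
#' global threshold for the whole run). The realized threshold is attached
#' so the percentile/CV correspondence can be audited against any dataset.
#'
#' @param peaks tibble with a `cv` column.
#' @param percentile percentile of the CV ranking retained (default 80).
#' @return peaks with an `excluded_by` column (`"none"` or `"cv_filter"`);
#'   attribute `"cv_threshold"` holds the realized CV threshold.
#' @export
filter_by_cv <- function(peaks, percentile = 80) {
  if (nrow(peaks) == 0) abort("filter_by_cv(): no peaks supplied.")
  thr <- unname(quantile(peaks$cv, percentile / 100, type = 7))
  out <- mutate(peaks,
                excluded_by = if_else(.data$cv > thr, "cv_filter", "none"))
  attr(out, "cv_threshold") <- thr
  out
}

#' Median-centre log2 peak ratios per timepoint
#'
#' Compensates for per-timepoint deviations of the sample:standard mixing
#' ratio from 1:1 by subtracting, at each timepoint, the median of the
#' retained peaks' log2 ratios from every peak at that timepoint. After the
#' adjustment each timepoint's retained log2 ratios have median 0.
#'
#' @param peaks tibble with `ratio`, `timepoint_index` and (optionally)
#'   `excluded_by`; offsets are computed from retained peaks only but
#'   applied to all peaks at the timepoint.
#' @return peaks with a `log2_ratio` column (adjusted); attribute
#'   `"offsets"` is a tibble of the per-timepoint medians subtracted.
#' @export
normalize_timepoint_medians <- function(peaks) {
  out <- peaks
  if (!"log2_ratio" %in% names(out)) out$log2_ratio <- log2(out$ratio)
  keep <- if ("excluded_by" %in% names(out)) out$excluded_by == "none" else TRUE
  offs <- out[keep, ] |>
    group_by(.data$timepoint_index) |>
    summarise(offset = median(.data$log2_ratio), n_retained = n(),
              .groups = "drop")
  empty_tp <- setdiff(unique(out$timepoint_index), offs$timepoint_index)
  if (length(empty_tp)) {
    warn(paste0("No retained peaks at timepoint(s) ",
                paste(empty_tp, collapse = ", "),
                "; offsets undefined there, timepoint left unadjusted."))
  }
  idx <- match(out$timepoint_index, offs$timepoint_index)
  adj <- ifelse(is.na(idx), 0, offs$offset[idx])
  out$log2_ratio <- out$log2_ratio - adj
  attr(out, "offsets") <- offs
  out
}

#' Flag inconsistent peak ratios within a protein-timepoint group
#'
#' Scale-invariant inconsistency score: for each value the mean absolute
#' difference to the other group members, divided by the grand mean of all
#' pairwise absolute differences in the group. Values whose score exceeds
#' `cutoff` are flagged. Groups smaller than `min_group` are returned
#' unflagged (too few peaks to judge consistency), as are zero-dispersion
#' groups. This is the package's concrete reconstruction of an
#' integrated-inconsistent-rate style filter; the cutoff's meaning is "this
#' peak disagrees with the group about `cutoff` times more than average".
#'
#' @param x numeric log2 ratios of one protein at one timepoint.
#' @param cutoff flag threshold (default 1.81).
#' @param min_group smallest group size tested (default 4).
#' @return logical outlier flags, same length as `x`.
#' @examples
#' detect_peak_outliers_iir(c(0, 0.1, -0.1, 5)) # last value flagged
#' @export
detect_peak_outliers_iir <- function(x, cutoff = 1.81, min_group = 4) {
  n <- length(x)
  if (n < min_group) return(rep(FALSE, n))
  d <- abs(outer(x, x, "-"))
  grand <- sum(d) / (n * (n - 1)) # mean over ordered pairs = unordered mean
  if (grand == 0) return(rep(FALSE, n))
  score <- rowSums(d) / (n - 1) / grand
  score > cutoff
}

#' Small-sample correction factor for the standard error of a mean
#'
#' `c_N = sqrt((N-1)/2) * Gamma((N-1)/2) / Gamma(N/2)`: multiplying the
#' sample standard deviation (N-1 divisor) by `c_N` makes it an unbiased
#' estimate of the population standard deviation under normality. `c_N > 1`,
#' decreasing in N, tending to 1.
#'
#' @param N group size(s), each >= 2.
#' @return the correction factor(s).
#' @examples
#' gurland_cN(2)  # sqrt(pi/2) ~ 1.2533
#' gurland_cN(10) # ~ 1.0281
#' @export
gurland_cN <- function(N) {
  if (any(N < 2)) abort("gurland_cN(): N must be >= 2.")
  exp(0.5 * log((N - 1) / 2) + lgamma((N - 1) / 2) - lgamma(N / 2))
}

#' Lognormal protein-ratio estimate for one protein-timepoint group
#'
#' Fits a lognormal by maximum likelihood to the (linear-scale) peak ratios:
#' `mu`, `sigma` are the mean and MLE sd of the natural-log ratios. The
#' protein ratio is the fitted lognormal mean `exp(mu + sigma^2/2)`,
#' reported in log2. The 95% CI is `ratio +/- 1.96 * c_N * s / sqrt(N)` on
#' the linear scale (then log2-transformed, so it may be asymmetric in log2
#' units), where `s` is the lognormal standard deviation
#' `sqrt(exp(sg^2)-1) * exp(mu + sg^2/2)` computed with the unbiased (N-1)
#' log-variance `sg^2` so the Gurland factor applies, and `c_N` is
#' [gurland_cN()]. With a single peak the estimate is that peak's ratio and
#' the CI is flagged unavailable.
#'
#' @param log2_ratios numeric log2 peak ratios of one protein-timepoint.
#' @return one-row tibble: `log2_ratio`, `ci_low`, `ci_high`, `n_peaks`,
#'   `s` (linear-scale lognormal sd), `ci_defined`.
#' @export
estimate_protein_ratio <- function(log2_ratios) {
  x <- log2_ratios[is.finite(log2_ratios)]
  N <- length(x)
  if (N == 0) abort("estimate_protein_ratio(): no ratios supplied.")
  lx <- x * log(2) # natural log of the linear ratios
  mu <- mean(lx)
  if (N == 1) {
    return(tibble(log2_ratio = x, ci_low = NA_real_, ci_high = NA_real_,
                  n_peaks = 1L, s = NA_real_, ci_defined = FALSE))
  }
  sig2_ml <- mean((lx - mu)^2)      # MLE, N divisor: the point estimate
  sig2_ub <- var(lx)                # N-1 divisor: feeds the CI via s
  point_lin <- exp(mu + sig2_ml / 2)
  s <- sqrt(exp(sig2_ub) - 1) * exp(mu + sig2_ub / 2)
  half <- 1.96 * gurland_cN(N) * s / sqrt(N)
  lo <- point_lin - half
  hi <- point_lin + half
  tibble(log2_ratio = log2(point_lin),
         ci_low = if (lo > 0) log2(lo) else -Inf,
         ci_high = log2(hi),
         n_peaks = as.integer(N),
         s = s,
         ci_defined = TRUE)
}

#' Select timepoints for one protein's timecourse
#'
#' Applies the threshold-lowering rule: with k starting at 4, a timepoint
#' enters the timecourse if it has at least k retained peaks; if fewer than
#' `min_timepoints` timepoints qualify, k is lowered (3, 2, 1) until enough
#' do. If even k = 1 leaves fewer than `min_timepoints` timepoints the
#' protein is detected but unresolvable and no timecourse is built.
#'
#' @param n_peaks_per_tp named or plain integer vector of retained peak
#'   counts per timepoint.
#' @param min_timepoints minimum timepoints required (default 8).
#' @param start_threshold initial peaks-per-timepoint threshold (default 4).
#' @return list `threshold` (k used, or NA) and `include` (logical per
#'   timepoint).
#' @export
select_timecourse_timepoints <- function(n_peaks_per_tp, min_timepoints = 8,
                                         start_threshold = 4) {
  for (k in seq(start_threshold, 1)) {
    inc <- n_peaks_per_tp >= k
    if (sum(inc) >= min_timepoints) {
      return(list(threshold = as.integer(k), include = inc))
    }
  }
  list(threshold = NA_integer_, include = rep(FALSE, length(n_peaks_per_tp)))
}

#' Flag outlier timepoints by summed nearest-neighbour distance
#'
#' For each point the absolute differences to its temporal neighbours are
#' summed (endpoints count their single neighbour twice); a point is flagged
#' when its summed distance exceeds `factor` times the timecourse mean of
#' those distances. No temporal model is assumed. Constant series (mean
#' distance 0) and series shorter than 3 points are returned unflagged.
#'
#' @param values numeric log2 ratios ordered in time.
#' @param factor flag multiplier (default 4.15).
#' @return logical flags, same length as `values`.
#' @export
detect_timepoint_outliers <- function(values, factor = 4.15) {
  n <- length(values)
  if (n < 3) {
    warn("detect_timepoint_outliers(): fewer than 3 points, none flagged.")
    return(rep(FALSE, n))
  }
  left <- c(NA, abs(diff(values)))
  right <- c(abs(diff(values)), NA)
  d <- ifelse(is.na(left), 2 * right, ifelse(is.na(right), 2 * left,
                                             left + right))
  m <- mean(d)
  if (m == 0) return(rep(FALSE, n))
  d > factor * m
}

#' Roll a peak-ratio table up to protein abundance timecourses
#'
#' Runs the full rollup in its fixed order: orient ratios, CV-percentile
#' filter, log2 transform, per-timepoint median normalization, per-group
#' inconsistency (IIR-style) outlier flags, lognormal ratio estimation with
#' Gurland-corrected CIs, timepoint selection under the threshold-lowering
#' rule, and nearest-neighbour timepoint outlier flags. An audit of record
#' counts at every stage accompanies the result; `peaks_in` always equals
#' `retained + cv_filtered + iir_flagged + rejected`.
#'
#' @param peaks tibble `peak_id`, `protein_id`, `timepoint_index`, `time_h`,
#'   `ratio`, `cv`.
#' @param cv_percentile CV-ranking percentile retained (default 80).
#' @param iir_cutoff inconsistency score cutoff (default 1.81).
#' @param nn_factor nearest-neighbour distance multiplier (default 4.15).
#' @param min_timepoints minimum timepoints per timecourse (default 8).
#' @param start_threshold starting peaks-per-timepoint threshold (default 4).
#' @param orientation orientation of the input ratios (see
#'   [orient_ratios()]).
#' @return list of class `proteome_quant`:
#'   * `timecourses`: tibble `protein_id`, `timepoint_index`, `time_h`,
#'     `log2_ratio`, `ci_low`, `ci_high`, `n_peaks`, `s`, `outlier_flag`,
#'     `peaks_threshold_used`;
#'   * `peaks`: the annotated peak table (with `excluded_by`, `log2_ratio`);
#'   * `audit`: stage-by-stage record counts, per-timepoint offsets, the
#'     realized CV threshold, and the number of unresolvable proteins.
#' @export
quantify_proteome <- function(peaks,
                              cv_percentile = 80,
                              iir_cutoff = 1.81,
                              nn_factor = 4.15,
                              min_timepoints = 8,
                              start_threshold = 4,
                              orientation = "light_over_heavy") {
  n_in <- nrow(peaks)
  oriented <- orient_ratios(peaks, orientation)
  n_rejected <- nrow(attr(oriented, "rejected"))

  flt <- filter_by_cv(oriented, cv_percentile)
  cv_threshold <- attr(flt, "cv_threshold")

  nrm <- normalize_timepoint_medians(flt)
  offsets <- attr(nrm, "offsets")

  # IIR pass within protein x timepoint groups of >= 4 retained peaks
  nrm <- nrm |>
    group_by(.data$protein_id, .data$timepoint_index) |>
    mutate(excluded_by = {
      keep <- .data$excluded_by == "none"
      fl <- rep(FALSE, length(keep))
      if (sum(keep) >= 4) {
        fl[keep] <- detect_peak_outliers_iir(.data$log2_ratio[keep],
                                             cutoff = iir_cutoff)
      }
      if_else(fl, "iir_outlier", .data$excluded_by)
    }) |>
    ungroup()

  retained <- dplyr::filter(nrm, .data$excluded_by == "none")

  per_protein <- retained |>
    tidyr::nest(.by = "protein_id") |>
    mutate(tc = purrr::map(.data$data, function(df) {
      cnt <- df |>
        group_by(.data$timepoint_index, .data$time_h) |>
        summarise(n = n(), .groups = "drop") |>
        arrange(.data$timepoint_index)
      sel <- select_timecourse_timepoints(cnt$n, min_timepoints,
                                          start_threshold)
      if (is.na(sel$threshold)) return(NULL)
      keep_tp <- cnt$timepoint_index[sel$include]
      est <- purrr::map_dfr(keep_tp, function(ti) {
        grp <- df$log2_ratio[df$timepoint_index == ti]
        e <- estimate_protein_ratio(grp)
        e$timepoint_index <- ti
        e$time_h <- df$time_h[df$timepoint_index == ti][1]
        e
      }) |> arrange(.data$timepoint_index)
      est$outlier_flag <- detect_timepoint_outliers(est$log2_ratio,
                                                    factor = nn_factor)
      est$peaks_threshold_used <- sel$threshold
      est
    }))
  unresolvable <- per_protein$protein_id[purrr::map_lgl(per_protein$tc, is.null)]
  tc_cols <- c("protein_id", "timepoint_index", "time_h", "log2_ratio",
               "ci_low", "ci_high", "n_peaks", "s", "ci_defined",
               "outlier_flag", "peaks_threshold_used")
  resolved <- dplyr::filter(per_protein,
                            !purrr::map_lgl(.data$tc, is.null))
  tcs <- if (nrow(resolved) == 0) {
    tibble(protein_id = character(), timepoint_index = integer(),
           time_h = numeric(), log2_ratio = numeric(), ci_low = numeric(),
           ci_high = numeric(), n_peaks = integer(), s = numeric(),
           ci_defined = logical(), outlier_flag = logical(),
           peaks_threshold_used = integer())
  } else {
    resolved |>
      dplyr::select("protein_id", "tc") |>
      tidyr::unnest("tc") |>
      dplyr::select(all_of(tc_cols))
  }

  audit <- list(
    peaks_in = n_in,
    rejected_nonpositive = n_rejected,
    cv_filtered = sum(nrm$excluded_by == "cv_filter"),
    iir_flagged = sum(nrm$excluded_by == "iir_outlier"),
    retained = nrow(retained),
    retained_fraction = nrow(retained) / n_in,
    cv_threshold = cv_threshold,
    timepoint_offsets = offsets,
    timepoint_outliers_flagged = sum(tcs$outlier_flag),
    proteins_detected = dplyr::n_distinct(peaks$protein_id),
    proteins_resolvable = dplyr::n_distinct(tcs$protein_id),
    proteins_unresolvable = length(unresolvable))
  structure(list(timecourses = tcs, peaks = nrm, audit = audit),
            class = "proteome_quant")
}

#' @export
print.proteome_quant <- function(x, ...) {
  a <- x$audit
  cat("<proteome_quant>\n")
  cat(sprintf("  peaks: %d in; %d retained (%.1f%%), %d CV-filtered, %d IIR-flagged, %d rejected\n",
              a$peaks_in, a$retained, 100 * a$retained_fraction,
              a$cv_filtered, a$iir_flagged, a$rejected_nonpositive))
  cat(sprintf("  realized CV threshold: %.3f\n", a$cv_threshold))
  cat(sprintf("  proteins: %d detected, %d resolvable timecourses\n",
              a$proteins_detected, a$proteins_resolvable))
  invisible(x)
}
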