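pk_tbl <- function(ratio, cv = 0.1, tp = 0L, protein = "p1") {
  tibble::tibble(peak_id = sprintf("k%03d", seq_along(ratio)),
                 protein_id = protein, timepoint_index = tp,
                 time_h = 2 * tp, ratio = ratio, cv = cv)
}

test_that("ratio orientation flips reciprocals and rejects nonpositive", {
  pk <- pk_tbl(c(2, 1, 0, -1))
  out <- orient_ratios(pk, "heavy_over_light")
  expect_equal(out$ratio, c(0.5, 1))
  expect_equal(nrow(attr(out, "rejected")), 2)
  same <- orient_ratios(pk_tbl(c(2, 1)), "light_over_heavy")
  expect_equal(same$ratio, c(2, 1))
})

test_that("CV filter uses the interpolated percentile with strict exclusion", {
  pk <- pk_tbl(rep(1, 10), cv = seq(0.01, 0.10, by = 0.01))
  out <- filter_by_cv(pk, percentile = 80)
  expect_equal(attr(out, "cv_threshold"), 0.082)
  expect_equal(out$excluded_by, c(rep("none", 8), "cv_filter", "cv_filter"))
  # ties: all CVs equal -> nothing excluded
  tied <- filter_by_cv(pk_tbl(rep(1, 6), cv = 0.3))
  expect_true(all(tied$excluded_by == "none"))
  expect_error(filter_by_cv(pk_tbl(numeric(0))), "no peaks")
})

test_that("CV filter retains exactly the configured mass on continuous CVs", {
  withr::with_seed(10, {
    pk <- pk_tbl(rep(1, 10000), cv = rgamma(10000, 2.78, 7))
  })
  out <- filter_by_cv(pk, 80)
  expect_equal(sum(out$excluded_by == "none"), 8000)
})

test_that("median normalization centres each timepoint and is idempotent", {
  pk <- dplyr::bind_rows(pk_tbl(c(1, 2, 4), tp = 0L),
                         pk_tbl(c(8, 8, 8), tp = 1L))
  out <- normalize_timepoint_medians(pk)
  expect_equal(out$log2_ratio[1:3], c(-1, 0, 1))
  expect_equal(out$log2_ratio[4:6], c(0, 0, 0))
  offs <- attr(out, "offsets")
  expect_equal(offs$offset, c(1, 3))
  again <- normalize_timepoint_medians(out)
  expect_equal(attr(again, "offsets")$offset, c(0, 0))
})

test_that("inconsistency scores flag the divergent peak of the worked example", {
  expect_equal(detect_peak_outliers_iir(c(0, 0, 0, 0)),
               rep(FALSE, 4)) # zero-dispersion guard
  expect_equal(detect_peak_outliers_iir(c(0, 0.1, -0.1, 5)),
               c(FALSE, FALSE, FALSE, TRUE))
  # hand-computed score of the flagged value: mean distance 5.0 over grand
  # mean 2.5667 = 1.948, just past the 1.81 cutoff; 1.95 must not flag it
  expect_equal(detect_peak_outliers_iir(c(0, 0.1, -0.1, 5), cutoff = 1.95),
               rep(FALSE, 4))
  expect_equal(detect_peak_outliers_iir(c(0, 1, 50)), rep(FALSE, 3))
})

test_that("Gurland factors match their gamma-function closed forms", {
  expect_equal(gurland_cN(2), sqrt(pi / 2), tolerance = 1e-12)
  expect_equal(gurland_cN(10),
               sqrt(9 / 2) * gamma(9 / 2) / gamma(5), tolerance = 1e-12)
  expect_equal(gurland_cN(10), 1.0281, tolerance = 1e-4)
  expect_equal(gurland_cN(1e6), 1, tolerance = 1e-5)
  cs <- gurland_cN(2:50)
  expect_true(all(diff(cs) < 0))
  expect_true(all(cs > 1))
  expect_error(gurland_cN(1), "N must be >= 2")
})

test_that("lognormal ratio estimate handles degenerate and large samples", {
  e <- estimate_protein_ratio(rep(log2(1.5), 5))
  expect_equal(e$log2_ratio, log2(1.5))
  expect_equal(e$s, 0)
  expect_equal(e$ci_low, e$ci_high)
  one <- estimate_protein_ratio(log2(2))
  expect_false(one$ci_defined)
  expect_equal(one$log2_ratio, 1)
  withr::with_seed(11, {
    draws <- rlnorm(10000, 0, 0.3)
  })
  big <- estimate_protein_ratio(log2(draws))
  expect_lt(abs(big$log2_ratio - log2(exp(0.045))), 0.01)
})

test_that("timecourse threshold lowering follows the 4/3/2/1 rule", {
  sel <- select_timecourse_timepoints(rep(5, 10))
  expect_equal(sel$threshold, 4L)
  expect_equal(sum(sel$include), 10)
  counts <- c(rep(4, 7), rep(3, 2), rep(0, 5))
  sel2 <- select_timecourse_timepoints(counts)
  expect_equal(sel2$threshold, 3L)
  expect_equal(sum(sel2$include), 9)
  sel3 <- select_timecourse_timepoints(c(rep(1, 7), rep(0, 7)))
  expect_true(is.na(sel3$threshold))
  expect_false(any(sel3$include))
})

test_that("nearest-neighbour rule flags lone spikes but not ramps", {
  expect_false(any(detect_timepoint_outliers(rep(2, 14))))
  expect_false(any(detect_timepoint_outliers(seq(0, 13)))) # equal steps
  y <- rep(0, 14); y[7] <- 3
  fl <- detect_timepoint_outliers(y)
  expect_true(fl[7])
  expect_equal(sum(fl), 1) # neighbours stay unflagged
  expect_warning(out <- detect_timepoint_outliers(c(1, 2)), "fewer than 3")
  expect_equal(out, c(FALSE, FALSE))
})

test_that("the rollup audit preserves the peak counting identity", {
  cfg <- sim_config(n_genes = 60, seed = 12)
  ds <- simulate_dataset(cfg, coverage = FALSE)
  pk <- ds$peaks$peaks
  pk$ratio[c(3, 10)] <- 0 # inject unorientable records
  q <- quantify_proteome(pk)
  a <- q$audit
  expect_equal(a$peaks_in,
               a$retained + a$cv_filtered + a$iir_flagged +
                 a$rejected_nonpositive)
  expect_lte(a$proteins_resolvable, a$proteins_detected)
  # offsets recentre the CV-passing peaks (the set normalization saw;
  # IIR flags are assigned afterwards)
  keep <- q$peaks$excluded_by != "cv_filter"
  med <- tapply(q$peaks$log2_ratio[keep], q$peaks$timepoint_index[keep],
                median)
  expect_true(all(abs(med) < 1e-9))
})

test_that("proteins without enough timepoints are dropped as unresolvable", {
  # one protein present at 6 timepoints only
  pk <- dplyr::bind_rows(lapply(0:5, function(tp) {
    pk_tbl(exp(rnorm(5, 0, 0.05)), tp = as.integer(tp))
  }))
  q <- quantify_proteome(pk)
  expect_equal(nrow(q$timecourses), 0)
  expect_equal(q$audit$proteins_unresolvable, 1)
})
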