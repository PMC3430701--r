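test_that("a noise-free cosine is recovered exactly", {
  y <- 2 + 1 * cos(2 * pi * (grid_14 - 6) / 24)
  f <- fit_sinusoid_24h(grid_14, y)
  expect_equal(f$mesor, 2, tolerance = 1e-10)
  expect_equal(f$halfamp, 1, tolerance = 1e-10)
  expect_equal(f$phase, 6, tolerance = 1e-8)
  expect_equal(f$fold_change, 4, tolerance = 1e-8)
  expect_equal(fourier_score(f), 1, tolerance = 1e-10)
})

test_that("constant series yield zero amplitude and an undefined phase", {
  f <- fit_sinusoid_24h(grid_14, rep(5, 14))
  expect_equal(f$halfamp, 0)
  expect_true(is.na(f$phase))
  expect_equal(fourier_score(f), 0)
})

test_that("too few points or too short a span is refused", {
  expect_error(fit_sinusoid_24h(grid_14[1:6], rnorm(6)), "unresolvable")
  expect_error(fit_sinusoid_24h(seq(0, 10, length.out = 9), rnorm(9)),
               "half a period")
})

test_that("the closed-form fit matches a brute-force grid search", {
  withr::with_seed(30, {
    for (k in 1:10) {
      y <- runif(1, -2, 2) +
        runif(1, 0.3, 2) * cos(2 * pi * (grid_14 - runif(1, 0, 24)) / 24) +
        rnorm(14, 0, 0.3)
      f <- fit_sinusoid_24h(grid_14, y)
      g <- grid_search_sinusoid(grid_14, y)
      dphi <- abs(f$phase - g$phase)
      expect_lt(min(dphi, 24 - dphi), 0.05)
      expect_lt(abs(f$halfamp - g$halfamp), 0.005)
    }
  })
})

test_that("on an even whole-period grid the score equals the DFT magnitude", {
  t12 <- seq(0, 22, by = 2)
  withr::with_seed(31, y <- rnorm(12))
  f <- fit_sinusoid_24h(t12, y)
  dft <- sum(y * exp(-2i * pi * t12 / 24))
  expect_equal(fourier_score(f), 2 * Mod(dft) / 12, tolerance = 1e-9)
})

test_that("AR(1) fits recover known coefficients on long series", {
  y0 <- ref_ar1(10000, 0, 1, seed = 32)
  f0 <- fit_ar1(seq_along(y0) * 2, y0, detrend = FALSE)
  expect_equal(f0$phi, 0, tolerance = 0.02)
  y6 <- ref_ar1(10000, 0.6, 1, seed = 33)
  f6 <- fit_ar1(seq_along(y6) * 2, y6, detrend = FALSE)
  expect_lt(abs(f6$phi - 0.6), 0.02)
  # detrended variant agrees on long series
  f6d <- fit_ar1(seq_along(y6) * 2, y6, detrend = TRUE)
  expect_lt(abs(f6d$phi - f6$phi), 0.01)
})

test_that("short-series AR(1) fits are nearly unbiased in aggregate", {
  # naive residual autocorrelation at n = 14 is biased by roughly -0.2;
  # the projection-corrected moment match keeps |bias| well under 0.06
  phis <- vapply(1:300, function(k) {
    fit_ar1(grid_14, ref_ar1(14, 0.3, 0.25, seed = 1000 + k),
            quiet = TRUE)$phi
  }, numeric(1))
  expect_lt(abs(mean(phis) - 0.3), 0.06)
})

test_that("constant series give a degenerate null and the floor p-value", {
  f <- fit_ar1(grid_14, rep(3, 14))
  expect_true(f$degenerate)
  expect_equal(f$innovation_sd, 0)
  ns <- simulate_null_scores(f, grid_14, n_sims = 200, seed = 1)
  expect_true(all(ns$F == 0))
  tc <- dplyr::bind_rows(
    as_tc("flat", grid_14, rep(3, 14)),
    as_tc("pure", grid_14, cos(2 * pi * grid_14 / 24)))
  cyc <- detect_cycling(tc, n_sims = 200, seed = 2, moderate_phi = FALSE)
  r <- cyc$results
  expect_equal(r$p[r$gene_id == "pure"], 1 / 201) # noise-free oscillator
  expect_equal(r$p[r$gene_id == "flat"], 1)
})

test_that("null score simulation is reproducible and scales with noise", {
  nm <- fit_ar1(grid_14, ref_ar1(14, 0.3, 0.25, seed = 40))
  a <- simulate_null_scores(nm, grid_14, n_sims = 500, seed = 7)
  b <- simulate_null_scores(nm, grid_14, n_sims = 500, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, simulate_null_scores(nm, grid_14, 500, seed = 8)))
})

test_that("simulated null scores match an independent reference distribution", {
  # fixed phi/sd: package nulls vs a test-local AR(1) generator + plain OLS
  nm <- structure(list(phi = 0.3, innovation_sd = 0.25,
                       gamma0 = 0.25^2 / (1 - 0.3^2), rss = 1, n = 14,
                       degenerate = FALSE), class = "ar1_null")
  pkg <- simulate_null_scores(nm, grid_14, n_sims = 3000, seed = 9)
  ref <- vapply(1:3000, function(k) {
    fit_sinusoid_24h(grid_14, ref_ar1(14, 0.3, 0.25, seed = 5000 + k))$halfamp
  }, numeric(1))
  qs <- c(0.25, 0.5, 0.75, 0.9)
  expect_equal(unname(quantile(pkg$F, qs)), unname(quantile(ref, qs)),
               tolerance = 0.05)
})

test_that("empirical p-values follow the add-one formula", {
  nulls <- seq_len(1000) / 1000
  expect_equal(cycling_pvalue(2, nulls), 1 / 1001)
  expect_equal(cycling_pvalue(0, nulls), 1)
  expect_equal(cycling_pvalue(0.5005, nulls), (1 + 500) / 1001,
               tolerance = 1e-12)
  expect_error(cycling_pvalue(1, numeric(0)), "empty")
})

test_that("q-values reproduce the hand-worked step-up example", {
  q <- estimate_qvalues(c(0.01, 0.02, 0.04), pi0_method = "fixed", pi0 = 1,
                        robust = FALSE)
  expect_equal(q$qvalues, c(0.03, 0.03, 0.04))
  single <- estimate_qvalues(0.2, pi0_method = "fixed", pi0 = 1,
                             robust = FALSE)
  expect_equal(single$qvalues, 0.2)
  expect_error(estimate_qvalues(c(0.1, 0)), "0, 1")
  expect_error(estimate_qvalues(numeric(0)), "no p-values")
})

test_that("q-values are monotone in p and bounded, pi0 sane on uniform p", {
  withr::with_seed(41, p <- runif(10000))
  q <- estimate_qvalues(p)
  expect_gte(q$pi0, 0.95 - 0.05)
  expect_lte(q$pi0, 1)
  o <- order(p)
  expect_true(all(diff(q$qvalues[o]) >= -1e-12))
  expect_true(all(q$qvalues >= 0 & q$qvalues <= 1))
  # non-robust variant agrees with Benjamini-Hochberg when pi0 is 1
  qbh <- estimate_qvalues(p[1:100], pi0_method = "fixed", pi0 = 1,
                          robust = FALSE)
  expect_equal(qbh$qvalues, p.adjust(p[1:100], "BH"), tolerance = 1e-12)
})

test_that("corrected cycling proportion follows the misclassification formula", {
  id <- estimate_cycling_proportion(300, 1000, 1, 1)
  expect_equal(id$corrected_proportion, 0.3)
  ex <- estimate_cycling_proportion(680, 1000, 0.80, 0.95)
  expect_equal(ex$corrected_proportion, (0.68 + 0.95 - 1) / 0.75,
               tolerance = 1e-12)
  expect_equal(ex$corrected_count, round(0.84 * 1000))
  expect_error(estimate_cycling_proportion(5, 10, 0.5, 0.5),
               "non-informative")
  clamped <- estimate_cycling_proportion(10, 1000, 0.9, 0.99)
  expect_gte(clamped$corrected_proportion, 0)
})

test_that("cycling detection output is tidy-able and internally consistent", {
  cfg <- sim_config(n_genes = 40, seed = 42)
  ds <- simulate_dataset(cfg, coverage = FALSE)
  tc <- dplyr::filter(ds$timecourses, level == "mRNA")
  cyc <- detect_cycling(tc, n_sims = 200, seed = 3)
  r <- tidy(cyc)
  expect_equal(nrow(r), 40)
  expect_true(all(r$p > 0 & r$p <= 1, na.rm = TRUE))
  expect_true(all(r$q >= 0 & r$q <= 1, na.rm = TRUE))
  expect_true(all(r$phase >= 0 & r$phase < 24, na.rm = TRUE))
  expect_true(all(r$fold_change >= 1, na.rm = TRUE))
  g <- glance(cyc)
  expect_equal(g$n_significant, sum(r$significant))
  # short series are reported unresolvable, not dropped
  tc2 <- dplyr::bind_rows(tc, as_tc("short", grid_14[1:5], rnorm(5), "mRNA"))
  cyc2 <- detect_cycling(tc2, n_sims = 200, seed = 3)
  expect_false(cyc2$results$resolvable[cyc2$results$gene_id == "short"])
})
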