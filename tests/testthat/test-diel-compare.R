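test_that("lag mapping lands in (-2, 22] with the stated conventions", {
  expect_equal(compute_lag(14, 2), 12)   # antiphase pair
  expect_equal(compute_lag(6, 6), 0)
  expect_equal(compute_lag(23, 1), 2)
  expect_equal(compute_lag(2, 0.5), -1.5) # small negative stays negative
  expect_equal(compute_lag(0, 22), 22)
  withr::with_seed(50, {
    pm <- runif(500, 0, 24); pp <- runif(500, 0, 24)
    lag <- compute_lag(pm, pp)
    expect_true(all(lag > -2 & lag <= 22))
    # bijection: lag recovers the phase difference mod 24
    expect_equal(lag %% 24, (pp - pm) %% 24, tolerance = 1e-12)
  })
})

test_that("amplitude ratios report both metrics and the damping flag", {
  eq <- amplitude_ratio(1, 1)
  expect_equal(eq$amp_ratio_log, 1)
  expect_equal(eq$amp_ratio_fold, 1)
  expect_false(eq$damped)
  ex <- amplitude_ratio(1, 0.25)
  expect_equal(ex$amp_ratio_log, 4)
  expect_equal(ex$amp_ratio_fold, 2^1.5)
  expect_true(ex$damped)
  # fold-of-fold identity: half-amps from 18.1- and 8.5-fold changes
  hm <- log2(18.1) / 2; hp <- log2(8.5) / 2
  expect_equal(amplitude_ratio(hm, hp)$amp_ratio_fold, 18.1 / 8.5,
               tolerance = 1e-12)
  inf <- amplitude_ratio(1, 0)
  expect_true(is.infinite(inf$amp_ratio_log))
})

test_that("phase classes partition lags into the named bands", {
  lag <- c(12, 1.5, 9.5, 2, -2, 8, 11, 13, 8.5, 21, NA)
  cls <- classify_phase_relationship(lag)
  expect_equal(as.character(cls),
               c("antiphase", "in_phase", "other", "in_phase", "in_phase",
                 "lagged_2_8", "antiphase", "antiphase", "other", "other",
                 NA))
  defined <- cls[!is.na(cls)]
  expect_false(any(is.na(defined))) # every defined lag in exactly one class
})

test_that("transcriptional-control calls need both phase and amplitude match", {
  expect_true(classify_transcriptional_control(0, 1))
  expect_false(classify_transcriptional_control(0, 3))
  expect_false(classify_transcriptional_control(12, 1))
  expect_true(classify_transcriptional_control(-2, 0.5)) # inclusive bounds
  expect_false(classify_transcriptional_control(2.1, 1))
})

test_that("pairing joins significant fits and classifies each gene once", {
  mk_res <- function(ids, phase, H, sig = TRUE) {
    tibble::tibble(gene_id = ids, level = "x", n_points = 14, mesor = 0,
                   halfamp = H, fold_change = 2^(2 * H), phase = phase,
                   F = H, stat = 1, phi = 0.3, p = 0.001, q = 0.001,
                   significant = sig, resolvable = TRUE)
  }
  m <- mk_res(c("a", "b", "c"), c(6, 14, 3), c(1, 1, 0.2))
  p <- mk_res(c("a", "b", "d"), c(7, 2, 5), c(0.9, 0.2, 0.2))
  pr <- pair_cycling(m, p)
  expect_equal(sort(pr$pairs$gene_id), c("a", "b"))
  a <- pr$pairs[pr$pairs$gene_id == "a", ]
  expect_equal(a$lag, 1)
  expect_equal(as.character(a$phase_class), "in_phase")
  expect_true(a$transcriptional_control)
  b <- pr$pairs[pr$pairs$gene_id == "b", ]
  expect_equal(b$lag, 12)
  expect_equal(as.character(b$phase_class), "antiphase")
  expect_true(b$damped)
  s <- summarize_cohort(pr)
  expect_equal(s$counts$n_paired, 2)
  expect_equal(s$counts$in_phase + s$counts$lagged_2_8 +
                 s$counts$antiphase + s$counts$other, 2)
  g <- glance(pr)
  expect_equal(g$n_paired, 2)
})

test_that("peak-window lag medians recover constructed group medians", {
  withr::with_seed(51, {
    # morning-peaking genes with lags centred at 6.7 h, evening at 4.2 h
    n <- 80
    morning <- tibble::tibble(
      gene_id = sprintf("m%03d", 1:n),
      phase_mrna = runif(n, 2, 5),
      lag = 6.7 + rnorm(n, 0, 1.5))
    evening <- tibble::tibble(
      gene_id = sprintf("e%03d", 1:n),
      phase_mrna = runif(n, 16, 20),
      lag = 4.2 + rnorm(n, 0, 1.2))
    pairs <- dplyr::bind_rows(morning, evening)
  })
  lw <- lag_by_peak_window(pairs)
  expect_equal(lw$n, c(80, 80))
  expect_equal(lw$median_lag[lw$window == "morning"], 6.7, tolerance = 0.5)
  expect_equal(lw$median_lag[lw$window == "evening"], 4.2, tolerance = 0.5)
  # empty windows report n = 0 with undefined medians
  noon <- tibble::tibble(gene_id = "x", phase_mrna = 12, lag = 3)
  lw2 <- lag_by_peak_window(noon)
  expect_equal(lw2$n, c(0, 0))
  expect_true(all(is.na(lw2$median_lag)))
})
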