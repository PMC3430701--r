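test_that("truth generation honours the cycler count and is reproducible", {
  cfg <- sim_config(n_genes = 100, fraction_cyclers = 0.5, seed = 1)
  tr1 <- generate_diel_truth(cfg)
  tr2 <- generate_diel_truth(cfg)
  expect_identical(tr1, tr2)
  expect_equal(nrow(tr1), 100)
  expect_equal(sum(tr1$is_cycler), 50)
  expect_false(any(duplicated(tr1$gene_id)))
  expect_true(all(tr1$mrna_phase[tr1$is_cycler] >= 0 &
                    tr1$mrna_phase[tr1$is_cycler] < 24))
  expect_true(all(tr1$mrna_halfamp >= 0))
  # non-cyclers are flat at both levels
  expect_true(all(tr1$mrna_halfamp[!tr1$is_cycler] == 0))
  expect_true(all(tr1$protein_halfamp[!tr1$is_cycler] == 0))
})

test_that("a point-mass lag places every protein phase 12 h after the mRNA", {
  cfg <- sim_config(n_genes = 50, fraction_cyclers = 1,
                    lag_dist = dist_point(12), seed = 2)
  tr <- generate_diel_truth(cfg)
  expect_equal(tr$protein_phase, (tr$mrna_phase + 12) %% 24)
})

test_that("damping clamp keeps protein half-amplitude at or below the mRNA's", {
  cfg <- sim_config(n_genes = 200, fraction_cyclers = 1,
                    damping_clamp = TRUE, seed = 3)
  tr <- generate_diel_truth(cfg)
  expect_true(all(tr$protein_halfamp <= tr$mrna_halfamp + 1e-12))
})

test_that("invalid distribution specifications fail naming the field", {
  expect_error(sim_config(lag_dist = list(name = "nope")), "lag_dist")
  expect_error(sim_config(phase_dist = list(meanlog = 1)), "phase_dist")
  expect_error(sim_config(ar1_phi = 1.2), "ar1_phi")
  expect_error(sim_config(fraction_cyclers = -0.1), "fraction_cyclers")
})

test_that("noise-free cyclers trace an exact cosine peaking at their phase", {
  cfg <- sim_config(n_genes = 1, fraction_cyclers = 1,
                    halfamp_dist = dist_point(1),
                    phase_dist = dist_point(6),
                    damping_dist = dist_point(1),
                    lag_dist = dist_point(0),
                    baseline_dist_mrna = dist_point(2),
                    innovation_sd = 0, seed = 4)
  tr <- generate_diel_truth(cfg)
  tc <- simulate_timecourses(tr, cfg)
  m <- tc[tc$level == "mRNA", ]
  expect_equal(m$log2_abundance, 2 + cos(2 * pi * (grid_14 - 6) / 24),
               tolerance = 1e-12)
  expect_equal(m$time_h[which.max(m$log2_abundance)], 6)
})

test_that("generated AR(1) noise has the configured lag-1 autocorrelation", {
  long <- seq(0, 2 * 9999, by = 2)
  for (phi in c(0, 0.6)) {
    cfg <- sim_config(n_genes = 1, fraction_cyclers = 0, times = long,
                      ar1_phi = phi, innovation_sd = 1, seed = 5)
    tr <- generate_diel_truth(cfg)
    tc <- simulate_timecourses(tr, cfg)
    y <- tc$log2_abundance[tc$level == "mRNA"]
    r <- y - mean(y)
    a1 <- sum(r[-1] * r[-length(r)]) / sum(r^2)
    expect_equal(a1, phi, tolerance = 0.02)
  }
})

test_that("degenerate peak dispersion reproduces true ratios exactly", {
  cfg <- small_config(peak_sigma = 0, mixing_bias = rep(0, 14),
                      outlier_peak_rate = 0, outlier_timepoint_rate = 0)
  ds <- simulate_dataset(cfg, coverage = FALSE)
  pk <- ds$peaks$peaks
  truth_l2 <- ds$peaks$peak_truth$true_log2
  expect_equal(log2(pk$ratio), truth_l2, tolerance = 1e-12)
  expect_true(all(pk$cv == 0))
})

test_that("a known mixing bias shifts that timepoint's peak-ratio median", {
  b <- rep(0, 14); b[5] <- 1
  cfg <- sim_config(n_genes = 300, mixing_bias = b, seed = 6,
                    outlier_peak_rate = 0, outlier_timepoint_rate = 0)
  ds <- simulate_dataset(cfg, coverage = FALSE)
  pk <- dplyr::left_join(ds$peaks$peaks, ds$peaks$peak_truth,
                         by = c("peak_id", "protein_id", "timepoint_index"))
  dev <- log2(pk$ratio) - pk$true_log2
  med <- tapply(dev, pk$timepoint_index, median)
  expect_equal(unname(med[["4"]]), 1, tolerance = 0.03)
  expect_equal(unname(med[["0"]]), 0, tolerance = 0.03)
})

test_that("outlier-peak bookkeeping matches the emitted flags", {
  cfg <- sim_config(n_genes = 200, outlier_peak_rate = 0.05, seed = 7)
  ds <- simulate_dataset(cfg, coverage = FALSE)
  pt <- ds$peaks$peak_truth
  rate <- mean(pt$is_outlier_peak)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
  expect_identical(nrow(pt), nrow(ds$peaks$peaks))
  expect_identical(pt$peak_id, ds$peaks$peaks$peak_id)
})

test_that("coverage honours antisense settings and total-bp bookkeeping", {
  cfg <- sim_config(n_genes = 20, antisense_detect_prob = 0, seed = 8,
                    gene_length = 200, gene_gap = 50, depth = 5)
  ds <- simulate_dataset(cfg, coverage = TRUE)
  for (cv in ds$coverage) {
    minus_on_plus_genes <- ds$genes[ds$genes$strand == "+", ]
    ab <- summarize_gene_coverage(cv, ds$genes)
    expect_true(all(ab$antisense == 0))
    expect_equal(cv$total_aligned_bp,
                 sum(cv$depth_plus) + sum(cv$depth_minus))
  }
})

test_that("identical config and seed give identical datasets end to end", {
  cfg <- small_config(n_genes = 10, gene_length = 150, gene_gap = 50)
  d1 <- simulate_dataset(cfg, coverage = TRUE)
  d2 <- simulate_dataset(cfg, coverage = TRUE)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$timecourses, d2$timecourses)
  expect_identical(d1$peaks$peaks, d2$peaks$peaks)
  expect_identical(d1$coverage[[3]]$depth_plus, d2$coverage[[3]]$depth_plus)
})

test_that("adding genes does not perturb existing gene streams", {
  cfg10 <- sim_config(n_genes = 10, seed = 9)
  cfg20 <- sim_config(n_genes = 20, seed = 9)
  t10 <- simulate_timecourses(generate_diel_truth(cfg10), cfg10)
  tr20 <- generate_diel_truth(cfg20)
  t20 <- simulate_timecourses(tr20, cfg20)
  g5 <- "g00005"
  # noise streams keyed by gene index: same index, same level -> same draw
  n10 <- t10$log2_abundance[t10$gene_id == g5 & t10$level == "mRNA"]
  n20 <- t20$log2_abundance[t20$gene_id == g5 & t20$level == "mRNA"]
  tr10 <- generate_diel_truth(cfg10)
  sig10 <- tr10[tr10$gene_id == g5, ]
  sig20 <- tr20[tr20$gene_id == g5, ]
  # remove each run's own deterministic signal before comparing noise
  w <- 2 * pi / 24
  s10 <- if (sig10$is_cycler) sig10$mrna_baseline +
    sig10$mrna_halfamp * cos(w * (grid_14 - sig10$mrna_phase)) else
      rep(sig10$mrna_baseline, 14)
  s20 <- if (sig20$is_cycler) sig20$mrna_baseline +
    sig20$mrna_halfamp * cos(w * (grid_14 - sig20$mrna_phase)) else
      rep(sig20$mrna_baseline, 14)
  expect_equal(n10 - s10, n20 - s20, tolerance = 1e-10)
})
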