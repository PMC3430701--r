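# Shared fixtures: everything is generated in code at test time.

grid_14 <- seq(0, 26, by = 2)

small_config <- function(n_genes = 30, seed = 101, ...) {
  sim_config(n_genes = n_genes, seed = seed, ...)
}

# deterministic AR(1) series on an arbitrary grid (test-local generator,
# independent of the package's internal one)
ref_ar1 <- function(n, phi, sd, seed) {
  withr::with_seed(seed, {
    x <- numeric(n)
    x[1] <- rnorm(1, 0, sd / sqrt(1 - phi^2))
    for (i in seq_len(n - 1)) x[i + 1] <- phi * x[i] + rnorm(1, 0, sd)
    x
  })
}

# brute-force sinusoid fit: grid search over phase with exact inner
# least squares for (mesor, half-amplitude) at each candidate phase
grid_search_sinusoid <- function(times, values, phase_step = 0.01,
                                 period = 24) {
  phases <- seq(0, period - phase_step, by = phase_step)
  w <- 2 * pi / period
  best <- list(sse = Inf)
  for (ph in phases) {
    cc <- cos(w * (times - ph))
    X <- cbind(1, cc)
    cf <- qr.coef(qr(X), values)
    res <- values - X %*% cf
    sse <- sum(res^2)
    if (sse < best$sse) {
      best <- list(sse = sse, phase = ph, mesor = cf[1], halfamp = cf[2])
    }
  }
  if (best$halfamp < 0) {
    best$halfamp <- -best$halfamp
    best$phase <- (best$phase + period / 2) %% period
  }
  best
}

# timecourse tibble in the layout detect_cycling() expects
as_tc <- function(id, times, values, level = "other") {
  tibble::tibble(gene_id = id, level = level, time_h = times,
                 log2_abundance = values)
}
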