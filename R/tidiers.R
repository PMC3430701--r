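#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a sinusoid fit
#'
#' @param x a `sinusoid_fit`.
#' @param ... unused.
#' @return one row per parameter: term, estimate.
#' @export
tidy.sinusoid_fit <- function(x, ...) {
  tibble(term = c("mesor", "cos_coef", "sin_coef", "halfamp", "phase",
                  "fold_change"),
         estimate = c(x$mesor, x$cos_coef, x$sin_coef, x$halfamp, x$phase,
                      x$fold_change))
}

#' @rdname tidy.sinusoid_fit
#' @export
glance.sinusoid_fit <- function(x, ...) {
  tibble(n = x$n, period = x$period, halfamp = x$halfamp, phase = x$phase,
         fold_change = x$fold_change, residual_sd = x$residual_sd,
         rss = x$rss)
}

#' Tidy cycling-detection results
#'
#' @param x a `diel_cycling`.
#' @param ... unused.
#' @return the per-series results tibble.
#' @export
tidy.diel_cycling <- function(x, ...) x$results

#' @rdname tidy.diel_cycling
#' @export
glance.diel_cycling <- function(x, ...) {
  r <- x$results
  tibble(n_series = nrow(r), n_resolvable = sum(r$resolvable),
         n_significant = sum(r$significant), pi0 = x$pi0,
         phi_pooled = x$phi_pooled, q_cutoff = x$q_cutoff,
         n_sims = x$n_sims)
}

#' Tidy a paired mRNA-protein comparison
#'
#' @param x a `diel_pairing`.
#' @param ... unused.
#' @return the per-gene pairs tibble.
#' @export
tidy.diel_pairing <- function(x, ...) x$pairs

#' @rdname tidy.diel_pairing
#' @export
glance.diel_pairing <- function(x, ...) {
  if (nrow(x$pairs) == 0) {
    return(tibble(n_paired = 0L))
  }
  s <- summarize_cohort(x)
  dplyr::bind_cols(s$counts, s$medians)
}
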