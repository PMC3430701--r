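#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_histogram
#'   geom_abline geom_vline labs theme_minimal scale_x_continuous autoplot
#'   annotate geom_errorbar scale_colour_manual
#' @export
ggplot2::autoplot

# light-period shading defaults: sunrise 05:30, sunset 18:30 local time,
# used purely as plot annotation on clock-hour axes
shade_light <- function(p, sunrise = 5.5, sunset = 18.5) {
  p + annotate("rect", xmin = sunrise, xmax = sunset, ymin = -Inf,
               ymax = Inf, alpha = 0.08, fill = "gold")
}

#' Plot a timecourse with its fitted sinusoid
#'
#' @param object a `sinusoid_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sinusoid_fit <- function(object, ...) {
  tgrid <- seq(min(object$times), max(object$times), length.out = 200)
  w <- 2 * pi / object$period
  curve <- tibble(
    time_h = tgrid,
    value = object$mesor + object$cos_coef * cos(w * tgrid) +
      object$sin_coef * sin(w * tgrid))
  ggplot(tibble(time_h = object$times, value = object$values),
         aes(.data$time_h, .data$value)) +
    geom_line(data = curve, colour = "steelblue") +
    geom_point() +
    labs(x = "time (h since midnight)", y = "log2 abundance",
         title = sprintf("half-amplitude %.2f log2, phase %s h",
                         object$halfamp,
                         ifelse(is.na(object$phase), "undef",
                                sprintf("%.1f", object$phase)))) +
    theme_minimal()
}

#' Amplitude comparison scatter (mRNA vs protein)
#'
#' Half-amplitudes of paired genes with the 1:1 line; points below the line
#' are damped at the protein level.
#'
#' @param pairing a `diel_pairing`.
#' @return a ggplot.
#' @export
plot_amplitude_comparison <- function(pairing) {
  p <- if (inherits(pairing, "diel_pairing")) pairing$pairs else pairing
  ggplot(p, aes(.data$halfamp_mrna, .data$halfamp_protein,
                colour = .data$damped)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    geom_point(alpha = 0.6) +
    scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey40")) +
    labs(x = "mRNA half-amplitude (log2)",
         y = "protein half-amplitude (log2)", colour = "damped") +
    theme_minimal()
}

#' Phase comparison scatter (mRNA vs protein peak times)
#'
#' @param pairing a `diel_pairing`.
#' @param in_phase_window half-width of the in-phase band drawn around the
#'   diagonal (default 2 h).
#' @return a ggplot.
#' @export
plot_phase_comparison <- function(pairing, in_phase_window = 2) {
  p <- if (inherits(pairing, "diel_pairing")) pairing$pairs else pairing
  g <- ggplot(p, aes(clock_hour(.data$phase_mrna),
                     clock_hour(.data$phase_protein),
                     colour = .data$phase_class)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    geom_abline(slope = 1, intercept = c(-in_phase_window, in_phase_window),
                linetype = 3, colour = "grey60") +
    geom_point(alpha = 0.6) +
    scale_x_continuous(limits = c(0, 24), breaks = seq(0, 24, 6)) +
    labs(x = "mRNA peak (clock h)", y = "protein peak (clock h)",
         colour = "class") +
    theme_minimal()
  shade_light(g)
}

#' Histogram of protein-after-mRNA lag times
#'
#' @param pairing a `diel_pairing`.
#' @param binwidth histogram bin width in hours (default 1).
#' @return a ggplot.
#' @export
plot_lag_histogram <- function(pairing, binwidth = 1) {
  p <- if (inherits(pairing, "diel_pairing")) pairing$pairs else pairing
  ggplot(p, aes(.data$lag)) +
    geom_histogram(binwidth = binwidth, boundary = 0, fill = "steelblue",
                   colour = "white") +
    geom_vline(xintercept = c(-2, 2, 8, 11, 13), linetype = 3,
               colour = "grey50") +
    labs(x = "protein-after-mRNA lag (h)", y = "genes") +
    theme_minimal()
}
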