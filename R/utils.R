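#' @importFrom rlang abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join bind_rows n row_number across all_of if_else rename
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats median quantile var sd rnorm rpois rlnorm rgamma runif
#'   rbinom qnorm uniroot toeplitz setNames complete.cases
#' @importFrom utils head tail
NULL

# Deterministic 31-bit seed streams derived from (master seed, key...).
# Substreams are stable under adding genes: stream identity depends only on
# its own key, never on how many other streams were drawn.
derive_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1, keeps derived seeds valid R integers
  h <- as.numeric(master) %% m
  for (part in list(...)) {
    codes <- if (is.character(part)) utf8ToInt(part) else as.numeric(part)
    for (cd in codes) h <- (h * 31 + (cd %% m)) %% m
  }
  as.integer(h)
}

with_stream <- function(master, ..., code) {
  withr::with_seed(derive_seed(master, ...), code)
}

#' Distribution specifications for the synthetic-data generator
#'
#' Small named-list constructors used by [sim_config()] to describe the
#' distributions of gene-level truth parameters (phases, half-amplitudes,
#' lags, peak counts). `dist_mixture()` combines components with weights.
#'
#' @param value,min,max,mean,sd,meanlog,sdlog,shape,rate Distribution
#'   parameters on the scale of the quantity being drawn.
#' @param components list of distribution specs.
#' @param weights numeric mixture weights (normalised internally).
#' @return A list with a `name` element, consumed by the generator.
#' @examples
#' dist_point(12)
#' dist_mixture(list(dist_normal(3.5, 1.5), dist_uniform(0, 24)), c(.5, .5))
#' @export
dist_point <- function(value) list(name = "point", value = value)

#' @rdname dist_point
#' @export
dist_uniform <- function(min, max) list(name = "uniform", min = min, max = max)

#' @rdname dist_point
#' @export
dist_normal <- function(mean, sd) list(name = "normal", mean = mean, sd = sd)

#' @rdname dist_point
#' @export
dist_lognormal <- function(meanlog, sdlog) {
  list(name = "lognormal", meanlog = meanlog, sdlog = sdlog)
}

#' @rdname dist_point
#' @export
dist_gamma <- function(shape, rate) list(name = "gamma", shape = shape, rate = rate)

#' @rdname dist_point
#' @param mean_total mean of the shifted Poisson (support starts at 1).
#' @export
dist_shifted_poisson <- function(mean_total) {
  stopifnot(mean_total >= 1)
  list(name = "shifted_poisson", mean_total = mean_total)
}

#' @rdname dist_point
#' @export
dist_mixture <- function(components, weights) {
  stopifnot(length(components) == length(weights), all(weights >= 0))
  list(name = "mixture", components = components, weights = weights / sum(weights))
}

# Draw n values from a distribution spec; `field` names the config field in
# error messages so misconfiguration is traceable.
draw_dist <- function(d, n, field = "distribution") {
  if (!is.list(d) || is.null(d$name)) {
    abort(paste0("Invalid distribution specification for `", field,
                 "`: expected a list with a `name` element."))
  }
  switch(d$name,
    point = rep(d$value, n),
    uniform = runif(n, d$min, d$max),
    normal = rnorm(n, d$mean, d$sd),
    lognormal = rlnorm(n, d$meanlog, d$sdlog),
    gamma = rgamma(n, shape = d$shape, rate = d$rate),
    shifted_poisson = 1L + rpois(n, d$mean_total - 1),
    mixture = {
      k <- sample.int(length(d$components), n, replace = TRUE, prob = d$weights)
      out <- numeric(n)
      for (j in seq_along(d$components)) {
        idx <- which(k == j)
        if (length(idx)) out[idx] <- draw_dist(d$components[[j]], length(idx), field)
      }
      out
    },
    abort(paste0("Unknown distribution name '", d$name, "' in config field `",
                 field, "`."))
  )
}

# FNV-1a over the deparsed object; used to stamp outputs with the producing
# configuration. Plain R so output files stay text-reproducible.
config_hash <- function(x) {
  s <- paste(deparse(x, control = c("keepNA", "niceNames")), collapse = "")
  h <- 2166136261
  for (cd in utf8ToInt(s)) {
    h <- bitwXor(h, cd)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

# clock-hour label (hours since local midnight) for a time on the 0..26 grid
clock_hour <- function(time_h) time_h %% 24
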