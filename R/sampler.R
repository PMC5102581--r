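#' Define a triangular distribution
#'
#' The three-parameter (minimum, mode, maximum) distribution used throughout
#' the uncertainty analysis, mirroring the best/base/worst sensitivity
#' limits.
#'
#' @param low Minimum.
#' @param mode Most common value, with `low <= mode <= high`.
#' @param high Maximum; must strictly exceed `low`.
#' @return A `triangular_dist` list.
#' @export
#' @examples
#' triangular_dist(0.392, 0.484, 0.577)
triangular_dist <- function(low, mode, high) {
  if (!all(is.finite(c(low, mode, high)))) {
    abort("low, mode and high must be finite numbers")
  }
  if (low >= high) {
    abort("degenerate distribution: low must be strictly below high",
          class = "biocogs_degenerate_dist")
  }
  if (mode < low || mode > high) abort("mode must lie in [low, high]")
  structure(list(low = low, mode = mode, high = high),
            class = "triangular_dist")
}

#' @export
print.triangular_dist <- function(x, ...) {
  cat(sprintf("<triangular_dist> Triangular(%g, %g, %g)\n",
              x$low, x$mode, x$high))
  invisible(x)
}

#' Closed-form mean of a triangular distribution
#' @param dist A [triangular_dist()].
#' @return `(low + mode + high) / 3`.
#' @export
triangular_mean <- function(dist) (dist$low + dist$mode + dist$high) / 3

#' Closed-form CDF of a triangular distribution
#' @param dist A [triangular_dist()].
#' @param q Quantile(s).
#' @return P(X <= q).
#' @export
triangular_cdf <- function(dist, q) {
  a <- dist$low; m <- dist$mode; b <- dist$high
  ifelse(q <= a, 0,
    ifelse(q >= b, 1,
      ifelse(q <= m,
             (q - a)^2 / ((b - a) * (m - a)),
             1 - (b - q)^2 / ((b - a) * (b - m)))))
}

#' Sample a triangular distribution by inversion
#'
#' Draws are generated by the inverse-CDF method from `runif()` under R's
#' default Mersenne-Twister generator, so a given `seed` reproduces the same
#' sequence on any platform.
#'
#' @param dist A [triangular_dist()].
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @return Numeric vector of `n` draws in `[low, high]`.
#' @export
#' @examples
#' sample_triangular(triangular_dist(0.392, 0.484, 0.577), 5, seed = 1)
sample_triangular <- function(dist, n, seed = NULL) {
  if (!inherits(dist, "triangular_dist")) abort("dist must be a triangular_dist")
  if (n < 1) abort("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  a <- dist$low; m <- dist$mode; b <- dist$high
  u <- runif(n)
  fc <- (m - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (m - a)),
         b - sqrt((1 - u) * (b - a) * (b - m)))
}

#' Draw joint parameter samples for the Monte Carlo analysis
#'
#' Independent triangular draws of titer and DSP-yield delta (and, when the
#' distribution is supplied, a material-cost multiplier).
#'
#' @param dists Named list of [triangular_dist()] objects with elements
#'   `titer`, `dsp_yield_delta` and optionally `material_multiplier`, e.g.
#'   from [uricase_distributions()].
#' @param n Number of joint draws.
#' @param seed Optional integer seed.
#' @return Tibble with `seed_index`, `titer`, `dsp_yield_delta` and (if
#'   sampled) `material_multiplier`.
#' @export
sample_parameters <- function(dists, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- tibble(
    seed_index = seq_len(n),
    titer = sample_triangular(dists$titer, n),
    dsp_yield_delta = sample_triangular(dists$dsp_yield_delta, n)
  )
  if (!is.null(dists$material_multiplier)) {
    out$material_multiplier <- sample_triangular(dists$material_multiplier, n)
  }
  out
}

#' Synthetic Monte Carlo response surface
#'
#' Generates a table of `(titer, dsp_yield_delta, cog)` whose response is an
#' exact plane plus Gaussian noise:
#' `cog = intercept + beta_titer * titer + beta_yield * dsp_yield_delta +
#' N(0, noise_sd)`. This is the test harness for the surrogate fitter: the
#' planted coefficients are recoverable independently of the cost engine.
#'
#' @param truth Named list or vector with `intercept`, `beta_titer`,
#'   `beta_yield`.
#' @param dists As in [sample_parameters()].
#' @param n Number of rows (>= 3).
#' @param noise_sd Standard deviation of the additive noise (>= 0).
#' @param seed Optional integer seed.
#' @return Tibble with `titer`, `dsp_yield_delta`, `cog`.
#' @export
synthetic_mc_surface <- function(truth, dists, n, noise_sd = 0, seed = NULL) {
  if (n < 3) abort("n must be >= 3")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  truth <- as.list(truth)
  draws <- sample_parameters(dists, n)
  draws$cog <- truth$intercept + truth$beta_titer * draws$titer +
    truth$beta_yield * draws$dsp_yield_delta +
    if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
  draws[, c("titer", "dsp_yield_delta", "cog")]
}
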