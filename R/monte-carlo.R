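#' Moving-average convergence check
#'
#' Declares a Monte Carlo run stable at the first index `n` (with
#' `n >= window`) where the cumulative moving average has changed by less
#' than `tol` in relative terms across the last `window` entries:
#' `|MA_n - MA_(n-window+1)| / MA_n < tol`.
#'
#' @param ma_series Numeric series of cumulative moving averages.
#' @param window Look-back window in runs (>= 2).
#' @param tol Relative tolerance (e.g. 0.005 for 0.5%).
#' @return The first converged run index, or `NA_integer_` if never
#'   satisfied (including series shorter than the window).
#' @export
#' @examples
#' convergence_check(rep(5, 100), window = 50, tol = 0.005) # 50
convergence_check <- function(ma_series, window = 50, tol = 0.005) {
  if (window < 2) abort("window must be >= 2")
  n <- length(ma_series)
  if (n < window) return(NA_integer_)
  idx <- window:n
  ok <- abs(ma_series[idx] - ma_series[idx - window + 1]) /
    abs(ma_series[idx]) < tol
  if (!any(ok)) return(NA_integer_)
  idx[which(ok)[1]]
}

#' Monte Carlo analysis of CoG/g under parameter uncertainty
#'
#' Draws titer and DSP-yield perturbations from their triangular
#' distributions, evaluates the cost engine at every draw, and tracks the
#' cumulative moving average of CoG/g together with its convergence point.
#' Draws whose yield delta would push the composite DSP yield outside (0, 1]
#' are rejected and resampled (the count is recorded).
#'
#' @param fs A [flowsheet()].
#' @param model A `cost_model` from [uricase_costing()].
#' @param dists Named distribution list from [uricase_distributions()];
#'   only `titer` and `dsp_yield_delta` are sampled (the top two sensitivity
#'   parameters).
#' @param n_max Number of simulation runs (default 1000).
#' @param seed Integer seed recorded in the result.
#' @param window,tol Convergence rule; see [convergence_check()].
#' @return An `mc_result` tibble with columns `run`, `titer`,
#'   `dsp_yield_delta`, `cog`, `moving_average`, and attributes `seed`,
#'   `converged_at`, `n_rejected`, `process`. Supports [glance()] and
#'   [autoplot()].
#' @export
#' @examples
#' cfg <- uricase_config()
#' mc <- run_monte_carlo(uricase_flowsheets(cfg)$atps,
#'                       uricase_costing(cfg, "atps"),
#'                       uricase_distributions(cfg), n_max = 200, seed = 1)
#' glance(mc)
run_monte_carlo <- function(fs, model, dists, n_max = 1000, seed = NULL,
                            window = 50, tol = 0.005) {
  if (n_max < 1) abort("n_max must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  base_yield <- chain_yield(fs)
  titer <- sample_triangular(dists$titer, n_max)
  delta <- sample_triangular(dists$dsp_yield_delta, n_max)
  n_rejected <- 0L
  repeat {
    bad <- which(base_yield + delta / 100 <= 0 | base_yield + delta / 100 > 1)
    if (length(bad) == 0) break
    n_rejected <- n_rejected + length(bad)
    titer[bad] <- sample_triangular(dists$titer, length(bad))
    delta[bad] <- sample_triangular(dists$dsp_yield_delta, length(bad))
  }
  if (n_rejected > 0) {
    warn(sprintf("%d draw(s) produced an invalid DSP yield and were resampled",
                 n_rejected))
  }
  cog <- cog_value(fs, model, titer, delta)$cog
  ma <- cumsum(cog) / seq_len(n_max)
  out <- tibble(run = seq_len(n_max), titer = titer,
                dsp_yield_delta = delta, cog = cog, moving_average = ma)
  structure(out,
            class = c("mc_result", class(out)),
            seed = seed, converged_at = convergence_check(ma, window, tol),
            n_rejected = n_rejected, window = window, tol = tol,
            process = attr(fs, "process_id"))
}

#' @rdname run_monte_carlo
#' @param x An `mc_result`.
#' @param ... Unused.
#' @export
glance.mc_result <- function(x, ...) {
  tibble(
    process = attr(x, "process") %||% NA_character_,
    n_runs = nrow(x),
    seed = attr(x, "seed") %||% NA_integer_,
    converged_at = attr(x, "converged_at"),
    n_rejected = attr(x, "n_rejected"),
    mean = mean(x$cog), sd = sd(x$cog),
    min = min(x$cog), max = max(x$cog)
  )
}

#' Scatter view of a Monte Carlo run
#'
#' CoG/g against titer, coloured by the DSP-yield perturbation (or the
#' reverse with `x = "dsp_yield_delta"`), mirroring the standard
#' two-dimensional views of a cost cloud.
#'
#' @param object An `mc_result`.
#' @param x Which parameter to place on the x-axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mc_result <- function(object, x = c("titer", "dsp_yield_delta"),
                               ...) {
  x <- match.arg(x)
  colour_var <- setdiff(c("titer", "dsp_yield_delta"), x)
  ggplot(object, aes(x = .data[[x]], y = .data$cog,
                     colour = .data[[colour_var]])) +
    geom_point(alpha = 0.6) +
    scale_colour_viridis_c(name = colour_var) +
    labs(x = x, y = "CoG/g (USD)",
         title = sprintf("Monte Carlo CoG/g (%s)",
                         attr(object, "process") %||% "")) +
    theme_minimal()
}
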