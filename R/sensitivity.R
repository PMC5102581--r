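#' Packaged best/base/worst sensitivity scenarios
#'
#' One-at-a-time scenario grid over the four cost drivers: fermentation titer
#' (0.577 / 0.484 / 0.392 g/L), DSP yield (+10 / 0 / -10 percentage points),
#' material cost (-25% / 0 / +25% on the named materials) and labor location
#' (Mexico / UK / USA wage sets). The printed wage table is carried verbatim;
#' note its role-by-role values do not order Mexico below the UK, so the
#' "best" labor scenario is best by label, not necessarily by cost.
#'
#' @param config A configuration tree from [uricase_config()].
#' @return Tibble with `variable` and list-columns `best`, `base`, `worst`.
#' @export
uricase_scenarios <- function(config = uricase_config()) {
  sc <- config$scenarios
  tibble(
    variable = names(sc),
    best = purrr::map(sc, "best"),
    base = purrr::map(sc, "base"),
    worst = purrr::map(sc, "worst")
  )
}

scenario_cog <- function(fs, model, variable, value) {
  switch(variable,
    titer = cog_per_gram(fs, model, titer = value),
    dsp_yield = cog_per_gram(fs, model, dsp_yield_delta = value),
    material_cost = cog_per_gram(fs, model, material_multiplier = value),
    labor_location = cog_per_gram(fs, model, labor_location = value),
    abort(sprintf("unknown scenario variable '%s'", variable))
  )$cog_per_gram
}

#' Run the one-at-a-time scenario grid
#'
#' Evaluates CoG/g at the best, base and worst value of each scenario
#' variable while all other variables are held at base, and returns one
#' tornado entry per variable. `material_cost` scenarios are expressed as
#' multipliers applied to the named materials only (fermentation media, ATPS
#' chemicals, UF/DF filters).
#'
#' @param fs A [flowsheet()].
#' @param model A `cost_model` from [uricase_costing()].
#' @param scenarios Scenario grid from [uricase_scenarios()].
#' @return A `tornado` tibble: `variable`, `cog_best`, `cog_base`,
#'   `cog_worst`, `span` (absolute USD/g between best and worst).
#' @export
#' @examples
#' cfg <- uricase_config()
#' fs <- uricase_flowsheets(cfg)$atps
#' run_scenarios(fs, uricase_costing(cfg, "atps")) |> tornado_rank()
run_scenarios <- function(fs, model, scenarios = NULL) {
  scenarios <- scenarios %||% uricase_scenarios()
  out <- purrr::pmap(scenarios, function(variable, best, base, worst) {
    tibble(
      variable = variable,
      cog_best = scenario_cog(fs, model, variable, best[[1]]),
      cog_base = scenario_cog(fs, model, variable, base[[1]]),
      cog_worst = scenario_cog(fs, model, variable, worst[[1]])
    )
  })
  out <- dplyr::bind_rows(out)
  out$span <- abs(out$cog_worst - out$cog_best)
  class(out) <- c("tornado", class(out))
  attr(out, "process") <- attr(fs, "process_id")
  out
}

#' Rank tornado entries by CoG/g span
#'
#' @param entries A tornado tibble from [run_scenarios()].
#' @return The entries sorted by decreasing span; ties broken alphabetically
#'   by variable name.
#' @export
tornado_rank <- function(entries) {
  if (nrow(entries) < 1) abort("at least one tornado entry is required")
  entries[order(-entries$span, entries$variable), ]
}

#' Tornado plot of a sensitivity analysis
#'
#' Bars span from the best-case to the worst-case CoG/g of each variable,
#' crossing the vertical base-scenario line, ranked by span.
#'
#' @param object A tornado tibble from [run_scenarios()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tornado <- function(object, ...) {
  ranked <- tornado_rank(object)
  ranked$variable <- factor(ranked$variable, levels = rev(ranked$variable))
  ggplot(ranked, aes(y = .data$variable)) +
    geom_segment(aes(x = .data$cog_best, xend = .data$cog_worst,
                     yend = .data$variable), linewidth = 6,
                 colour = "steelblue") +
    geom_vline(aes(xintercept = .data$cog_base), linetype = 2) +
    labs(x = "CoG/g (USD)", y = NULL,
         title = sprintf("Sensitivity of CoG/g (%s)",
                         attr(object, "process") %||% "")) +
    theme_minimal()
}
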