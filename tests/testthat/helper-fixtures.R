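# Shared fixtures built in code. The toy flowsheet/model pair has round
# numbers so closed-form cost oracles are easy to state; the packaged
# configuration is loaded once for the fixture-level tests.

pkg_cfg <- uricase_config()
pkg_fs <- uricase_flowsheets(pkg_cfg)

toy_flowsheet <- function(yields = c(0.9, 0.8), titer = 1,
                          volume_factors = rep(1, length(yields)),
                          fermenter_volume = 10) {
  ops <- dplyr::bind_rows(
    unit_operation("ferm", "fermentation", 1),
    dplyr::bind_rows(purrr::map2(
      seq_along(yields), yields,
      function(i, y) unit_operation(paste0("mid", i), "centrifugation", y,
                                    volume_factors[i]))),
    unit_operation("ufdf", "ufdf", 1)
  )
  flowsheet("toy", fermenter_volume, titer, ops)
}

# purely variable-cost model: cog = per_batch / (V x titer x yield) exactly
toy_variable_model <- function(per_batch = 100, target_output = 50) {
  cost_model(target_output = target_output, materials_other = per_batch,
             base = list(titer = 1, labor_location = "UK",
                         material_multiplier = 1))
}

# random flowsheet generator for property-style tests
random_flowsheet <- function(n_mid = sample(1:5, 1)) {
  toy_flowsheet(yields = runif(n_mid, 0.5, 1),
                volume_factors = runif(n_mid, 0.5, 3),
                titer = runif(1, 0.1, 2))
}
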