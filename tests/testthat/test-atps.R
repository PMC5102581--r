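test_that("split_system divides volume by the top fraction and conserves it", {
  sp <- atps_spec(12, 0.4)
  out <- split_system(1, sp, recovery = 1, product_mass = 2)
  expect_equal(out$top$volume, 4.8)
  expect_equal(out$bottom$volume, 7.2)
  expect_equal(out$top$volume + out$bottom$volume,
               sp$system_volume_multiplier * 1)
  # full recovery sends all product to the destination phase
  expect_equal(out$top$product_mass, 2)
  expect_equal(out$bottom$product_mass, 0)
  # component masses split by the partition fractions and conserve
  expect_equal(out$top$components + out$bottom$components, out$inventory)
  # recovery scales the destination mass only
  out2 <- split_system(1, sp, recovery = 0.66, product_mass = 2)
  expect_equal(out2$top$product_mass, 1.32)
})

test_that("packaged back-extraction reproduces the published worked example", {
  be <- uricase_back_extraction(pkg_cfg)
  expect_equal(be$dilution_factor, 10)
  expect_equal(be$bottom_volume / be$second_system_volume, 0.56)
  # dilution factor is invariant under uniform scaling of the sample volume
  be5 <- uricase_back_extraction(pkg_cfg, sample_volume = 5)
  expect_equal(be5$dilution_factor, be$dilution_factor)
  expect_equal(be5$bottom_volume, 5 * be$bottom_volume)
})

test_that("back-extraction conserves component mass per batch", {
  spec <- uricase_atps(pkg_cfg)
  first <- split_system(1, spec$atps, recovery = 1, product_mass = 1)
  be <- back_extract(first, spec$recycle,
                     spec$second_system_volume_multiplier,
                     spec$second_system_ammonium_sulfate_pct)
  # inputs: first-system inventory + fresh second-system salt
  inputs <- sum(first$inventory) + be$fresh_inputs[["second_system_as"]]
  # outputs: discarded first bottom + collected second bottom + recycled top
  outputs <- sum(be$discarded) + sum(be$collected$components) +
    sum(be$recycled_stream)
  expect_equal(inputs, outputs)
  # at steady state the recycled stream replaces exactly r x inventory
  expect_equal(be$recycled_stream,
               first$inventory - be$fresh_demand)
})

test_that("zero recycle fractions return an empty recycled stream", {
  spec <- uricase_atps(pkg_cfg)
  first <- split_system(1, spec$atps)
  rec0 <- recycle_spec(0, 0, 0, 0.56)
  be <- back_extract(first, rec0, spec$second_system_volume_multiplier)
  expect_equal(unname(be$recycled_stream), c(0, 0, 0))
  expect_equal(be$fresh_demand, first$inventory)
})

test_that("phase-composition preconditions fail with named rules", {
  spec <- uricase_atps(pkg_cfg)
  first <- split_system(1, spec$atps)
  # bottom phase must dominate the second system
  expect_error(
    back_extract(first, recycle_spec(bottom_fraction_second_system = 0.4),
                 spec$second_system_volume_multiplier),
    "bottom fraction > 0.5", class = "biocogs_phase_error")
  # salt content must exceed polymer content
  expect_error(
    back_extract(first, spec$recycle, spec$second_system_volume_multiplier,
                 fresh_ammonium_sulfate_pct = 2),
    "salt content", class = "biocogs_phase_error")
})

test_that("steady-state fresh demand matches the batch-cycle fixed point", {
  rec <- recycle_spec()  # packaged 60/20/20
  inv <- c(peg = 100, ammonium_sulfate = 80, nacl = 20)
  fresh <- steady_state_fresh_demand(rec, inv)
  expect_equal(fresh[["peg"]], 40)   # 60% reuse -> 40% fresh
  expect_equal(fresh[["ammonium_sulfate"]], 64)
  expect_equal(fresh[["nacl"]], 16)
  # oracle: iterate the batch recursion explicitly for 20 batches
  r <- c(peg = 0.6, ammonium_sulfate = 0.2, nacl = 0.2)
  recycled <- c(peg = 0, ammonium_sulfate = 0, nacl = 0)
  for (b in 1:20) {
    fresh_b <- inv - recycled
    recycled <- r * inv
  }
  expect_equal(fresh, fresh_b)
  # full reuse -> zero fresh demand at steady state
  full <- steady_state_fresh_demand(recycle_spec(1, 1, 1, 0.56), inv)
  expect_equal(unname(full), c(0, 0, 0))
})

test_that("spec constructors validate their domains", {
  expect_error(atps_spec(0.5, 0.4), "multiplier")
  expect_error(atps_spec(12, 1.2), "top_fraction")
  expect_error(atps_spec(12, 0.4, composition = c(peg = 60,
                                                  ammonium_sulfate = 50,
                                                  nacl = 0)), "sum")
  expect_error(recycle_spec(r_peg = 1.3), "\\[0, 1\\]")
})
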