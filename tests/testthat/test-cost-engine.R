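test_that("batches_required follows target / (V x titer x yield)", {
  expect_equal(batches_required(10, 1, 1, 1), 10)
  # chromatography base: 25 x 0.484 x 0.432 = 5.2272 g per batch
  expect_equal(batches_required(800, 25, 0.484, 0.432), 800 / 5.2272)
  # inverse proportionality in titer
  expect_equal(batches_required(800, 25, 2 * 0.484, 0.432),
               batches_required(800, 25, 0.484, 0.432) / 2)
  expect_equal(batches_required(7, 1, 1, 1, continuous = FALSE), 7)
  expect_equal(batches_required(7.2, 1, 1, 1, continuous = FALSE), 8)
  expect_error(batches_required(-1, 1, 1, 1), "target_output")
  expect_error(batches_required(1, 1, 0, 1), "titer")
  expect_error(batches_required(1, 1, 1, 1.2), "dsp_yield")
})

test_that("ufdf_filter_count applies the ceiling rule and is monotone", {
  expect_identical(ufdf_filter_count(0, 100), 0L)
  expect_identical(ufdf_filter_count(101, 100), 2L)
  expect_identical(ufdf_filter_count(100, 100), 1L)
  v <- seq(0, 500, by = 7)
  expect_true(all(diff(ufdf_filter_count(v, 50)) >= 0))
  expect_error(ufdf_filter_count(-1, 100), "volume")
  expect_error(ufdf_filter_count(1, 0), "capacity")
})

test_that("zero-fixed-cost model matches the closed-form CoG/g oracle", {
  fs <- toy_flowsheet(yields = c(0.9, 0.8), fermenter_volume = 10)
  m <- toy_variable_model(per_batch = 100, target_output = 50)
  for (titer in c(0.5, 1, 2)) {
    res <- cog_per_gram(fs, m, titer = titer)
    # cog = per_batch_variable / (V x titer x yield), exactly
    expect_equal(res$cog_per_gram, 100 / (10 * titer * 0.72))
    expect_equal(sum(res$category_costs), res$cog_per_gram * res$annual_mass)
  }
})

test_that("CoG/g is linear in costs and strictly decreasing in titer and yield", {
  fs <- pkg_fs$chromatography
  m <- uricase_costing(pkg_cfg, "chromatography")
  base <- cog_per_gram(fs, m)$cog_per_gram
  m2 <- m
  m2$annual_fixed <- 2 * m$annual_fixed
  m2$materials_other <- 2 * m$materials_other
  m2$consumables_other <- 2 * m$consumables_other
  m2$headcount_equivalent <- 2 * m$headcount_equivalent
  m2$ufdf$filter_cost <- 2 * m$ufdf$filter_cost
  m2$line_items <- lapply(m$line_items, function(it) {
    it$cost <- 2 * it$cost; it
  })
  expect_equal(cog_per_gram(fs, m2)$cog_per_gram, 2 * base)

  titers <- seq(0.392, 0.577, length.out = 7)
  cogs_t <- sapply(titers, function(t) cog_per_gram(fs, m, titer = t)$cog_per_gram)
  expect_true(all(diff(cogs_t) < 0))
  deltas <- seq(-10, 10, length.out = 7)
  cogs_y <- sapply(deltas, function(d)
    cog_per_gram(fs, m, dsp_yield_delta = d)$cog_per_gram)
  expect_true(all(diff(cogs_y) < 0))
})

test_that("yield perturbations outside (0, 1] raise a domain error", {
  fs <- pkg_fs$chromatography
  m <- uricase_costing(pkg_cfg, "chromatography")
  expect_error(cog_per_gram(fs, m, dsp_yield_delta = -44), "outside")
  expect_error(cog_per_gram(fs, m, dsp_yield_delta = 60), "outside")
})

test_that("calibration round-trips the published base cases exactly", {
  m_c <- calibrate_fixture(pkg_fs$chromatography, pkg_cfg)
  m_a <- calibrate_fixture(pkg_fs$atps, pkg_cfg)
  r_c <- cog_per_gram(pkg_fs$chromatography, m_c)
  r_a <- cog_per_gram(pkg_fs$atps, m_a)
  expect_equal(r_c$cog_per_gram, 9396.97, tolerance = 1e-9)
  expect_equal(r_a$cog_per_gram, 5452.00, tolerance = 1e-9)
  # fixed point: perturbing titer by zero leaves CoG/g unchanged
  expect_identical(cog_per_gram(pkg_fs$atps, m_a, titer = 0.484)$cog_per_gram,
                   r_a$cog_per_gram)
  # labor anchored at 13% of the total
  sh <- breakdown_shares(r_c)
  expect_equal(sh$share[sh$category == "labor"], 0.13, tolerance = 1e-9)
  # shared upstream inputs (media line, wage sets) are identical across
  # process calibrations, and the recycle model reuses the ATPS calibration
  media <- function(m) Filter(function(it) it$item == "2xYT medium",
                              m$line_items)[[1]]$cost
  expect_identical(media(m_c), media(m_a))
  expect_identical(m_c$wages, m_a$wages)
  expect_equal(uricase_costing(pkg_cfg, "atps_recycle"), m_a)
})

test_that("infeasible share vectors fail with a diagnostic", {
  shares <- c(capital = 0.55, materials = 0.0001, consumables = 0.13,
              labor = 0.13, other = 0.1899)
  expect_error(
    calibrate_fixture(pkg_fs$atps, pkg_cfg, target_shares = shares),
    "infeasible share vector", class = "biocogs_calibration_error")
  shares2 <- c(capital = 0.55, materials = 0.17, consumables = 0.0001,
               labor = 0.13, other = 0.1499)
  expect_error(
    calibrate_fixture(pkg_fs$atps, pkg_cfg, target_shares = shares2),
    "UF/DF filters", class = "biocogs_calibration_error")
})

test_that("breakdown shares sum to one and are scale invariant", {
  m <- uricase_costing(pkg_cfg, "atps")
  res <- cog_per_gram(pkg_fs$atps, m)
  sh <- breakdown_shares(res)
  expect_equal(sum(sh$share), 1)
  expect_true(all(sh$share >= 0 & sh$share <= 1))
  # homogeneity: doubling every cost leaves shares untouched
  res2 <- res
  res2$category_costs <- 2 * res$category_costs
  expect_equal(breakdown_shares(res2)$share, sh$share)
  # single-category model puts its whole share there
  fs <- toy_flowsheet()
  solo <- cog_per_gram(fs, toy_variable_model())
  sh_solo <- breakdown_shares(solo)
  expect_equal(sh_solo$share[sh_solo$category == "materials"], 1)
})

test_that("batches, not titer and yield separately, drive variable costs", {
  # doubling titer while halving yield leaves the batch count - and with it
  # every per-batch cost - unchanged (volumes are titer-independent)
  fs <- toy_flowsheet(yields = c(0.9, 0.5))
  m <- toy_variable_model()
  a <- cog_per_gram(fs, m, titer = 0.5)
  fs2 <- toy_flowsheet(yields = c(0.9, 0.25))
  b <- cog_per_gram(fs2, m, titer = 1)
  expect_equal(a$batches, b$batches)
  expect_equal(a$cog_per_gram, b$cog_per_gram)
})

test_that("tidy and glance expose the cost result as tibbles", {
  res <- cog_per_gram(pkg_fs$atps, uricase_costing(pkg_cfg, "atps"))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$category, COST_CATEGORIES)
  gl <- glance(res)
  expect_equal(gl$cog_per_gram, res$cog_per_gram)
  expect_equal(gl$process, "atps")
})
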