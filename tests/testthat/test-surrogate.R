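dists <- uricase_distributions(pkg_cfg)
truth <- list(intercept = 9400, beta_titer = -19883, beta_yield = -227)

test_that("fit_linear recovers a noiseless plane exactly", {
  surf <- synthetic_mc_surface(truth, dists, n = 60, noise_sd = 0, seed = 31)
  s <- fit_linear(surf)
  expect_equal(s$intercept, truth$intercept)
  expect_equal(s$beta_titer, truth$beta_titer)
  expect_equal(s$beta_yield, truth$beta_yield)
  # residual orthogonality at machine precision
  res <- residuals(s$fit)
  expect_lt(abs(sum(res * surf$titer)), 1e-6)
  expect_lt(abs(sum(res)), 1e-6)
  # row order is irrelevant
  s2 <- fit_linear(surf[sample(nrow(surf)), ])
  expect_equal(s2$beta_titer, s$beta_titer)
})

test_that("coefficient error shrinks like 1/sqrt(n) under noise", {
  rmse_at <- function(n) {
    errs <- sapply(1:8, function(i) {
      surf <- synthetic_mc_surface(truth, dists, n = n, noise_sd = 300,
                                   seed = 1000 + i)
      fit_linear(surf)$beta_titer - truth$beta_titer
    })
    sqrt(mean(errs^2))
  }
  r_small <- rmse_at(100)
  r_big <- rmse_at(1600)
  # 16x the data should cut the RMSE by about 4; allow generous slack
  expect_lt(r_big, r_small / 2)
})

test_that("collinear designs raise a singular-design error", {
  surf <- synthetic_mc_surface(truth, dists, n = 30, seed = 7)
  surf$dsp_yield_delta <- 2 * surf$titer
  expect_error(fit_linear(surf), "singular",
               class = "biocogs_singular_design")
  expect_error(fit_linear(surf[1:2, ]), "3 rows")
})

test_that("engine-fit surrogates have significant negative slopes, steeper for chromatography", {
  fit_for <- function(p) {
    mc <- run_monte_carlo(pkg_fs[[p]], uricase_costing(pkg_cfg, p), dists,
                          n_max = 400, seed = 55)
    fit_linear(mc)
  }
  s_chrom <- fit_for("chromatography")
  s_atps <- fit_for("atps")
  for (s in list(s_chrom, s_atps)) {
    expect_lt(s$beta_titer, 0)
    expect_lt(s$beta_yield, 0)
    expect_true(all(s$p_values < 0.01))
  }
  expect_gt(abs(s_chrom$beta_titer), abs(s_atps$beta_titer))
  expect_gt(abs(s_chrom$beta_yield), abs(s_atps$beta_yield))
})

test_that("packaged reference surrogates carry the published slopes, recentred at base", {
  s <- uricase_surrogates()
  expect_equal(s$atps$beta_yield, -83)
  expect_equal(s$atps_recycle$beta_yield, -83)
  expect_equal(s$chromatography$beta_titer, -19883)
  # raw intercepts preserved as metadata
  expect_equal(s$chromatography$raw_intercept, 191956)
  expect_equal(uricase_surrogates(recentered = FALSE)$chromatography$intercept,
               191956)
  # recentred form predicts the published base CoG/g at base parameters
  base_pt <- data.frame(titer = 0.484, dsp_yield_delta = 0)
  expect_equal(predict(s$chromatography, base_pt), 9396.97)
  expect_equal(predict(s$atps, base_pt), 5452.00)
  expect_equal(predict(s$atps_recycle, base_pt), 5430)
})

test_that("overlap fractions behave at the limits and under affine rescaling", {
  s <- uricase_surrogates()
  # identical distributions overlap completely
  same <- overlap_analysis(s$atps, s$atps, dists, n = 2000, seed = 3)
  expect_equal(same$frac_chrom_in_overlap, 1)
  expect_equal(same$frac_atps_in_overlap, 1)
  # separating one surrogate beyond the combined spread kills the overlap
  far <- s$atps
  far$intercept <- far$intercept + 1e6
  none <- overlap_analysis(far, s$atps, dists, n = 2000, seed = 3)
  expect_equal(none$frac_chrom_in_overlap, 0)
  expect_equal(none$frac_atps_in_overlap, 0)
  expect_true(is.na(none$overlap_low))
  # common affine rescaling of both cost axes leaves the fractions unchanged
  rescale <- function(x, a, b) {
    x$intercept <- a * x$intercept + b
    x$beta_titer <- a * x$beta_titer
    x$beta_yield <- a * x$beta_yield
    x
  }
  ref <- overlap_analysis(s$chromatography, s$atps, dists, n = 5000, seed = 4)
  scaled <- overlap_analysis(rescale(s$chromatography, 3.5, 200),
                             rescale(s$atps, 3.5, 200), dists,
                             n = 5000, seed = 4)
  expect_equal(scaled$frac_chrom_in_overlap, ref$frac_chrom_in_overlap)
  expect_equal(scaled$frac_atps_in_overlap, ref$frac_atps_in_overlap)
})

test_that("support and sample bounds agree as the sample grows", {
  s <- uricase_surrogates()
  sup <- overlap_analysis(s$chromatography, s$atps, dists)
  samp <- overlap_analysis(s$chromatography, s$atps, dists, n = 1e5,
                           seed = 8, bounds = "sample")
  # empirical ranges are nested inside the support, so sampled fractions sit
  # a little below the deterministic support fractions
  expect_lt(abs(sup$frac_chrom_in_overlap - samp$frac_chrom_in_overlap), 0.05)
  expect_lt(abs(sup$frac_atps_in_overlap - samp$frac_atps_in_overlap), 0.08)
  expect_gte(sup$overlap_high, samp$overlap_high)
  expect_lte(sup$overlap_low, samp$overlap_low)
})
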