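test_that("cane biomass equation reproduces hand arithmetic and limits", {
  est <- cane_biomass(D = 0.030, H = 3.00, rho_S = 1100, taper = 0.977,
                      BM_L = 0.100)
  expect_equal(est$BM_S, pi * 0.03^2 / 4 * 3 * 1100 * 0.977, tolerance = 1e-12)
  expect_equal(est$BM_S, 2.2790, tolerance = 1e-4)
  expect_equal(est$BM_C, 2.3790, tolerance = 1e-4)

  # zero stalk -> leaf only
  expect_equal(cane_biomass(0.03, 0, 1100, BM_L = 0.1)$BM_C, 0.1)
  # unit cylinder: D = 2/sqrt(pi), H = 1, rho = 1, taper = 1 -> 1 kg
  expect_equal(cane_biomass(2 / sqrt(pi), 1, 1, taper = 1)$BM_C, 1)

  expect_error(cane_biomass(-0.01, 3, 1100), class = "canemass_domain_error")
  expect_error(cane_biomass(0.03, 3, 1100, taper = 0), class = "canemass_domain_error")
})

test_that("cane biomass is linear in density and taper, quadratic in diameter", {
  base <- cane_biomass(0.025, 2.5, 900, taper = 0.95, BM_L = 0)$BM_S
  expect_equal(cane_biomass(0.025, 2.5, 1800, taper = 0.95)$BM_S, 2 * base)
  expect_equal(cane_biomass(0.025, 2.5, 900, taper = 2 * 0.95)$BM_S, 2 * base)
  expect_equal(cane_biomass(0.050, 2.5, 900, taper = 0.95)$BM_S, 4 * base)
})

test_that("tch converts per-cane biomass to tons per hectare", {
  expect_equal(tch(2.379, 8, 1.2), 158.6)
  expect_equal(tch(2.379, 0), 0)
  # shipped default spacing is the 0.9/1.5 midpoint
  expect_identical(eval(formals(tch)$S), 1.2)
  expect_error(tch(2, 8, S = 0), class = "canemass_domain_error")

  # round-trip back to per-cane biomass
  bmc <- c(0.4, 1.7, 2.9)
  expect_equal(tch(bmc, 8, 1.3) * 1.3 / (10 * 8), bmc)
})

test_that("taper factor calibration averages measured/estimated ratios", {
  expect_equal(calibrate_taper_factor(c(2.00, 1.95), c(2.05, 2.00)),
               mean(c(2 / 2.05, 1.95 / 2)))
  expect_equal(calibrate_taper_factor(c(2.00, 1.95), c(2.05, 2.00)),
               0.9753, tolerance = 1e-4)
  expect_equal(calibrate_taper_factor(c(1.2, 3.4), c(1.2, 3.4)), 1.0)
  expect_error(calibrate_taper_factor(c(1, 2), c(1, 0)),
               class = "canemass_domain_error")
  expect_error(calibrate_taper_factor(c(1, 2), c(1, 2, 3)),
               class = "canemass_input_error")
})

test_that("taper calibration recovers the generating factor", {
  true_f <- 0.955
  uncorr <- c(0.8, 1.5, 2.1, 2.6, 3.0)
  # noise-free: exact recovery
  expect_equal(calibrate_taper_factor(true_f * uncorr, uncorr), true_f)
  # noisy: within a few sampling s.e.
  set.seed(42)
  n <- 400
  uncorr <- runif(n, 0.5, 3)
  meas <- true_f * uncorr * (1 + rnorm(n, 0, 0.05))
  f_hat <- calibrate_taper_factor(meas, uncorr)
  expect_lt(abs(f_hat - true_f), 4 * true_f * 0.05 / sqrt(n))
  # pooled-ratio alternative agrees to first order
  expect_equal(calibrate_taper_factor(meas, uncorr, method = "pooled_ratio"),
               f_hat, tolerance = 0.01)
})

test_that("stalk density from destructive sample inverts the cylinder model", {
  expect_equal(stalk_density_from_sample(2.33264, 0.03, 3.0), 1100,
               tolerance = 1e-4)
  expect_equal(stalk_density_from_sample(0, 0.03, 3.0), 0)
  expect_error(stalk_density_from_sample(1, 0, 3), class = "canemass_domain_error")

  # algebraic inverse of the biomass equation (taper removed first)
  set.seed(1)
  for (i in 1:10) {
    D <- runif(1, 0.01, 0.05); H <- runif(1, 0.5, 4); rho <- runif(1, 400, 1200)
    bm <- cane_biomass(D, H, rho, taper = 0.977)$BM_S
    expect_equal(stalk_density_from_sample(bm / 0.977, D, H), rho)
  }
})

test_that("wet content is the complement of the dry/wet ratio", {
  expect_equal(wet_content(0.030, 0.100), 0.70)
  expect_equal(wet_content(0.1, 0.1), 0)
  expect_equal(wet_content(0, 0.1), 1)
  expect_error(wet_content(0.2, 0.1), class = "canemass_domain_error")
  expect_error(wet_content(0.1, 0), class = "canemass_domain_error")
  set.seed(2)
  w <- runif(20, 0.01, 1); d <- w * runif(20)
  expect_true(all(wet_content(d, w) >= 0 & wet_content(d, w) <= 1))
})

test_that("LAI offset correction subtracts the mean calibration difference", {
  out <- correct_lai(2.5, calib_measured = c(2.0, 3.0),
                     calib_observed = c(1.8, 2.6))
  expect_equal(attr(out, "offset"), 0.3)
  expect_equal(out$actual, 2.2)
  expect_false(out$negative)

  # zero offset is the identity
  ident <- correct_lai(c(0.5, 2), calib_measured = 2, calib_observed = 2)
  expect_equal(ident$actual, c(0.5, 2))

  # negatives retained and flagged; clamped column on request
  neg <- correct_lai(0.2, calib_measured = 2.3, calib_observed = 2.0,
                     clamp = TRUE)
  expect_equal(neg$actual, -0.1)
  expect_true(neg$negative)
  expect_equal(neg$clamped, 0)

  expect_error(correct_lai(1, numeric(0), numeric(0)),
               class = "canemass_config_error")
})
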