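test_that("replicate precision is the sample standard deviation", {
  expect_equal(replicate_sd(c(2, 2, 2, 2, 2)), 0)
  expect_equal(replicate_sd(1:5), 1.5811, tolerance = 1e-4)
  expect_error(replicate_sd(3), class = "canemass_input_error")
})

test_that("five-replicate sd carries the known small-sample bias", {
  # E[s] = c4(5) * sigma ~= 0.94 * sigma; documented, not corrected
  set.seed(8)
  est <- mean(replicate(1e4, replicate_sd(rnorm(5, 10, 0.2))))
  expect_equal(est, 0.18800, tolerance = 0.02)
})

test_that("stalk-density propagation follows the inverse biomass equation", {
  expect_equal(
    sigma_rho_s(1000, 0.10, sigma_D = 0.05 * 1, D = 1, sigma_H = 0.05 * 1, H = 1),
    150.0
  )
  expect_equal(sigma_rho_s(1000, 0, 0, 1, 0, 1), 0)
  # homogeneity: doubling every sigma doubles the output
  a <- sigma_rho_s(900, 0.08, 0.002, 0.03, 0.2, 2.5)
  b <- sigma_rho_s(900, 0.16, 0.004, 0.03, 0.4, 2.5)
  expect_equal(b, 2 * a)
  expect_error(sigma_rho_s(1000, 0.1, 0.01, 0, 0.1, 1),
               class = "canemass_domain_error")
})

test_that("cane-biomass propagation reproduces hand arithmetic", {
  # all relative sigmas 0.05, BM_S = 2 kg, sigma_BML = 0.05 kg
  args <- list(D = 0.03, H = 3, rho_S = 1100, BM_S = 2,
               sigma_D = 0.0015, sigma_H = 0.15, sigma_rho = 55,
               sigma_BML = 0.05, BM_L = 0.1)
  add <- do.call(propagate_bmc, c(args, second_order = "additive"))
  expect_equal(add$theta, sqrt(0.015), tolerance = 1e-9)
  expect_equal(add$theta, 0.12247, tolerance = 1e-4)
  expect_equal(add$chi, 0.0025 * sqrt(10), tolerance = 1e-9)
  expect_equal(add$chi, 0.00791, tolerance = 1e-3)
  expect_equal(add$sigma_BMC, 0.2655, tolerance = 1e-3)

  quad <- do.call(propagate_bmc, c(args, second_order = "quadrature"))
  expect_equal(quad$theta, add$theta)
  expect_equal(quad$sigma_BMC,
               sqrt((sqrt(0.015) * 2)^2 + (0.0025 * sqrt(10) * 2)^2 + 0.05^2),
               tolerance = 1e-9)

  zero <- propagate_bmc(0.03, 3, 1100, BM_S = 2)
  expect_equal(zero$sigma_BMC, 0)
  leaf_only <- propagate_bmc(0.03, 3, 1100, BM_S = 2, sigma_BML = 0.07)
  expect_equal(leaf_only$sigma_BMC, 0.07)
})

test_that("TCH propagation reproduces hand arithmetic for both components", {
  args <- list(D = 0.03, H = 3, rho_S = 1100, BM_S = 2, C = 8,
               sigma_D = 0.0015, sigma_H = 0.15, sigma_rho = 55,
               sigma_C = 0.8, BM_L = 0.1, sigma_BML = 0.05, S = 1.2)
  add <- do.call(propagate_tch, c(args, second_order = "additive"))
  expect_equal(add$TSH, 2 * 8 * 10 / 1.2)
  expect_equal(add$TLH, 0.1 * 8 * 10 / 1.2)
  expect_equal(add$theta_TSH, 0.15811, tolerance = 1e-4)
  expect_equal(add$theta_TLH, 0.50990, tolerance = 1e-4)
  expect_equal(add$sigma_TCH, 23.33, tolerance = 1e-3)

  quad <- do.call(propagate_tch, c(args, second_order = "quadrature"))
  expect_equal(quad$sigma_TCH, 21.445, tolerance = 1e-3)

  none <- propagate_tch(0.03, 3, 1100, BM_S = 2, C = 8)
  expect_equal(none$sigma_TCH, 0)
})

test_that("delta-method precision matches a Monte-Carlo oracle", {
  # independent-Gaussian simulation of the full estimate, two CV settings
  mc_oracle <- function(cv, n = 2e5) {
    set.seed(99)
    D <- rnorm(n, 0.03, cv * 0.03); H <- rnorm(n, 3, cv * 3)
    R <- rnorm(n, 1100, cv * 1100); L <- rnorm(n, 0.1, cv * 0.1)
    C <- rnorm(n, 8, cv * 8)
    BMC <- pi * D^2 / 4 * H * R * 0.977 + L
    list(bmc = sd(BMC), tch = sd(BMC * C * 10 / 1.2))
  }
  for (cv in c(0.05, 0.10)) {
    mc <- mc_oracle(cv)
    bms <- pi * 0.03^2 / 4 * 3 * 1100 * 0.977
    dm_bmc <- propagate_bmc(0.03, 3, 1100, BM_S = bms,
                            sigma_D = cv * 0.03, sigma_H = cv * 3,
                            sigma_rho = cv * 1100, sigma_BML = cv * 0.1)
    dm_tch <- propagate_tch(0.03, 3, 1100, BM_S = bms, C = 8,
                            sigma_D = cv * 0.03, sigma_H = cv * 3,
                            sigma_rho = cv * 1100, sigma_C = cv * 8,
                            BM_L = 0.1, sigma_BML = cv * 0.1)
    expect_equal(dm_bmc$sigma_BMC, mc$bmc, tolerance = 0.05)
    expect_equal(dm_tch$sigma_TCH, mc$tch, tolerance = 0.05)
  }
})

test_that("first-order propagation is homogeneous and chi vanishes faster", {
  base <- propagate_bmc(0.03, 3, 1100, BM_S = 2, sigma_D = 0.001,
                        sigma_H = 0.1, sigma_rho = 40, sigma_BML = 0.02,
                        second_order = "none")
  scaled <- propagate_bmc(0.03, 3, 1100, BM_S = 2, sigma_D = 0.003,
                          sigma_H = 0.3, sigma_rho = 120, sigma_BML = 0.06,
                          second_order = "none")
  expect_equal(scaled$sigma_BMC, 3 * base$sigma_BMC)

  ratios <- vapply(c(0.1, 0.05, 0.01, 0.001), function(cv) {
    p <- propagate_bmc(0.03, 3, 1100, BM_S = 2, sigma_D = cv * 0.03,
                       sigma_H = cv * 3, sigma_rho = cv * 1100)
    p$chi / (p$theta + p$chi)
  }, numeric(1))
  # chi/theta shrinks linearly with the common CV
  expect_true(all(diff(ratios) < 0))
  expect_lt(ratios[4], ratios[1] / 50)
})

test_that("total precision at location is the prescribed tier mix", {
  mix <- total_precision_at_location(0.03, 3, 1100, BM_S = 2,
                                     sigma_D_ideal = 0.003,
                                     sigma_H_ideal = 0.329,
                                     sigma_rho_fit = 65,
                                     sigma_BML_fit = 0.058, BM_L = 0.1)
  direct <- propagate_bmc(0.03, 3, 1100, BM_S = 2, sigma_D = 0.003,
                          sigma_H = 0.329, sigma_rho = 65,
                          sigma_BML = 0.058, BM_L = 0.1)
  expect_equal(mix, direct)
  # with the fitting sigmas off it reduces to D/H-only propagation
  dh_only <- total_precision_at_location(0.03, 3, 1100, BM_S = 2,
                                         sigma_D_ideal = 0.003,
                                         sigma_H_ideal = 0.329,
                                         sigma_rho_fit = 0, sigma_BML_fit = 0)
  expect_equal(dh_only$theta, sqrt((2 * 0.1)^2 + (0.329 / 3)^2))
})

test_that("precision table: fitting sigma is the trend RMSE, zero noise gives zeros", {
  cfg <- homogeneous_config()
  cmp <- simulate_campaign(cfg)
  fits <- fit_growth_curves(cmp, force_origin = FALSE)
  intv <- simulate_intensive(cfg)
  pt <- suppressWarnings(build_precision_table(cmp, fits, intv))
  fit_rows <- pt$absolute[pt$absolute$tier == "fitting", ]
  expect_equal(fit_rows$sigma[fit_rows$parameter == "rho_S"],
               rep(fits$trends$rho_S$rmse, 3))
  expect_equal(fit_rows$sigma[fit_rows$parameter == "BM_L"],
               rep(fits$trends$BM_L$rmse, 3))
  # zero-noise campaign: every measured-tier sigma is 0
  meas <- pt$absolute[pt$absolute$tier %in%
                        c("instrument", "idealization", "within_esu"), ]
  expect_true(all(abs(meas$sigma) < 1e-9))
})

test_that("precision table recovers the generating sigmas", {
  cfg <- truth_config(seed = 31)
  cmp <- simulate_campaign(cfg)
  fits <- fit_growth_curves(cmp)
  intv <- simulate_intensive(cfg, n_sets = 10)
  pt <- suppressWarnings(build_precision_table(cmp, fits, intv))
  joined <- dplyr::inner_join(
    pt$absolute, cfg$precisions,
    by = c("parameter", "stage", "tier"), suffix = c("_est", "_true")
  ) |>
    dplyr::filter(tier %in% c("instrument", "idealization"), sigma_true > 0)
  rel_err <- abs(joined$sigma_est - joined$sigma_true) / joined$sigma_true
  expect_lt(median(rel_err), 0.20)
  # instrument <= idealization violations warn, never error
  expect_s3_class(pt$relative, "tbl_df")
})
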