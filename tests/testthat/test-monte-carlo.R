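test_that("zero perturbation gives identical replicates and a zero band", {
  t <- c(30, 80, 140, 200, 260, 320)
  y <- growth_logistic(t, 2.5, 0.028, 150)
  general <- fit_logistic(t, y * c(1.02, 0.98, 1.01, 0.99, 1.02, 0.98),
                          force_origin = FALSE)
  ens <- perturb_and_refit(t, y, sigma = 0, general = general, n = 20,
                           seed = 1, t_grid = seq(0, 330, by = 30))
  expect_equal(max(ens$band$sd), 0)
  expect_equal(unname(apply(ens$curves, 2, function(col) diff(range(col)))),
               rep(0, ncol(ens$curves)))
})

test_that("perturbation ensembles are reproducible under a fixed seed", {
  set.seed(77)
  t <- c(30, 80, 140, 200, 260, 320)
  y <- growth_logistic(t, 2.5, 0.028, 150) + rnorm(6, 0, 0.1)
  general <- fit_logistic(t, y, force_origin = FALSE)
  a <- perturb_and_refit(t, y, 0.1, general, n = 30, seed = 5)
  b <- perturb_and_refit(t, y, 0.1, general, n = 30, seed = 5)
  expect_identical(a$band, b$band)
  expect_identical(a$params, b$params)
})

test_that("band width grows with the input sigma", {
  set.seed(13)
  t <- rep(c(30, 80, 140, 200, 260, 320), 3)
  y <- growth_logistic(t, 2.5, 0.028, 150) + rnorm(length(t), 0, 0.05)
  general <- fit_logistic(t, y, force_origin = FALSE)
  widths <- vapply(c(0.02, 0.1, 0.3), function(s) {
    mean(perturb_and_refit(t, y, s, general, n = 60, seed = 11)$band$sd)
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("with shape parameters pinned the band matches the closed form", {
  # pin k and t0 so the re-fit estimates only the asymptote; the estimator
  # is then linear in the data and its s.e. is known exactly:
  # sd(delta_hat) = sigma / sqrt(sum f0(t)^2),  band sd(t*) = f0(t*) sd(delta_hat)
  t <- seq(20, 340, by = 10)
  truth <- c(delta_y = 2.5, k = 0.03, t0 = 150)
  f0 <- growth_logistic(t, 1, truth["k"], truth["t0"])
  y <- truth["delta_y"] * f0
  general <- fake_logistic_fit(truth, half_widths = c(2, 1e-9, 1e-9),
                               data = tibble::tibble(t = t, y = y))
  sigma <- 0.2
  ens <- perturb_and_refit(t, y, sigma, general, n = 100, seed = 21,
                           t_grid = c(150, 250, 330))
  se_delta <- sigma / sqrt(sum(f0^2))
  expected <- growth_logistic(c(150, 250, 330), 1, truth["k"], truth["t0"]) *
    se_delta
  expect_equal(ens$band$sd, expected, tolerance = 0.10)
})

test_that("tch profile: degenerate ensembles give the pointwise product", {
  t_grid <- seq(0, 330, by = 30)
  bm_fit <- fake_logistic_fit(c(delta_y = 2.5, k = 0.028, t0 = 150),
                              c(0.5, 0.005, 20))
  dn_fit <- fake_logistic_fit(c(delta_y = 20, k = -0.004, t0 = 300),
                              c(2, 0.002, 30))
  bm_curve <- predict(bm_fit, t_grid)
  dn_curve <- predict(dn_fit, t_grid)
  mk_ens <- function(fit, curve, n) {
    structure(list(params = tibble::tibble(), t_grid = t_grid,
                   curves = matrix(rep(curve, each = n), nrow = n),
                   base_fit = fit, band = NULL, n_failed = 0L),
              class = "perturbation_ensemble")
  }
  prof <- tch_profile(mk_ens(bm_fit, bm_curve, 10), mk_ens(dn_fit, dn_curve, 10))
  expect_equal(prof$mean, tch(bm_curve, dn_curve, 1.2))
  expect_equal(max(prof$sd), 0)

  bad <- mk_ens(dn_fit, dn_curve, 10)
  bad$t_grid <- bad$t_grid + 1
  expect_error(tch_profile(mk_ens(bm_fit, bm_curve, 10), bad),
               class = "canemass_input_error")
})

test_that("product-band relative variance adds component-wise for small CVs", {
  t_grid <- seq(60, 330, by = 30)
  bm_fit <- fake_logistic_fit(c(delta_y = 2.5, k = 0.028, t0 = 150),
                              c(0.5, 0.005, 20))
  dn_fit <- fake_logistic_fit(c(delta_y = 20, k = -0.004, t0 = 300),
                              c(2, 0.002, 30))
  bm_curve <- predict(bm_fit, t_grid)
  dn_curve <- predict(dn_fit, t_grid)
  cv_a <- 0.05; cv_b <- 0.08
  set.seed(3)
  n <- 200
  mk_scaled <- function(fit, curve, cv) {
    structure(list(params = tibble::tibble(), t_grid = t_grid,
                   curves = outer(rnorm(n, 1, cv), curve),
                   base_fit = fit, band = NULL, n_failed = 0L),
              class = "perturbation_ensemble")
  }
  prof <- tch_profile(mk_scaled(bm_fit, bm_curve, cv_a),
                      mk_scaled(dn_fit, dn_curve, cv_b))
  rel <- prof$sd / tch(bm_curve, dn_curve, 1.2)
  expect_equal(rel, rep(sqrt(cv_a^2 + cv_b^2), length(rel)), tolerance = 0.10)
})

test_that("the campaign-level bands shrink from early to late season", {
  cfg <- truth_config(seed = 61)
  cmp <- simulate_campaign(cfg)
  fits <- fit_growth_curves(cmp)
  intv <- simulate_intensive(cfg)
  pt <- suppressWarnings(build_precision_table(cmp, fits, intv))
  profs <- campaign_tch_uncertainty(cmp, fits, pt, n_biomass = 30,
                                    n_density = 30, seed = 8,
                                    t_grid = seq(40, 330, by = 10))
  stage_rel <- purrr::map_dfr(profs, profile_stage_precision) |>
    dplyr::group_by(stage) |>
    dplyr::summarise(rel = mean(rel_sd_pct), .groups = "drop")
  early <- stage_rel$rel[stage_rel$stage == "early"]
  late <- stage_rel$rel[stage_rel$stage == "late"]
  expect_gt(early, late)
})
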