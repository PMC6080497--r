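test_that("logistic fit recovers exact-data coefficients", {
  t <- c(20, 60, 100, 140, 180, 220, 280, 340)
  truth <- c(delta_y = 2.5, k = 0.03, t0 = 150)
  y <- growth_logistic(t, truth[1], truth[2], truth[3])
  fit <- fit_logistic(t, y, force_origin = FALSE)
  expect_equal(coef(fit), truth, tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-8)
  # sigmoid identity: f(t0) = delta_y / 2
  expect_equal(predict(fit, coef(fit)["t0"]),
               unname(coef(fit)["delta_y"]) / 2, ignore_attr = TRUE)
  # declining curve (k < 0), the cane-density shape
  yd <- growth_logistic(t, 20, -0.004, 300)
  fd <- fit_logistic(t, yd, force_origin = FALSE)
  expect_equal(coef(fd), c(delta_y = 20, k = -0.004, t0 = 300),
               tolerance = 1e-5)
})

test_that("logistic curve is monotone and bounded for k > 0", {
  t <- seq(0, 400, by = 5)
  y <- growth_logistic(t, 3, 0.02, 180)
  expect_true(all(diff(y) > 0))
  expect_true(all(y > 0 & y < 3))
  # asymptote
  expect_equal(growth_logistic(1e6, 2.5, 0.03, 150), 2.5, tolerance = 1e-9)
  expect_equal(growth_logistic(150, 2.5, 0.03, 150), 1.25)
})

test_that("origin forcing pulls the early curve towards zero", {
  t <- c(60, 120, 180, 240, 300)
  y <- growth_logistic(t, 2.5, 0.02, 150) + 0.3   # offset data away from 0
  free <- fit_logistic(t, y, force_origin = FALSE)
  forced <- fit_logistic(t, y, force_origin = TRUE, origin_weight = 5)
  expect_lt(abs(predict(forced, 0)), abs(predict(free, 0)))
})

test_that("logistic fit validates its inputs and reports uncertainty", {
  expect_error(fit_logistic(1:3, 1:3), class = "canemass_input_error")
  expect_error(fit_logistic(c(-5, 1, 2, 3), c(1, 2, 3, 4)),
               class = "canemass_domain_error")
  set.seed(3)
  t <- seq(20, 340, by = 20)
  y <- growth_logistic(t, 2.5, 0.03, 150) + rnorm(length(t), 0, 0.1)
  fit <- fit_logistic(t, y)
  expect_true(all(fit$ci95[, "lower"] <= coef(fit)))
  expect_true(all(coef(fit) <= fit$ci95[, "upper"]))
  expect_gt(fit$rmse, 0)
  expect_identical(fit$n_obs, length(t))
})

test_that("constrained refit is self-consistent on the pooled data", {
  set.seed(4)
  t <- rep(c(30, 80, 140, 200, 260, 320), 4)
  y <- growth_logistic(t, 2.5, 0.028, 150) * (1 + rnorm(length(t), 0, 0.08))
  general <- fit_logistic(t, y, force_origin = FALSE)
  re <- refit_constrained(general, t, y)
  expect_equal(coef(re), coef(general), tolerance = 1e-6)
})

test_that("constrained refit always lands inside the widened bounds", {
  set.seed(5)
  for (i in 1:30) {
    t <- c(30, 70, 110, 150, 200, 250, 300, 330)
    truth_dy <- runif(1, 1.5, 3.5)
    y_pool <- growth_logistic(t, truth_dy, runif(1, 0.015, 0.04),
                              runif(1, 120, 200)) *
      (1 + rnorm(length(t), 0, 0.1))
    general <- fit_logistic(t, y_pool, force_origin = FALSE)
    y_sub <- y_pool * runif(1, 0.7, 1.3)
    re <- refit_constrained(general, t, y_sub)
    b <- re$bounds
    expect_true(all(coef(re) >= b$lower - 1e-9))
    expect_true(all(coef(re) <= b$upper + 1e-9))
  }
})

test_that("per-field refits pull towards field-level truth within bounds", {
  t <- rep(c(30, 70, 110, 150, 200, 250, 300, 330), 2)
  fid <- rep(c("A", "B"), each = 8)
  dy <- c(A = 2.2, B = 2.8)
  set.seed(6)
  y <- growth_logistic(t, dy[fid], 0.028, 150) * (1 + rnorm(length(t), 0, 0.05))
  general <- fit_logistic(t, y, force_origin = FALSE)
  re_a <- refit_constrained(general, t[fid == "A"], y[fid == "A"])
  re_b <- refit_constrained(general, t[fid == "B"], y[fid == "B"])
  expect_lt(coef(re_a)["delta_y"], coef(general)["delta_y"])
  expect_gt(coef(re_b)["delta_y"], coef(general)["delta_y"])
  expect_lt(abs(coef(re_a)["delta_y"] - 2.2), abs(coef(general)["delta_y"] - 2.2))
  expect_lt(abs(coef(re_b)["delta_y"] - 2.8), abs(coef(general)["delta_y"] - 2.8))
})

test_that("trend fits recover exact data and expose RMSE", {
  lin <- fit_trend(c(1, 2), c(2, 4), "linear_through_origin")
  expect_equal(unname(coef(lin)), 2)
  expect_equal(lin$rmse, 0)

  t <- seq(10, 350, by = 20)
  y <- 0.002 * t + 1e-5 * t^2
  p2 <- fit_trend(t, y, "poly2_through_origin")
  expect_equal(unname(coef(p2)), c(0.002, 1e-5), tolerance = 1e-9)

  full <- fit_trend(t, 450 + 1.5 * t, "linear")
  expect_equal(unname(coef(full)), c(450, 1.5), tolerance = 1e-9)

  expect_error(fit_trend(1, 2, "linear"), class = "canemass_input_error")
  # constant abscissa makes the slope unidentifiable
  expect_error(fit_trend(rep(5, 4), 1:4, "linear"), class = "canemass_fit_error")
})

test_that("trend RMSE estimates the generating noise level", {
  # stalk-density-like fit: sd 65 kg/m^3 on a linear trend, n = 30
  set.seed(7)
  rmses <- replicate(5, {
    t <- seq(10, 350, length.out = 30)
    y <- 450 + 1.5 * t + rnorm(30, 0, 65)
    fit_trend(t, y, "linear")$rmse
  })
  expect_equal(mean(rmses), 65, tolerance = 0.2)
})

test_that("growth stages split at days 150 and 300", {
  expect_equal(as.character(growth_stage(c(0, 100, 149))),
               rep("early", 3))
  expect_equal(as.character(growth_stage(c(150, 225, 300))), rep("mid", 3))
  expect_equal(as.character(growth_stage(c(301, 400))), rep("late", 2))
  expect_error(growth_stage(-1), class = "canemass_domain_error")
})
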