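#' Three-parameter logistic growth curve
#'
#' `f(t) = delta_y / (1 + exp(-k (t - t0)))`: `delta_y` is the horizontal
#' asymptote (the limiting value of the fitted quantity), `k` the growth
#' rate (1/day) and `t0` the sigmoid midpoint (day). Negative `k` gives a
#' declining curve (used for cane spatial density over the season).
#'
#' @param t Days since start of growth.
#' @param delta_y Asymptote, in the units of the modelled quantity.
#' @param k Growth rate, 1/day.
#' @param t0 Sigmoid midpoint, day.
#' @return Curve values at `t`.
#' @export
growth_logistic <- function(t, delta_y, k, t0) {
  # clamp the exponent so extreme t never overflows
  z <- pmin(pmax(-k * (t - t0), -700), 700)
  delta_y / (1 + exp(z))
}

logistic_jacobian <- function(t, delta_y, k, t0) {
  z <- pmin(pmax(-k * (t - t0), -700), 700)
  e <- exp(z)
  denom <- (1 + e)^2
  cbind(
    delta_y = 1 / (1 + e),
    k = delta_y * (t - t0) * e / denom,
    t0 = -delta_y * k * e / denom
  )
}

logistic_start <- function(t, y) {
  y_max <- max(y)
  y_min <- min(y)
  delta0 <- max(y_max * 1.05, 1e-8)
  # map onto the logit scale and regress to get slope/midpoint seeds
  frac <- pmin(pmax(y / delta0, 1e-3), 1 - 1e-3)
  z <- log(frac / (1 - frac))
  sl <- tryCatch(coef(lm(z ~ t)), error = function(e) c(0, 0.01))
  k0 <- sl[[2]]
  if (!is.finite(k0) || abs(k0) < 1e-6) {
    k0 <- if (stats::cor(t, y) >= 0) 0.02 else -0.02
  }
  t00 <- -sl[[1]] / k0
  if (!is.finite(t00)) t00 <- mean(t)
  t00 <- min(max(t00, min(t) - diff(range(t))), max(t) + diff(range(t)))
  # declining curves start near the asymptote, so seed delta at the top
  if (k0 < 0) delta0 <- max(y_max * 1.02, 1e-8)
  c(delta_y = delta0, k = k0, t0 = t00)
}

#' Fit a logistic growth curve by nonlinear least squares
#'
#' Levenberg-Marquardt least squares with analytic Jacobian and optional
#' box bounds on the coefficients. "Forcing through the origin" is
#' implemented as an appended pseudo-observation (t = 0, y = 0) with a
#' configurable weight: a three-parameter logistic is strictly positive at
#' t = 0, so an exact origin constraint is impossible; the pseudo-point
#' reproduces the intent (curve near zero at the start of growth) without
#' breaking the functional form.
#'
#' @param t Days since start of growth (non-negative).
#' @param y Observed values.
#' @param force_origin Append the (0, 0) pseudo-observation?
#' @param origin_weight Weight of the pseudo-observation relative to one
#'   real observation.
#' @param bounds Optional list with numeric vectors `lower` and `upper` of
#'   length 3 (`delta_y`, `k`, `t0`).
#' @param start Optional named starting values; a data-driven heuristic is
#'   used otherwise.
#' @param control List of optimizer tolerances: `ftol`, `ptol` (relative
#'   tolerances, default 1e-10) and `maxfev` (max function evaluations,
#'   default 10000).
#' @return An object of class `logistic_fit`: coefficients, 95% confidence
#'   intervals from the linearized (Jacobian-based) covariance with
#'   t-quantiles at `n - 3` degrees of freedom, RMSE over the real
#'   observations, and fit metadata. Supports [predict()], [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' t <- seq(20, 340, by = 40)
#' y <- growth_logistic(t, 2.5, 0.03, 150)
#' fit_logistic(t, y, force_origin = FALSE)
#' @export
fit_logistic <- function(t, y, force_origin = FALSE, origin_weight = 1,
                         bounds = NULL, start = NULL, control = list()) {
  if (length(t) != length(y)) stop_input("`t` and `y` must have equal length")
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (length(t) < 4) stop_input("need at least 4 observations to fit 3 coefficients")
  if (any(t < 0)) stop_domain("`t` must be non-negative")

  ctrl <- utils::modifyList(list(ftol = 1e-10, ptol = 1e-10, maxfev = 10000), control)
  n_real <- length(t)
  w <- rep(1, n_real)
  tf <- t; yf <- y
  if (force_origin) {
    tf <- c(tf, 0); yf <- c(yf, 0); w <- c(w, origin_weight)
  }
  sw <- sqrt(w)

  par0 <- start %||% logistic_start(t, y)
  lower <- c(1e-12, -Inf, -Inf)
  upper <- c(Inf, Inf, Inf)
  if (!is.null(bounds)) {
    lower <- pmax(lower, bounds$lower)
    upper <- pmin(upper, bounds$upper)
    par0 <- pmin(pmax(par0, lower), upper)
  }

  resid_fn <- function(p) sw * (growth_logistic(tf, p[1], p[2], p[3]) - yf)
  jac_fn <- function(p) sw * logistic_jacobian(tf, p[1], p[2], p[3])

  res <- minpack.lm::nls.lm(
    par = par0, fn = resid_fn, jac = jac_fn,
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(
      ftol = ctrl$ftol, ptol = ctrl$ptol, maxfev = ctrl$maxfev, maxiter = 1024
    )
  )
  if (res$info == 0 || res$info == 5) {
    rlang::abort(
      sprintf("logistic fit did not converge (info = %d: %s)", res$info, res$message),
      class = "canemass_fit_error",
      diagnostics = list(info = res$info, par = res$par, start = par0)
    )
  }
  est <- setNames(as.numeric(res$par), c("delta_y", "k", "t0"))

  # linearized covariance; guard the rank-deficient / saturated cases
  J <- jac_fn(est)
  r_all <- resid_fn(est)
  dof <- max(n_real - 3, 1)
  s2 <- sum(r_all^2) / dof
  JtJ <- crossprod(J)
  cov_ok <- is.finite(determinant(JtJ, logarithm = TRUE)$modulus) &&
    rcond(JtJ) > 1e-14
  if (cov_ok) {
    se <- sqrt(pmax(diag(solve(JtJ)) * s2, 0))
  } else {
    se <- rep(NA_real_, 3)
  }
  tq <- qt(0.975, dof)
  ci95 <- cbind(lower = est - tq * se, upper = est + tq * se)
  rownames(ci95) <- names(est)

  r_real <- growth_logistic(t, est[1], est[2], est[3]) - y
  structure(
    list(
      coefficients = est,
      ci95 = ci95,
      se = setNames(se, names(est)),
      rmse = sqrt(mean(r_real^2)),
      n_obs = n_real,
      converged = TRUE,
      force_origin = force_origin,
      origin_weight = origin_weight,
      bounds = if (is.null(bounds)) NULL else list(lower = lower, upper = upper),
      data = tibble(t = t, y = y),
      optimizer = list(info = res$info, message = res$message, niter = res$niter)
    ),
    class = "logistic_fit"
  )
}

#' @export
predict.logistic_fit <- function(object, t = NULL, ...) {
  t <- t %||% object$data$t
  p <- object$coefficients
  growth_logistic(unname(t), p[["delta_y"]], p[["k"]], p[["t0"]])
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' @export
print.logistic_fit <- function(x, ...) {
  p <- x$coefficients
  cat(sprintf(
    "Logistic growth fit: delta_y = %.4g, k = %.4g /day, t0 = %.4g day\n",
    p["delta_y"], p["k"], p["t0"]
  ))
  cat(sprintf("  n = %d, rmse = %.4g%s\n", x$n_obs, x$rmse,
              if (x$force_origin) ", origin-forced" else ""))
  invisible(x)
}

#' Widen a confidence interval into re-fit box bounds
#'
#' Each side of the interval is pushed outwards. The default convention
#' widens by a fraction of the interval half-width (symmetric in the
#' coefficient scale); the alternative widens each bound by a fraction of
#' its own magnitude.
#'
#' @param ci95 3x2 matrix of (lower, upper) bounds.
#' @param estimate Coefficient estimates (used to keep the box non-empty
#'   when an interval is degenerate).
#' @param expansion Widening fraction (default 0.10).
#' @param mode `"halfwidth"` or `"value"`.
#' @return List with `lower` and `upper` length-3 vectors.
#' @keywords internal
widen_bounds <- function(ci95, estimate, expansion = 0.10,
                         mode = c("halfwidth", "value")) {
  mode <- match.arg(mode)
  lo <- ci95[, "lower"]; hi <- ci95[, "upper"]
  bad <- !is.finite(lo) | !is.finite(hi)
  # degenerate/absent intervals fall back to a window around the estimate
  lo[bad] <- estimate[bad] - pmax(abs(estimate[bad]), 1) * 0.5
  hi[bad] <- estimate[bad] + pmax(abs(estimate[bad]), 1) * 0.5
  if (mode == "halfwidth") {
    half <- (hi - lo) / 2
    lo <- lo - expansion * half
    hi <- hi + expansion * half
  } else {
    lo <- lo - expansion * abs(lo)
    hi <- hi + expansion * abs(hi)
  }
  lo["delta_y"] <- max(lo["delta_y"], 1e-12)
  # keep the box non-degenerate so the optimizer accepts it
  eps <- pmax(abs(estimate) * 1e-9, 1e-12)
  hi <- pmax(hi, lo + eps)
  list(lower = unname(lo), upper = unname(hi))
}

#' Constrained per-field / per-unit logistic re-fit
#'
#' The hierarchical step of the growth-interpolator scheme: a pooled
#' "general" fit across all fields supplies starting values (its
#' coefficient estimates) and box bounds (its 95% confidence intervals,
#' widened by `expansion` to allow flexibility) for a re-fit on one field's
#' or one sampling unit's data. The returned coefficients always lie inside
#' the widened bounds.
#'
#' @param general A `logistic_fit` from the pooled data.
#' @param t,y The subset data to re-fit.
#' @param expansion Bound-widening fraction (default 0.10).
#' @param expansion_mode See [widen_bounds()].
#' @inheritParams fit_logistic
#' @return A `logistic_fit` whose `bounds` element records the widened box.
#' @export
refit_constrained <- function(general, t, y, expansion = 0.10,
                              expansion_mode = c("halfwidth", "value"),
                              force_origin = general$force_origin,
                              origin_weight = general$origin_weight,
                              control = list()) {
  if (!inherits(general, "logistic_fit")) stop_input("`general` must be a logistic_fit")
  b <- widen_bounds(general$ci95, general$coefficients, expansion,
                    match.arg(expansion_mode))
  start <- pmin(pmax(general$coefficients, b$lower), b$upper)
  fit <- fit_logistic(t, y, force_origin = force_origin,
                      origin_weight = origin_weight,
                      bounds = b, start = start, control = control)
  fit$general <- general$coefficients
  fit
}

#' Ordinary least-squares trend fits for auxiliary quantities
#'
#' Fits the time trends that feed the biomass equation: a linear trend for
#' stalk mass density, and through-origin polynomials for leaf biomass per
#' cane and LAI. The overall RMSE of the fit is the "function fitting
#' precision" of the quantity, used directly as its sigma in error
#' propagation.
#'
#' @param t Days since start of growth.
#' @param y Observed values.
#' @param kind `"linear"` (`y = a + b t`), `"linear_through_origin"`
#'   (`y = b t`) or `"poly2_through_origin"` (`y = c1 t + c2 t^2`).
#' @return An object of class `trend_fit` with `coefficients`, `rmse`,
#'   `n_obs` and the model `kind`; supports [predict()], [tidy()] and
#'   [glance()].
#' @examples
#' fit_trend(c(1, 2), c(2, 4), "linear_through_origin")
#' @export
fit_trend <- function(t, y, kind = c("linear", "linear_through_origin",
                                     "poly2_through_origin")) {
  kind <- match.arg(kind)
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  n_coef <- switch(kind, linear = 2L, linear_through_origin = 1L,
                   poly2_through_origin = 2L)
  if (length(t) < n_coef) stop_input("fewer points than coefficients")
  fit <- switch(kind,
    linear = lm(y ~ t),
    linear_through_origin = lm(y ~ t - 1),
    poly2_through_origin = lm(y ~ t + I(t^2) - 1)
  )
  if (any(is.na(coef(fit)))) {
    rlang::abort("rank-deficient trend fit", class = "canemass_fit_error")
  }
  cf <- coef(fit)
  names(cf) <- switch(kind,
    linear = c("intercept", "slope"),
    linear_through_origin = "slope",
    poly2_through_origin = c("c1", "c2")
  )
  structure(
    list(
      kind = kind,
      coefficients = cf,
      rmse = sqrt(mean(fit$residuals^2)),
      n_obs = length(t),
      data = tibble(t = t, y = y)
    ),
    class = "trend_fit"
  )
}

#' @export
predict.trend_fit <- function(object, t = NULL, ...) {
  t <- t %||% object$data$t
  cf <- object$coefficients
  switch(object$kind,
    linear = cf["intercept"] + cf["slope"] * t,
    linear_through_origin = cf["slope"] * t,
    poly2_through_origin = cf["c1"] * t + cf["c2"] * t^2
  )
}

#' @export
coef.trend_fit <- function(object, ...) object$coefficients

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Trend fit (%s): %s; rmse = %.4g, n = %d\n", x$kind,
              paste(sprintf("%s = %.4g", names(x$coefficients), x$coefficients),
                    collapse = ", "),
              x$rmse, x$n_obs))
  invisible(x)
}

#' Growth-stage classification
#'
#' Classifies days since start of growth into the three campaign stages:
#' early (before day 150), mid (day 150 up to and including day 300) and
#' late (after day 300).
#'
#' @param t Days since start of growth (non-negative).
#' @return Factor with levels `early`, `mid`, `late`.
#' @examples
#' growth_stage(c(100, 150, 301))
#' @export
growth_stage <- function(t) {
  if (any(t < 0, na.rm = TRUE)) stop_domain("`t` must be non-negative")
  factor(
    ifelse(t < 150, "early", ifelse(t <= 300, "mid", "late")),
    levels = c("early", "mid", "late")
  )
}

#' Stage midpoints used as representative evaluation days
#'
#' Days 75, 225 and 350: the centres of the early and mid stages and a
#' representative late-season day, used when stage-mean values of fitted
#' quantities are needed (e.g. relative precision tables).
#'
#' @return Named numeric vector (`early`, `mid`, `late`).
#' @export
stage_midpoints <- function() {
  c(early = 75, mid = 225, late = 350)
}
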