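# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' Tidy a logistic growth fit
#'
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @return One row per coefficient with `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    conf.low = unname(x$ci95[, "lower"]),
    conf.high = unname(x$ci95[, "upper"])
  )
}

#' Glance at a logistic growth fit
#'
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @return One-row tibble with `rmse`, `n_obs`, `converged`,
#'   `force_origin`.
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble(rmse = x$rmse, n_obs = x$n_obs, converged = x$converged,
         force_origin = x$force_origin)
}

#' Tidy a trend fit
#'
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @return One row per coefficient with `term` and `estimate`.
#' @export
tidy.trend_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' Glance at a trend fit
#'
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @return One-row tibble with `kind`, `rmse`, `n_obs`.
#' @export
glance.trend_fit <- function(x, ...) {
  tibble(kind = x$kind, rmse = x$rmse, n_obs = x$n_obs)
}

#' Plot a logistic growth fit
#'
#' Observations with the fitted sigmoid overlaid.
#'
#' @param object A `logistic_fit`.
#' @param n_grid Curve resolution.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.logistic_fit <- function(object, n_grid = 200, ...) {
  grid <- tibble(t = seq(0, max(object$data$t), length.out = n_grid))
  grid$y <- predict(object, grid$t)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "#2c7fb8", linewidth = 0.8) +
    ggplot2::labs(x = "days since start of growth", y = "fitted quantity") +
    ggplot2::theme_minimal()
}

#' Plot a TCH profile with its one-standard-deviation band
#'
#' @param object A `tch_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tch_profile <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "#a6bddb", alpha = 0.6) +
    ggplot2::geom_line(colour = "#2b8cbe", linewidth = 0.8) +
    ggplot2::labs(x = "days since start of growth", y = "TCH [t/ha]",
                  title = attr(object, "unit_id")) +
    ggplot2::theme_minimal()
}

#' Plot an empirical variogram
#'
#' @param object A `variogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.variogram <- function(object, ...) {
  d <- dplyr::filter(as_tibble(object), !is.na(.data$two_gamma))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$h, y = .data$two_gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.7) +
    ggplot2::scale_size_continuous(name = "pairs") +
    ggplot2::labs(x = "lag distance h [m]",
                  y = expression(2 * gamma ~ "[(t/ha)"^2 * "]")) +
    ggplot2::theme_minimal()
}

#' Plot a perturbation ensemble band
#'
#' @param object A `perturbation_ensemble`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.perturbation_ensemble <- function(object, ...) {
  b <- object$band
  base <- tibble(t = object$t_grid, y = predict(object$base_fit, object$t_grid))
  ggplot2::ggplot(b, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "#fdbb84", alpha = 0.5) +
    ggplot2::geom_line(data = base, ggplot2::aes(y = .data$y),
                       colour = "#e34a33", linewidth = 0.8) +
    ggplot2::labs(x = "days since start of growth", y = "fitted quantity") +
    ggplot2::theme_minimal()
}
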