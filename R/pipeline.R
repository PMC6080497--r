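# Campaign pipeline: biometrics -> biomass estimates -> growth curves -> TCH.

#' Average biometric records per sampling-unit visit
#'
#' Collapses corner replicates to one row per (field, unit, visit):
#' means of stalk height, diameter, cane and plant counts and effective
#' LAI.
#'
#' @param x A [campaign] object.
#' @return Tibble with one row per unit visit.
#' @export
unit_means <- function(x) {
  stopifnot(inherits(x, "campaign"))
  x$biometrics |>
    dplyr::group_by(.data$field_id, .data$unit_id, .data$unit_kind, .data$t) |>
    dplyr::summarise(
      dplyr::across(dplyr::any_of(c("H", "D", "C_row", "P_row", "LAI_eff")),
                    ~ mean(.x, na.rm = TRUE)),
      n_corners = dplyr::n(),
      .groups = "drop"
    )
}

#' Fit the auxiliary time trends from destructive records
#'
#' Stalk mass density follows a linear trend in time (sucrose accumulation
#' makes stalks denser), and leaf biomass per cane a through-origin
#' second-order polynomial. The RMSEs of these fits are the
#' function-fitting precisions used in error propagation.
#'
#' @param x A [campaign] object with destructive (`biomass`) records.
#' @param leaf_through_origin Force the leaf polynomial through the origin
#'   (default `TRUE`).
#' @return List with `trend_fit` elements `rho_S` and `BM_L`.
#' @export
fit_campaign_trends <- function(x, leaf_through_origin = TRUE) {
  stopifnot(inherits(x, "campaign"))
  bm <- x$biomass
  if (nrow(bm) == 0) stop_input("campaign has no destructive records")
  list(
    rho_S = fit_trend(bm$t, bm$rho_S, "linear"),
    BM_L = fit_trend(bm$t, bm$BM_L,
                     if (leaf_through_origin) "poly2_through_origin" else "linear")
  )
}

#' Estimate per-cane biomass for every sampling-unit visit
#'
#' Applies the allometric biomass equation to the unit-visit mean
#' biometrics, taking stalk density and leaf biomass from their fitted
#' time trends, and appends the directly measured cane masses from the
#' destructive records. The result is the pooled input for the general
#' growth-curve fit.
#'
#' @param x A [campaign] object.
#' @param trends Trend fits from [fit_campaign_trends()]; fitted from `x`
#'   when `NULL`.
#' @param taper Taper scaling factor (default 0.977).
#' @param spacing Mean row spacing, m (default 1.2).
#' @return Tibble with columns `field_id`, `unit_id`, `t`, `source`
#'   (`"estimated"` or `"measured"`), `BM_C`, `C_row`, `TCH`.
#' @export
estimate_biomass <- function(x, trends = NULL, taper = 0.977, spacing = 1.2) {
  stopifnot(inherits(x, "campaign"))
  trends <- trends %||% fit_campaign_trends(x)
  um <- unit_means(x)
  est <- um |>
    dplyr::mutate(
      rho_S = predict(trends$rho_S, .data$t),
      BM_L = pmax(predict(trends$BM_L, .data$t), 0),
      BM_C = cane_biomass(.data$D, .data$H, .data$rho_S, taper, .data$BM_L)$BM_C,
      source = "estimated"
    ) |>
    dplyr::select("field_id", "unit_id", "t", "source", "BM_C", "C_row")
  meas <- x$biomass |>
    dplyr::mutate(source = "measured", BM_C = .data$cane_mass, C_row = NA_real_) |>
    dplyr::select("field_id", "unit_id", "t", "source", "BM_C", "C_row")
  out <- dplyr::bind_rows(est, meas) |>
    dplyr::mutate(TCH = ifelse(is.na(.data$C_row), NA_real_,
                               tch(.data$BM_C, .data$C_row, spacing)))
  out
}

#' Fit the hierarchical growth-curve system for a campaign
#'
#' The two-level interpolator scheme: (1) a general logistic fit pooling
#' all cane-biomass values (estimated and measured) across fields, forced
#' towards the origin, then per-field constrained re-fits inside the
#' general fit's widened 95% confidence box; (2) the same hierarchy for
#' cane spatial density, with a general fit across all units and per-unit
#' re-fits (density declines over the season, so its logistic is not
#' origin-forced).
#'
#' @param x A [campaign] object.
#' @param estimates Biomass estimates from [estimate_biomass()]; computed
#'   from `x` when `NULL`.
#' @param force_origin Origin-force the biomass logistic (default `TRUE`).
#' @param expansion Confidence-bound widening fraction for the re-fits.
#' @param control Optimizer control list, see [fit_logistic()].
#' @return An object of class `campaign_fits`: `trends`, `biomass_general`,
#'   `biomass_fields` (named list), `density_general`, `density_units`
#'   (named list), and the unit-to-field map.
#' @export
fit_growth_curves <- function(x, estimates = NULL, force_origin = TRUE,
                              expansion = 0.10, control = list()) {
  stopifnot(inherits(x, "campaign"))
  trends <- fit_campaign_trends(x)
  estimates <- estimates %||% estimate_biomass(x, trends)

  general_bm <- fit_logistic(estimates$t, estimates$BM_C,
                             force_origin = force_origin, control = control)
  biomass_fields <- estimates |>
    dplyr::group_by(.data$field_id) |>
    dplyr::group_split() |>
    purrr::map(~ refit_constrained(general_bm, .x$t, .x$BM_C,
                                   expansion = expansion, control = control))
  names(biomass_fields) <- estimates |>
    dplyr::group_by(.data$field_id) |>
    dplyr::group_keys() |>
    dplyr::pull(.data$field_id)

  um <- unit_means(x)
  dens <- dplyr::filter(um, !is.na(.data$C_row))
  general_c <- fit_logistic(dens$t, dens$C_row, force_origin = FALSE,
                            control = control)
  dens_split <- dens |> dplyr::group_by(.data$unit_id) |> dplyr::group_split()
  density_units <- purrr::map(
    dens_split,
    ~ refit_constrained(general_c, .x$t, .x$C_row,
                        expansion = expansion, force_origin = FALSE,
                        control = control)
  )
  names(density_units) <- purrr::map_chr(dens_split, ~ .x$unit_id[1])
  unit_map <- dplyr::distinct(um, .data$field_id, .data$unit_id, .data$unit_kind)

  structure(
    list(
      trends = trends,
      biomass_general = general_bm,
      biomass_fields = biomass_fields,
      density_general = general_c,
      density_units = density_units,
      unit_map = unit_map
    ),
    class = "campaign_fits"
  )
}

#' @export
print.campaign_fits <- function(x, ...) {
  cat(sprintf(
    "Campaign growth-curve fits: general biomass (delta_y = %.3g kg) + %d field re-fits; general density + %d unit re-fits\n",
    x$biomass_general$coefficients["delta_y"],
    length(x$biomass_fields), length(x$density_units)
  ))
  invisible(x)
}

#' Pointwise TCH curves from fitted interpolators
#'
#' The field-level fitted cane-biomass curve is multiplied by each
#' sampling unit's fitted cane spatial density curve and converted to
#' t/ha; intra-field yield differences are carried entirely by the
#' per-unit density curves.
#'
#' @param fits A `campaign_fits` object.
#' @param t_grid Days at which to evaluate (default daily over the fitted
#'   range).
#' @param spacing Mean row spacing, m.
#' @return Tibble with columns `field_id`, `unit_id`, `t`, `BM_C`,
#'   `C_row`, `TCH`.
#' @export
predict_tch <- function(fits, t_grid = NULL, spacing = 1.2) {
  stopifnot(inherits(fits, "campaign_fits"))
  t_grid <- t_grid %||% seq(0, max(fits$biomass_general$data$t))
  purrr::imap_dfr(fits$density_units, function(dfit, uid) {
    fid <- fits$unit_map$field_id[fits$unit_map$unit_id == uid][1]
    bfit <- fits$biomass_fields[[fid]]
    bm <- predict(bfit, t_grid)
    cr <- pmax(predict(dfit, t_grid), 0)
    tibble(field_id = fid, unit_id = uid, t = t_grid,
           BM_C = bm, C_row = cr, TCH = tch(bm, cr, spacing))
  })
}
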