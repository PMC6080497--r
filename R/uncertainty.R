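# Three-tier precision framework and delta-method error propagation.
#
# Tiers: instrument operation (same plant, same instrument), idealization
# (neighbouring plants within GPS accuracy; contains the instrument
# component), function fitting (RMSE of the fitted time trend). Propagation
# uses first-order relative terms (theta) plus second-order corrections
# (chi); the two are combined in quadrature by default, with the additive
# combination available as a config-pinned alternative (see the methods
# vignette for why quadrature is the default).

second_order_modes <- c("quadrature", "additive", "none")

combine_terms <- function(theta, chi, scale, second_order) {
  switch(second_order,
    quadrature = sqrt((theta * scale)^2 + (chi * scale)^2),
    additive = (theta + chi) * abs(scale),
    none = theta * abs(scale)
  )
}

#' Replicate-based precision (sample standard deviation)
#'
#' The dispersion of repeated measurements of the same parameter: the
#' sample standard deviation (n - 1 denominator) of a replicate set. No
#' small-sample bias correction is applied, so at the usual five
#' replicates the estimate is on average about 6% below the true sigma.
#'
#' @param values Replicate measurements (at least 2).
#' @param tier Bookkeeping label, `"instrument"` or `"idealization"`.
#' @return The sample standard deviation.
#' @examples
#' replicate_sd(c(1, 2, 3, 4, 5))
#' @export
replicate_sd <- function(values, tier = c("instrument", "idealization")) {
  tier <- match.arg(tier)
  values <- values[is.finite(values)]
  if (length(values) < 2) stop_input("need at least 2 replicate values")
  sd(values)
}

#' Stalk-density precision by inverse propagation of the biomass equation
#'
#' Stalk mass density is computed, not measured: mass over cylindrical
#' volume. Its precision follows from propagating the biomass equation,
#' `sigma_rho = rho * sqrt(rel_BMS^2 + (2 sigma_D / D)^2 + (sigma_H / H)^2)`,
#' where the relative stalk-biomass dispersion is approximated by the
#' cane-biomass one (only cane-mass variation is measured destructively).
#'
#' @param rho_S Stalk mass density, kg/m^3.
#' @param rel_sigma_BMS Relative stalk (cane) biomass dispersion.
#' @param sigma_D,D Diameter precision and value, m.
#' @param sigma_H,H Height precision and value, m.
#' @return Absolute stalk-density precision, kg/m^3.
#' @examples
#' sigma_rho_s(1000, 0.10, sigma_D = 0.05 * 0.03, D = 0.03,
#'             sigma_H = 0.05 * 3, H = 3)
#' @export
sigma_rho_s <- function(rho_S, rel_sigma_BMS, sigma_D, D, sigma_H, H) {
  check_pos(D, "D"); check_pos(H, "H")
  rho_S * sqrt(rel_sigma_BMS^2 + (2 * sigma_D / D)^2 + (sigma_H / H)^2)
}

#' Delta-method precision of cane biomass
#'
#' Propagates the measurement precisions of diameter, height, stalk
#' density and leaf biomass through the biomass equation. The first-order
#' relative term is
#' `theta = sqrt((2 sD/D)^2 + (sH/H)^2 + (srho/rho)^2)` and the
#' second-order correction collects the pairwise products
#' `chi = sqrt(((sD/D)^2)^2 + (2 (sD/D)(sH/H))^2 + (2 (sD/D)(srho/rho))^2 +
#' ((sH/H)(srho/rho))^2)`; the diameter enters squared in the equation,
#' hence its doubled weight. The stalk term is scaled by `|BM_S|` and
#' combined with the leaf precision.
#'
#' @param D,H,rho_S Stalk diameter (m), height (m) and mass density
#'   (kg/m^3) at which to evaluate.
#' @param BM_S Stalk biomass per cane, kg (computed from the inputs when
#'   `NULL`, with `taper`).
#' @param sigma_D,sigma_H,sigma_rho,sigma_BML Absolute precisions of the
#'   four inputs (SI units).
#' @param taper Taper factor used when computing `BM_S` internally.
#' @param second_order How to combine the second-order term with the
#'   first-order one: `"quadrature"` (default; consistent with a
#'   Monte-Carlo of independent Gaussian inputs), `"additive"` (the
#'   as-printed reading) or `"none"`.
#' @return Tibble with columns `theta`, `chi`, `sigma_BMC` (kg) and
#'   `rel_sigma_BMC` (relative to `BM_S + BM_L`-free scale, i.e.
#'   `sigma_BMC / BM_C` when `BM_L` is supplied via `BM_L`).
#' @param BM_L Leaf biomass per cane, kg (used for the relative output).
#' @examples
#' propagate_bmc(D = 0.03, H = 3, rho_S = 1100, BM_S = 2,
#'               sigma_D = 0.0015, sigma_H = 0.15, sigma_rho = 55,
#'               sigma_BML = 0.05)
#' @export
propagate_bmc <- function(D, H, rho_S, BM_S = NULL,
                          sigma_D = 0, sigma_H = 0, sigma_rho = 0,
                          sigma_BML = 0, BM_L = 0, taper = 0.977,
                          second_order = c("quadrature", "additive", "none")) {
  second_order <- match.arg(second_order)
  check_pos(D, "D"); check_pos(H, "H"); check_pos(rho_S, "rho_S")
  BM_S <- BM_S %||% cane_biomass(D, H, rho_S, taper)$BM_S
  rd <- sigma_D / D; rh <- sigma_H / H; rr <- sigma_rho / rho_S
  theta <- sqrt((2 * rd)^2 + rh^2 + rr^2)
  chi <- sqrt((rd^2)^2 + (2 * rd * rh)^2 + (2 * rd * rr)^2 + (rh * rr)^2)
  stalk <- combine_terms(theta, chi, BM_S, second_order)
  sigma_BMC <- sqrt(stalk^2 + sigma_BML^2)
  tibble(
    theta = theta, chi = chi, sigma_BMC = sigma_BMC,
    rel_sigma_BMC = sigma_BMC / (BM_S + BM_L)
  )
}

#' Delta-method precision of directly computed TCH
#'
#' Propagates measurement precisions through the product of the biomass
#' equation and the areal conversion, splitting TCH into its stalk
#' (tons stalk per hectare, TSH) and leaf (tons leaf per hectare, TLH)
#' components. Each component gets a first-order relative term and a
#' second-order correction over all pairwise products (diameter terms
#' carry factor 2); the two scaled components combine in root-sum-square.
#'
#' @inheritParams propagate_bmc
#' @param C Cane count per row-metre.
#' @param sigma_C Absolute precision of `C`.
#' @param BM_L Leaf biomass per cane, kg.
#' @param sigma_BML Absolute leaf-biomass precision, kg.
#' @param S Mean row spacing, m.
#' @return Tibble with the component magnitudes (`TSH`, `TLH`, t/ha),
#'   their first- and second-order terms, `sigma_TCH` (t/ha) and
#'   `rel_sigma_TCH` (relative to `TSH + TLH`).
#' @examples
#' propagate_tch(D = 0.03, H = 3, rho_S = 1100, BM_S = 2, C = 8,
#'               sigma_D = 0.0015, sigma_H = 0.15, sigma_rho = 55,
#'               sigma_C = 0.8, BM_L = 0.1, sigma_BML = 0.05)
#' @export
propagate_tch <- function(D, H, rho_S, BM_S = NULL, C, sigma_D = 0,
                          sigma_H = 0, sigma_rho = 0, sigma_C = 0,
                          BM_L = 0, sigma_BML = 0, S = 1.2, taper = 0.977,
                          second_order = c("quadrature", "additive", "none")) {
  second_order <- match.arg(second_order)
  check_pos(D, "D"); check_pos(H, "H"); check_pos(rho_S, "rho_S")
  check_pos(C, "C"); check_pos(S, "S")
  BM_S <- BM_S %||% cane_biomass(D, H, rho_S, taper)$BM_S
  TSH <- BM_S * C * 10 / S
  TLH <- BM_L * C * 10 / S
  rd <- sigma_D / D; rh <- sigma_H / H; rr <- sigma_rho / rho_S
  rc <- sigma_C / C
  rl <- ifelse(BM_L > 0, sigma_BML / BM_L, 0)
  theta_TSH <- sqrt((2 * rd)^2 + rh^2 + rr^2 + rc^2)
  theta_TLH <- sqrt(rl^2 + rc^2)
  chi_TSH <- sqrt((rd^2)^2 + (2 * rd * rh)^2 + (2 * rd * rr)^2 +
                    (2 * rd * rc)^2 + (rh * rr)^2 + (rh * rc)^2 + (rr * rc)^2)
  chi_TLH <- rl * rc
  stalk <- combine_terms(theta_TSH, chi_TSH, TSH, second_order)
  leaf <- combine_terms(theta_TLH, chi_TLH, TLH, second_order)
  sigma_TCH <- sqrt(stalk^2 + leaf^2)
  tibble(
    TSH = TSH, TLH = TLH,
    theta_TSH = theta_TSH, chi_TSH = chi_TSH,
    theta_TLH = theta_TLH, chi_TLH = chi_TLH,
    sigma_TCH = sigma_TCH,
    rel_sigma_TCH = sigma_TCH / (TSH + TLH)
  )
}

#' Total precision at location for cane biomass
#'
#' The tier mix defining the "total precision at location": idealization
#' precisions for the directly measured diameter and height, and function
#' fitting precisions (trend RMSEs) for the modelled stalk density and
#' leaf biomass. The idealization precisions of the modelled quantities
#' are excluded because the trends are fitted through measurements already
#' carrying them, so the two are not independent.
#'
#' @inheritParams propagate_bmc
#' @param sigma_D_ideal,sigma_H_ideal Idealization precisions of D and H.
#' @param sigma_rho_fit,sigma_BML_fit Fitting precisions (trend RMSEs) of
#'   stalk density and leaf biomass.
#' @return As [propagate_bmc()].
#' @export
total_precision_at_location <- function(D, H, rho_S, BM_S = NULL,
                                        sigma_D_ideal, sigma_H_ideal,
                                        sigma_rho_fit, sigma_BML_fit,
                                        BM_L = 0, taper = 0.977,
                                        second_order = c("quadrature", "additive", "none")) {
  propagate_bmc(D, H, rho_S, BM_S,
                sigma_D = sigma_D_ideal, sigma_H = sigma_H_ideal,
                sigma_rho = sigma_rho_fit, sigma_BML = sigma_BML_fit,
                BM_L = BM_L, taper = taper,
                second_order = match.arg(second_order))
}

intensive_sigmas <- function(intensive) {
  intensive |>
    dplyr::group_by(.data$parameter, .data$stage, .data$tier, .data$set) |>
    dplyr::summarise(s = sd(.data$value), .groups = "drop") |>
    dplyr::group_by(.data$parameter, .data$stage, .data$tier) |>
    dplyr::summarise(sigma = mean(.data$s), .groups = "drop")
}

corner_sigmas <- function(campaign) {
  campaign$biometrics |>
    dplyr::group_by(.data$unit_id, .data$t) |>
    dplyr::summarise(
      dplyr::across(dplyr::any_of(c("H", "D", "C_row")),
                    ~ if (sum(is.finite(.x)) >= 2) sd(.x, na.rm = TRUE) else NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(stage = growth_stage(.data$t)) |>
    tidyr::pivot_longer(dplyr::any_of(c("H", "D", "C_row")),
                        names_to = "parameter", values_to = "s") |>
    dplyr::group_by(.data$parameter, stage = as.character(.data$stage)) |>
    dplyr::summarise(sigma = mean(.data$s, na.rm = TRUE), .groups = "drop") |>
    dplyr::mutate(tier = "within_esu")
}

#' Build the campaign precision table
#'
#' Assembles the full three-tier precision summary of a campaign:
#' absolute sigmas per parameter, growth stage and tier (instrument and
#' idealization from the intensive replicate sets; fitting from the trend
#' RMSEs; within-ESU from the corner-point dispersion), plus derived
#' relative precisions (%) for cane biomass, cane spatial density and
#' directly propagated TCH at each stage, at the tiers instrument,
#' idealization, fitting, total-at-location (idealization D/H + fitting
#' rho/leaf) and total-within-ESU (corner dispersion D/H/C + fitting
#' rho/leaf). Stage-representative values come from the fitted
#' interpolators evaluated at the stage midpoints (days 75/225/350) and
#' from stage means of the biometrics.
#'
#' @param x A [campaign] object.
#' @param fits A `campaign_fits` object from [fit_growth_curves()].
#' @param intensive Intensive replicate tibble, as from
#'   [simulate_intensive()] (columns `parameter`, `stage`, `tier`, `set`,
#'   `rep`, `value`).
#' @param spacing Mean row spacing, m.
#' @param second_order Second-order combination rule, see
#'   [propagate_bmc()].
#' @return Object of class `precision_table`: list with tibbles `absolute`
#'   (`parameter`, `stage`, `tier`, `sigma`) and `relative` (`quantity`,
#'   `stage`, `tier`, `rel_pct`), plus the stage-representative values in
#'   `$stage_values`. A tier entry with no data is reported absent
#'   (`NA`), not zero. If a recovered instrument sigma exceeds its
#'   idealization counterpart a warning is raised (the tiers are nested,
#'   so this signals under-sampled replicates), never an error.
#' @export
build_precision_table <- function(x, fits, intensive, spacing = 1.2,
                                  second_order = c("quadrature", "additive", "none")) {
  second_order <- match.arg(second_order)
  stopifnot(inherits(x, "campaign"), inherits(fits, "campaign_fits"))

  abs_meas <- intensive_sigmas(intensive)
  fit_rows <- tibble(
    parameter = rep(c("rho_S", "BM_L"), each = 3),
    stage = rep(c("early", "mid", "late"), 2),
    tier = "fitting",
    sigma = rep(c(fits$trends$rho_S$rmse, fits$trends$BM_L$rmse), each = 3)
  )
  corner <- corner_sigmas(x)
  absolute <- dplyr::bind_rows(abs_meas, fit_rows, corner) |>
    dplyr::arrange(.data$parameter, .data$stage, .data$tier)

  nest_chk <- absolute |>
    tidyr::pivot_wider(names_from = "tier", values_from = "sigma") |>
    dplyr::filter(!is.na(.data$instrument) & !is.na(.data$idealization) &
                    .data$instrument > .data$idealization)
  if (nrow(nest_chk) > 0) {
    warn(sprintf(
      "instrument precision exceeds idealization for: %s",
      paste(sprintf("%s/%s", nest_chk$parameter, nest_chk$stage), collapse = ", ")
    ))
  }

  # stage-representative values
  mids <- stage_midpoints()
  um <- unit_means(x) |> dplyr::mutate(stage = as.character(growth_stage(.data$t)))
  stage_meas <- um |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(D = mean(.data$D, na.rm = TRUE),
                     H = mean(.data$H, na.rm = TRUE),
                     C = mean(.data$C_row, na.rm = TRUE), .groups = "drop")
  stage_values <- tibble(
    stage = names(mids), t = unname(mids),
    rho_S = predict(fits$trends$rho_S, unname(mids)),
    BM_L = pmax(predict(fits$trends$BM_L, unname(mids)), 1e-6)
  ) |>
    dplyr::left_join(stage_meas, by = "stage") |>
    dplyr::mutate(
      BM_S = cane_biomass(.data$D, .data$H, .data$rho_S)$BM_S,
      BM_C = .data$BM_S + .data$BM_L
    )

  sig_of <- function(param, stg, tr) {
    hit <- absolute$sigma[absolute$parameter == param &
                            absolute$stage == stg & absolute$tier == tr]
    if (length(hit) == 0 || is.na(hit[[1]])) NA_real_ else hit[[1]]
  }

  rel_rows <- purrr::map_dfr(stage_values$stage, function(stg) {
    sv <- stage_values[stage_values$stage == stg, ]
    mixes <- list(
      instrument = c(D = "instrument", H = "instrument",
                     rho_S = "instrument", BM_L = "instrument", C = "instrument"),
      idealization = c(D = "idealization", H = "idealization",
                       rho_S = "idealization", BM_L = "idealization",
                       C = "idealization"),
      fitting = c(D = NA, H = NA, rho_S = "fitting", BM_L = "fitting", C = NA),
      total_at_location = c(D = "idealization", H = "idealization",
                            rho_S = "fitting", BM_L = "fitting",
                            C = "idealization"),
      total_within_esu = c(D = "within_esu", H = "within_esu",
                           rho_S = "fitting", BM_L = "fitting",
                           C = "within_esu")
    )
    purrr::imap_dfr(mixes, function(mix, tier_name) {
      gs <- function(p, key) {
        if (is.na(mix[[key]])) 0 else {
          s <- sig_of(p, stg, mix[[key]])
          if (is.na(s)) 0 else s
        }
      }
      sD <- gs("D", "D"); sH <- gs("H", "H")
      sR <- gs("rho_S", "rho_S"); sL <- gs("BM_L", "BM_L")
      sC <- gs("C_row", "C")
      bmc <- propagate_bmc(sv$D, sv$H, sv$rho_S, sv$BM_S,
                           sigma_D = sD, sigma_H = sH, sigma_rho = sR,
                           sigma_BML = sL, BM_L = sv$BM_L,
                           second_order = second_order)
      tchp <- propagate_tch(sv$D, sv$H, sv$rho_S, sv$BM_S, C = sv$C,
                            sigma_D = sD, sigma_H = sH, sigma_rho = sR,
                            sigma_C = sC, BM_L = sv$BM_L, sigma_BML = sL,
                            S = spacing, second_order = second_order)
      dplyr::bind_rows(
        tibble(quantity = "BM_C", stage = stg, tier = tier_name,
               rel_pct = 100 * bmc$rel_sigma_BMC),
        tibble(quantity = "C", stage = stg, tier = tier_name,
               rel_pct = if (tier_name == "fitting") NA_real_ else 100 * sC / sv$C),
        tibble(quantity = "TCH", stage = stg, tier = tier_name,
               rel_pct = 100 * tchp$rel_sigma_TCH)
      )
    })
  })

  structure(
    list(absolute = absolute, relative = rel_rows, stage_values = stage_values,
         second_order = second_order),
    class = "precision_table"
  )
}

#' @export
print.precision_table <- function(x, ...) {
  cat("Campaign precision table\n\nAbsolute sigmas (SI units):\n")
  print(tidyr::pivot_wider(x$absolute, names_from = "stage",
                           values_from = "sigma"), n = Inf)
  cat("\nRelative precisions (% of stage value):\n")
  print(tidyr::pivot_wider(x$relative, names_from = "stage",
                           values_from = "rel_pct"), n = Inf)
  invisible(x)
}
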