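#' Allometric cane biomass from stalk biometrics
#'
#' Estimates per-cane stalk and total biomass from stalk diameter, height
#' and stalk mass density, treating the stalk as a tapered cylinder:
#' `BM_S = (pi * D^2 / 4) * H * rho_S * taper`, and total cane biomass as
#' stalk plus leaf, `BM_C = BM_S + BM_L`. All arguments are vectorized and
#' strictly SI: metres, kilograms, kg/m^3.
#'
#' @param D Stalk diameter at ground level, m.
#' @param H Stalk height (ground to crown), m.
#' @param rho_S Stalk mass density, kg/m^3.
#' @param taper Dimensionless taper scaling factor correcting the cylinder
#'   volume for the stalk's tapered shape. The shipped default 0.977 is the
#'   destructive-calibration value for the reference campaign; recalibrate
#'   with [calibrate_taper_factor()] for a new cultivar or region.
#' @param BM_L Leaf biomass per cane, kg.
#' @return A tibble with columns `BM_S` (stalk biomass per cane, kg) and
#'   `BM_C` (cane biomass per cane, kg).
#' @seealso [tch()], [calibrate_taper_factor()], [stalk_density_from_sample()]
#' @examples
#' cane_biomass(D = 0.030, H = 3.00, rho_S = 1100, BM_L = 0.100)
#' @export
cane_biomass <- function(D, H, rho_S, taper = 0.977, BM_L = 0) {
  check_nonneg(D, "D"); check_nonneg(H, "H")
  check_nonneg(rho_S, "rho_S"); check_nonneg(BM_L, "BM_L")
  check_pos(taper, "taper")
  BM_S <- (pi * D^2 / 4) * H * rho_S * taper
  tibble(BM_S = BM_S, BM_C = BM_S + BM_L)
}

#' Tons cane per hectare from per-cane biomass and row counts
#'
#' Converts per-cane biomass and a cane count per row-metre into the
#' standard sugarcane yield metric, tons cane per hectare:
#' `TCH = BM_C * C_row * 10 / S`. `C_row / S` is the areal cane density in
#' canes/m^2 and the factor 10 converts kg/m^2 to t/ha.
#'
#' @param BM_C Cane biomass per cane, kg.
#' @param C_row Cane count per row-metre, canes/m.
#' @param S Mean row spacing, m. Default 1.2 m, the midpoint of the 0.9 m
#'   and 1.5 m spacings of a dual-row planting pattern.
#' @return TCH, t/ha (numeric vector).
#' @examples
#' tch(2.379, C_row = 8)
#' @export
tch <- function(BM_C, C_row, S = 1.2) {
  check_nonneg(BM_C, "BM_C"); check_nonneg(C_row, "C_row")
  check_pos(S, "S")
  BM_C * C_row * 10 / S
}

#' Calibrate the taper scaling factor against destructive samples
#'
#' The taper factor compensates the cylindrical stalk volume for the
#' stalk's tapered shape. It is calibrated by comparing destructively
#' measured stalk biomass with the uncorrected cylinder estimate
#' `(pi D^2 / 4) H rho_S` for the same canes.
#'
#' @param measured_BM_S Measured stalk biomass per cane, kg.
#' @param estimated_BM_S Uncorrected (taper = 1) estimated stalk biomass, kg.
#' @param method `"mean_of_ratios"` (default) averages the per-sample
#'   measured/estimated ratios; `"pooled_ratio"` divides the totals. The two
#'   differ only at second order in the sample scatter.
#' @return The taper factor (scalar).
#' @examples
#' calibrate_taper_factor(c(2.00, 1.95), c(2.05, 2.00))
#' @export
calibrate_taper_factor <- function(measured_BM_S, estimated_BM_S,
                                   method = c("mean_of_ratios", "pooled_ratio")) {
  method <- match.arg(method)
  if (length(measured_BM_S) != length(estimated_BM_S)) {
    stop_input("measured and estimated stalk biomass must have equal length")
  }
  if (length(measured_BM_S) == 0) stop_input("no calibration samples")
  check_nonneg(measured_BM_S, "measured_BM_S")
  check_pos(estimated_BM_S, "estimated_BM_S")
  switch(method,
    mean_of_ratios = mean(measured_BM_S / estimated_BM_S),
    pooled_ratio = sum(measured_BM_S) / sum(estimated_BM_S)
  )
}

#' Stalk mass density from a destructive sample
#'
#' Stalk mass divided by the cylindrical stalk volume. No taper correction
#' is applied at this stage: the taper factor is calibrated afterwards from
#' the ratio of measured to cylinder-estimated stalk biomass, so including
#' it here would absorb the very quantity being calibrated.
#'
#' @param mass Stalk mass, kg.
#' @param D Stalk diameter, m.
#' @param H Stalk height, m.
#' @return Stalk mass density, kg/m^3.
#' @examples
#' stalk_density_from_sample(2.33264, D = 0.03, H = 3.0)
#' @export
stalk_density_from_sample <- function(mass, D, H) {
  check_nonneg(mass, "mass")
  check_pos(D, "D"); check_pos(H, "H")
  mass / (pi * D^2 / 4 * H)
}

#' Wet (moisture) content from oven-dried samples
#'
#' The complement of the dried-to-wet mass ratio, `1 - dry/wet`.
#'
#' @param dry_mass Mass after oven drying, kg.
#' @param wet_mass Fresh mass, kg.
#' @return Wet content as a fraction in `[0, 1]`.
#' @examples
#' wet_content(0.030, 0.100)
#' @export
wet_content <- function(dry_mass, wet_mass) {
  check_nonneg(dry_mass, "dry_mass")
  check_pos(wet_mass, "wet_mass")
  if (any(dry_mass > wet_mass)) stop_domain("dry mass exceeds wet mass")
  1 - dry_mass / wet_mass
}

#' Correct effective LAI to actual LAI by destructive calibration
#'
#' Optical canopy analyzers report an effective leaf area index that is
#' biased by leaf clumping. A constant offset, the mean difference between
#' instrument-measured and destructively observed LAI over the calibration
#' dates, is subtracted from every effective value. The correction can push
#' small values slightly below zero; those are retained and flagged, and
#' optionally clamped to zero for plotting/export.
#'
#' @param effective Effective LAI values, m^2/m^2.
#' @param calib_measured Instrument LAI at the calibration dates.
#' @param calib_observed Destructively observed LAI at the same dates.
#' @param clamp If `TRUE`, add a `clamped` column with negatives set to 0.
#' @return A tibble with columns `effective`, `actual`, `negative` (flag),
#'   and `clamped` when requested; the offset is stored in the `"offset"`
#'   attribute.
#' @examples
#' correct_lai(2.5, calib_measured = c(2.0, 3.0), calib_observed = c(1.8, 2.6))
#' @export
correct_lai <- function(effective, calib_measured, calib_observed, clamp = FALSE) {
  if (length(calib_measured) == 0 || length(calib_measured) != length(calib_observed)) {
    rlang::abort("need at least one (measured, observed) calibration pair",
                 class = "canemass_config_error")
  }
  offset <- mean(calib_measured - calib_observed)
  actual <- effective - offset
  out <- tibble(
    effective = effective,
    actual = actual,
    negative = actual < 0
  )
  if (clamp) out$clamped <- pmax(actual, 0)
  attr(out, "offset") <- offset
  out
}
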