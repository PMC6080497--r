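# Perturbation-based uncertainty bands: perturb the observations feeding a
# constrained logistic re-fit, re-fit many times, and read the band off the
# ensemble of curves.

#' Perturb observations and re-fit the constrained logistic
#'
#' Each ensemble replicate adds independent Gaussian noise (the
#' total-at-location precision of every observation) to the unit-mean
#' values and re-runs the constrained re-fit inside the general fit's
#' widened confidence box. The pointwise standard deviation of the
#' ensemble of fitted curves is the uncertainty band. Replicates that fail
#' to converge are dropped and logged; the ensemble errors out if more
#' than `max_fail` of the replicates fail.
#'
#' @param t,y Observation days and values (typically unit-visit means).
#' @param sigma Perturbation standard deviation: scalar or one value per
#'   observation (absolute, same units as `y`).
#' @param general The pooled `logistic_fit` supplying starting values and
#'   bounds.
#' @param n Ensemble size (default 100).
#' @param seed Seed for the perturbation stream.
#' @param t_grid Evaluation grid for the band (default daily across the
#'   observation range).
#' @param expansion Bound-widening fraction passed to
#'   [refit_constrained()].
#' @param max_fail Maximum tolerated fraction of failed re-fits.
#' @return Object of class `perturbation_ensemble`: tibble of re-fitted
#'   coefficients (`$params`), the ensemble curve matrix (`$curves`,
#'   replicates x grid), the unperturbed baseline re-fit (`$base_fit`) and
#'   the band `$band` (tibble `t`, `mean`, `sd`).
#' @export
perturb_and_refit <- function(t, y, sigma, general, n = 100, seed = NULL,
                              t_grid = NULL, expansion = 0.10,
                              max_fail = 0.2) {
  if (n < 2) stop_input("ensemble size must be at least 2")
  if (any(sigma < 0)) stop_domain("`sigma` must be non-negative")
  sigma <- rep(sigma, length.out = length(y))
  t_grid <- t_grid %||% seq(floor(min(t)), ceiling(max(t)))
  if (!is.null(seed)) set.seed(seed)

  base_fit <- refit_constrained(general, t, y, expansion = expansion)
  fits <- vector("list", n)
  failed <- 0L
  for (i in seq_len(n)) {
    yi <- y + rnorm(length(y), 0, sigma)
    fits[[i]] <- tryCatch(
      refit_constrained(general, t, yi, expansion = expansion),
      error = function(e) NULL
    )
    if (is.null(fits[[i]])) failed <- failed + 1L
  }
  if (failed > max_fail * n) {
    rlang::abort(
      sprintf("perturbation ensemble: %d of %d re-fits failed", failed, n),
      class = "canemass_ensemble_error"
    )
  }
  if (failed > 0) cane_log("perturb_and_refit: dropped %d failed re-fit(s)", failed)
  fits <- purrr::compact(fits)

  params <- purrr::imap_dfr(fits, function(f, i) {
    tibble(replicate = i, delta_y = f$coefficients["delta_y"],
           k = f$coefficients["k"], t0 = f$coefficients["t0"])
  })
  curves <- do.call(rbind, purrr::map(fits, predict, t = t_grid))
  band <- tibble(
    t = t_grid,
    mean = colMeans(curves),
    sd = apply(curves, 2, sd)
  )
  structure(
    list(params = params, curves = curves, t_grid = t_grid,
         base_fit = base_fit, band = band, n_failed = failed),
    class = "perturbation_ensemble"
  )
}

#' @export
print.perturbation_ensemble <- function(x, ...) {
  cat(sprintf(
    "Perturbation ensemble: %d re-fits on %d-point grid (%d failed); mean band sd = %.3g\n",
    nrow(x$params), length(x$t_grid), x$n_failed, mean(x$band$sd)
  ))
  invisible(x)
}

#' TCH profile with a perturbation-ensemble uncertainty band
#'
#' Combines a field-level perturbed cane-biomass ensemble with a
#' unit-level perturbed cane-density ensemble. The mean profile is the
#' product of the two unperturbed baseline curves converted to t/ha; the
#' band is the pointwise standard deviation over all pairwise products of
#' perturbed curves (ensemble sizes multiply: 100 x 100 gives ten
#' thousand combinations), the two ensembles being treated as
#' independent.
#'
#' @param biomass_ens `perturbation_ensemble` of the field's cane-biomass
#'   curve (kg per cane).
#' @param density_ens `perturbation_ensemble` of the unit's cane spatial
#'   density curve (canes per row-metre).
#' @param S Mean row spacing, m.
#' @param unit_id Optional label stored on the profile.
#' @return Object of class `tch_profile`: tibble with columns `t`, `mean`,
#'   `sd` (t/ha) plus the stage classification, carrying the ensemble
#'   sizes as attributes.
#' @export
tch_profile <- function(biomass_ens, density_ens, S = 1.2, unit_id = NULL) {
  stopifnot(inherits(biomass_ens, "perturbation_ensemble"),
            inherits(density_ens, "perturbation_ensemble"))
  if (!identical(biomass_ens$t_grid, density_ens$t_grid)) {
    stop_input("biomass and density ensembles must share a time grid")
  }
  check_pos(S, "S")
  t_grid <- biomass_ens$t_grid
  mean_profile <- tch(
    pmax(predict(biomass_ens$base_fit, t_grid), 0),
    pmax(predict(density_ens$base_fit, t_grid), 0),
    S
  )
  bm <- biomass_ens$curves
  dn <- density_ens$curves
  sd_profile <- vapply(seq_along(t_grid), function(j) {
    prods <- tcrossprod(bm[, j], dn[, j]) * 10 / S
    sd(prods)
  }, numeric(1))
  out <- tibble(
    t = t_grid,
    stage = growth_stage(pmax(t_grid, 0)),
    mean = mean_profile,
    sd = sd_profile
  )
  structure(out,
            class = c("tch_profile", class(out)),
            unit_id = unit_id,
            n_biomass = nrow(bm), n_density = nrow(dn))
}

#' Per-stage relative precision of a TCH profile
#'
#' Averages `sd / mean` over the days of each growth stage, expressed in
#' percent. Days where the mean profile is below `min_mean` (t/ha) are
#' excluded: very young cane has near-zero yield and an unstable ratio.
#'
#' @param profile A `tch_profile` (or any tibble with `t`, `mean`, `sd`).
#' @param min_mean Exclusion threshold for the mean profile, t/ha.
#' @return Tibble with columns `stage` and `rel_sd_pct`.
#' @export
profile_stage_precision <- function(profile, min_mean = 1) {
  profile |>
    as_tibble() |>
    dplyr::filter(.data$mean > min_mean) |>
    dplyr::mutate(stage = growth_stage(.data$t)) |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(rel_sd_pct = 100 * mean(.data$sd / .data$mean),
                     .groups = "drop")
}

#' Perturbation-band TCH uncertainty for a whole campaign
#'
#' Runs the full perturbation scheme: for every field, perturb the pooled
#' cane-biomass values at their total-at-location precision and re-fit
#' `n_biomass` times; for every sampling unit, perturb its density
#' observations and re-fit `n_density` times; then form each unit's TCH
#' profile and band from the product ensemble.
#'
#' @param x A [campaign] object.
#' @param fits `campaign_fits` from [fit_growth_curves()].
#' @param ptable `precision_table` from [build_precision_table()]
#'   (supplies the total-at-location relative precisions per stage).
#' @param n_biomass,n_density Ensemble sizes (default 100 each).
#' @param seed Master seed; per-field and per-unit streams are derived
#'   from it.
#' @param t_grid Evaluation grid (default daily to the last visit).
#' @param spacing Row spacing, m.
#' @return Named list of `tch_profile` objects, one per sampling unit,
#'   with the per-field biomass ensembles attached as
#'   `attr(, "biomass_ensembles")`.
#' @export
campaign_tch_uncertainty <- function(x, fits, ptable, n_biomass = 100,
                                     n_density = 100, seed = 1L,
                                     t_grid = NULL, spacing = 1.2) {
  stopifnot(inherits(fits, "campaign_fits"), inherits(ptable, "precision_table"))
  est <- estimate_biomass(x, fits$trends, spacing = spacing)
  um <- unit_means(x)
  t_grid <- t_grid %||% seq(0, max(um$t))

  rel_at_loc <- function(quantity) {
    v <- ptable$relative |>
      dplyr::filter(.data$quantity == !!quantity,
                    .data$tier == "total_at_location")
    setNames(v$rel_pct / 100, v$stage)
  }
  rel_bmc <- rel_at_loc("BM_C")
  rel_c <- rel_at_loc("C")

  bm_ens <- purrr::imap(fits$biomass_fields, function(f, fid) {
    d <- dplyr::filter(est, .data$field_id == fid)
    sig <- abs(d$BM_C) * rel_bmc[as.character(growth_stage(d$t))]
    perturb_and_refit(d$t, d$BM_C, sig, fits$biomass_general,
                      n = n_biomass, seed = substream_seed(seed, paste0("bm-", fid)),
                      t_grid = t_grid)
  })
  profiles <- purrr::imap(fits$density_units, function(f, uid) {
    fid <- fits$unit_map$field_id[fits$unit_map$unit_id == uid][1]
    d <- dplyr::filter(um, .data$unit_id == uid, !is.na(.data$C_row))
    sig <- abs(d$C_row) * rel_c[as.character(growth_stage(d$t))]
    dens <- perturb_and_refit(d$t, d$C_row, sig, fits$density_general,
                              n = n_density,
                              seed = substream_seed(seed, paste0("c-", uid)),
                              t_grid = t_grid)
    tch_profile(bm_ens[[fid]], dens, S = spacing, unit_id = uid)
  })
  attr(profiles, "biomass_ensembles") <- bm_ens
  profiles
}
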