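# shared fixtures: all synthetic, built in code at test time

options(canemass.verbosity = 0)

# homogeneous truth: every field shares one biomass curve and every unit one
# density curve, so the general fit -> constrained re-fit hierarchy is
# self-consistent and zero-noise recovery is exact
homogeneous_config <- function(noise_tier = "none", seed = 7) {
  bio <- tibble::tibble(
    field_id = sprintf("F%d", 1:4),
    delta_y = 2.5, k = 0.028, t0 = 150
  )
  cfg <- truth_config(noise_tier = noise_tier, seed = seed, biomass = bio)
  cfg$density$delta_y <- 20
  cfg$density$k <- -0.004
  cfg$density$t0 <- 300
  # "no noise" means every configured sigma is zero, intensive sets included
  if (identical(noise_tier, "none")) cfg$precisions$sigma <- 0
  cfg
}

# minimal hand-built campaign for IO and validation tests
tiny_campaign <- function() {
  campaign(
    biometrics = tibble::tibble(
      field_id = c("F1", "F1", "F2"),
      unit_id = c("F1-ESU1", "F1-ESU1", "F2-ESU1"),
      unit_kind = "ESU",
      t = c(30, 100, 30),
      corner = 1,
      H = c(0.5, 1.4, 0.6),
      D = c(0.012, 0.022, 0.013),
      C_row = c(16, 14, 15),
      P_row = c(4, 4, 4),
      LAI_eff = c(0.8, 2.5, 0.9)
    ),
    biomass = tibble::tibble(
      field_id = "F1", unit_id = "F1-ESU1", t = 100,
      plant_mass = 6, canes_per_plant = 12, cane_mass = 0.5,
      BM_L = 0.12, rho_S = 600,
      wet_content_stalk = 0.8, wet_content_leaf = 0.75,
      BM_S_measured = 0.38
    ),
    fields = tibble::tibble(
      field_id = c("F1", "F2"), ratoon_cycle = 1, area_ha = c(58, 115),
      start_of_growth = "2014-10-30", harvest = "2015-10-07"
    )
  )
}

# logistic_fit-shaped object with known coefficients and confidence box,
# used to pin parameters and build closed-form oracles
fake_logistic_fit <- function(coefs, half_widths, data = NULL) {
  ci <- cbind(lower = coefs - half_widths, upper = coefs + half_widths)
  rownames(ci) <- names(coefs)
  structure(
    list(coefficients = coefs, ci95 = ci,
         se = half_widths / stats::qt(0.975, 10),
         rmse = 0, n_obs = if (is.null(data)) 0L else nrow(data),
         converged = TRUE, force_origin = FALSE, origin_weight = 1,
         data = data %||% tibble::tibble(t = numeric(), y = numeric())),
    class = "logistic_fit"
  )
}

# minimal degenerate perturbation ensemble around a known curve
ens_stub <- function(density = FALSE, n = 5, t_grid = seq(0, 330, by = 30)) {
  fit <- if (density) {
    fake_logistic_fit(c(delta_y = 20, k = -0.004, t0 = 300), c(2, 0.002, 30))
  } else {
    fake_logistic_fit(c(delta_y = 2.5, k = 0.028, t0 = 150), c(0.5, 0.005, 20))
  }
  curve <- predict(fit, t_grid)
  structure(list(params = tibble::tibble(), t_grid = t_grid,
                 curves = matrix(rep(curve, each = n), nrow = n),
                 base_fit = fit, band = NULL, n_failed = 0L),
            class = "perturbation_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(n^2) loop-based variogram oracle, independent of the implementation:
# enumerates unordered pairs column-major, bins each squared difference by
# linear scan, and averages each bin's collected values
variogram_oracle <- function(positions, values, bin_edges) {
  n_bins <- length(bin_edges) - 1
  bin_vals <- vector("list", n_bins)
  dropped <- 0L
  n <- length(positions)
  for (j in 2:n) {
    for (i in seq_len(j - 1)) {
      h <- abs(positions[j] - positions[i])
      d2 <- (values[j] - values[i])^2
      hit <- FALSE
      for (b in seq_len(n_bins)) {
        if (h >= bin_edges[b] && h < bin_edges[b + 1]) {
          bin_vals[[b]] <- c(bin_vals[[b]], d2)
          hit <- TRUE
          break
        }
      }
      if (!hit) dropped <- dropped + 1L
    }
  }
  list(
    two_gamma = vapply(bin_vals, function(v) {
      if (length(v) > 0) mean(v) else NA_real_
    }, numeric(1)),
    n_pairs = vapply(bin_vals, length, integer(1)),
    dropped = dropped
  )
}
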