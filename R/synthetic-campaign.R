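# Synthetic-campaign generator: known ground-truth growth curves plus the
# three-tier Gaussian noise structure, so every downstream stage of the
# pipeline can be validated against configured truth.

#' Default three-tier precision table
#'
#' Absolute one-standard-deviation precisions per parameter, growth stage
#' and tier, in SI units. The instrument-operation and idealization tiers
#' reproduce the reference campaign's intensive-replicate values (stalk
#' diameter and height in m, cane count per row-metre, LAI, stalk density
#' in kg/m^3, leaf biomass per cane in kg); the fitting tier is the overall
#' RMSE of the corresponding trend fit and is constant over stages
#' (stalk density 65 kg/m^3, leaf biomass 0.058 kg). Cane-mass sigmas are
#' derived from the leaf-biomass idealization sigmas divided by the
#' stage leaf fractions (0.5, 0.15, 0.07), the same construction used to
#' obtain the leaf values from cane-mass dispersion in the field.
#'
#' @return Tibble with columns `parameter`, `tier`, `stage`, `sigma`.
#' @export
default_precisions <- function() {
  grid <- function(parameter, tier, sigma) {
    tibble(parameter = parameter, tier = tier,
           stage = c("early", "mid", "late"), sigma = sigma)
  }
  dplyr::bind_rows(
    grid("D", "instrument", c(0.002, 0.002, 0.003)),
    grid("D", "idealization", c(0.002, 0.003, 0.004)),
    grid("H", "instrument", c(0.008, 0.102, 0.118)),
    grid("H", "idealization", c(0.056, 0.329, 0.259)),
    grid("C_row", "instrument", c(0.8, 0.7, 0.5)),
    grid("C_row", "idealization", c(6.3, 4.0, 2.1)),
    grid("LAI", "instrument", c(0.2, 0.2, 0.3)),
    grid("LAI", "idealization", c(0.2, 0.4, 0.4)),
    grid("rho_S", "instrument", c(73, 60, 84)),
    grid("rho_S", "idealization", c(84, 121, 143)),
    grid("rho_S", "fitting", c(65, 65, 65)),
    grid("BM_L", "instrument", c(0.0061, 0.0061, 0.0061)),
    grid("BM_L", "idealization", c(0.0146, 0.0312, 0.0153)),
    grid("BM_L", "fitting", c(0.058, 0.058, 0.058)),
    grid("cane_mass", "instrument", c(0.0061, 0.0061, 0.0061)),
    grid("cane_mass", "idealization", c(0.029, 0.208, 0.219))
  )
}

sigma_lookup <- function(precisions, parameter, tier, stage) {
  hit <- precisions$sigma[precisions$parameter == parameter &
                            precisions$tier == tier &
                            precisions$stage == as.character(stage)]
  if (length(hit) == 0) 0 else hit[[1]]
}

#' Ground-truth configuration for a synthetic campaign
#'
#' Defines the noise-free truth a synthetic campaign is drawn around:
#' per-field logistic cane-biomass curves, per-sampling-unit logistic cane
#' spatial density curves (declining over the season, `k < 0`), a linear
#' stalk-density trend, through-origin second-order polynomials for leaf
#' biomass per cane and LAI, linear wet-content declines, the taper factor
#' and row spacing, the visit schedule, and the three-tier noise table.
#' The default shape mimics the reference campaign: 4 fields with 3-5
#' sampling units each, one to two of them destructive (ESUB), four corner
#' replicates per visit, and idealization-tier measurement noise.
#'
#' @param n_fields Number of fields (default 4).
#' @param esus_per_field Sampling units per field (recycled; default
#'   `c(4, 5, 3, 4)`).
#' @param schedule Visit days since start of growth.
#' @param replicates Corner replicates per visit (default 4).
#' @param precisions Precision table as from [default_precisions()].
#' @param noise_tier Tier used for routine-visit measurement noise
#'   (`"idealization"` by default; the dispersion seen when revisiting a
#'   GPS-located point), or `"none"` for a noise-free campaign.
#' @param seed Master seed; per-unit substreams are derived
#'   deterministically from it so adding a unit does not perturb others.
#' @param ... Override any default truth component by name: `biomass`
#'   (tibble `field_id`, `delta_y`, `k`, `t0`), `density` (tibble
#'   `unit_id`, `field_id`, `unit_kind`, `delta_y`, `k`, `t0`), `rho`
#'   (`intercept`, `slope`), `leaf`/`lai` (`c1`, `c2`), `wet_stalk` /
#'   `wet_leaf` (`intercept`, `slope`), `taper`, `row_spacing`, `d_to_h`,
#'   `canes_per_plant`.
#' @return An object of class `truth_config`.
#' @export
truth_config <- function(n_fields = 4,
                         esus_per_field = c(4, 5, 3, 4),
                         schedule = c(30, 60, 100, 140, 180, 230, 280, 330),
                         replicates = 4,
                         precisions = default_precisions(),
                         noise_tier = "idealization",
                         seed = 1L,
                         ...) {
  overrides <- list(...)
  esus <- rep_len(esus_per_field, n_fields)
  field_id <- sprintf("F%d", seq_len(n_fields))
  biomass <- tibble(
    field_id = field_id,
    delta_y = rep_len(c(2.2, 2.9, 2.5, 1.9), n_fields),
    k = rep_len(c(0.025, 0.030, 0.028, 0.022), n_fields),
    t0 = rep_len(c(150, 160, 145, 170), n_fields)
  )
  units <- purrr::map2_dfr(field_id, esus, function(fid, n) {
    tibble(
      field_id = fid,
      unit_id = sprintf("%s-ESU%d", fid, seq_len(n)),
      # first unit of each field is destructive; F2 gets a second ESUB
      unit_kind = ifelse(seq_len(n) == 1 | (fid == "F2" & seq_len(n) == 2),
                         "ESUB", "ESU")
    )
  })
  # per-unit density asymptotes spread deterministically around 18 canes/m
  # (counts of 60-100 canes per 5 m row give 12-20 canes/row-m); keyed on
  # the unit id so adding a unit never changes another's truth
  spread <- (vapply(units$unit_id, hash31, numeric(1)) %% 11 - 5) / 5
  density <- dplyr::mutate(
    units,
    delta_y = 18 + 2.5 * unname(spread),
    k = -0.004,
    t0 = 300
  )
  cfg <- list(
    biomass = biomass,
    density = density,
    rho = c(intercept = 450, slope = 1.5),
    leaf = c(c1 = 0.0016, c2 = -3.2e-6),
    lai = c(c1 = 0.022, c2 = -3.5e-5),
    wet_stalk = c(intercept = 0.88, slope = -6e-4),
    wet_leaf = c(intercept = 0.80, slope = -5e-4),
    taper = 0.977,
    row_spacing = 1.2,
    d_to_h = 0.01,
    canes_per_plant = 12,
    schedule = schedule,
    replicates = replicates,
    precisions = precisions,
    noise_tier = noise_tier,
    seed = as.integer(seed)
  )
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  stopifnot(all(cfg$biomass$delta_y > 0))
  rho_on_schedule <- cfg$rho["intercept"] + cfg$rho["slope"] * cfg$schedule
  stopifnot(all(rho_on_schedule > 0), cfg$taper > 0, cfg$taper <= 1.05)
  structure(cfg, class = "truth_config")
}

#' @export
print.truth_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic campaign truth: %d fields, %d units (%d ESUB), %d visits, noise tier '%s', seed %d\n",
    nrow(x$biomass), nrow(x$density), sum(x$density$unit_kind == "ESUB"),
    length(x$schedule), x$noise_tier, x$seed
  ))
  invisible(x)
}

truth_rho <- function(config, t) {
  unname(config$rho["intercept"] + config$rho["slope"] * t)
}
truth_leaf <- function(config, t) {
  unname(config$leaf["c1"] * t + config$leaf["c2"] * t^2)
}
truth_lai <- function(config, t) {
  unname(config$lai["c1"] * t + config$lai["c2"] * t^2)
}

#' Evaluate the configured noise-free trajectories
#'
#' Exact evaluations of the configured truth on a time grid: per-field
#' cane biomass, per-unit cane spatial density, the stalk-density, leaf
#' and LAI trends, and the resulting TCH
#' (`BM_C * C * 10 / row_spacing` pointwise).
#'
#' @param config A [truth_config()].
#' @param t_grid Days since start of growth; must lie within
#'   `[0, max(schedule)]`.
#' @return A list of tibbles (`biomass`, `density`, `trends`, `tch`) of
#'   class `truth_curves`.
#' @export
true_curves <- function(config, t_grid) {
  stopifnot(inherits(config, "truth_config"))
  if (any(t_grid < 0) || any(t_grid > max(config$schedule))) {
    stop_domain("t_grid must lie within [0, %g]", max(config$schedule))
  }
  biomass <- tidyr::crossing(config$biomass, t = t_grid) |>
    dplyr::mutate(BM_C = growth_logistic(.data$t, .data$delta_y, .data$k, .data$t0)) |>
    dplyr::select("field_id", "t", "BM_C")
  density <- tidyr::crossing(config$density, t = t_grid) |>
    dplyr::mutate(C_row = growth_logistic(.data$t, .data$delta_y, .data$k, .data$t0)) |>
    dplyr::select("field_id", "unit_id", "unit_kind", "t", "C_row")
  trends <- tibble(
    t = t_grid,
    rho_S = truth_rho(config, t_grid),
    BM_L = truth_leaf(config, t_grid),
    LAI = truth_lai(config, t_grid)
  )
  tch_tbl <- density |>
    dplyr::left_join(biomass, by = c("field_id", "t")) |>
    dplyr::mutate(TCH = tch(.data$BM_C, .data$C_row, config$row_spacing)) |>
    dplyr::select("field_id", "unit_id", "t", "TCH")
  structure(
    list(biomass = biomass, density = density, trends = trends, tch = tch_tbl),
    class = "truth_curves"
  )
}

# truncated-at-zero Gaussian by redraw; returns draws plus redraw count
rtrunc0 <- function(n, mean, sd) {
  mean <- rep(mean, length.out = n)
  sd <- rep(sd, length.out = n)
  if (all(sd == 0)) return(list(x = mean, redraws = 0L))
  x <- rnorm(n, mean, sd)
  redraws <- 0L
  for (i in 1:100) {
    bad <- x < 0
    if (!any(bad)) break
    redraws <- redraws + sum(bad)
    x[bad] <- rnorm(sum(bad), mean[bad], sd[bad])
  }
  x[x < 0] <- 0
  list(x = x, redraws = redraws)
}

# invert the biomass equation: given truth BM_S, stalk density, taper and a
# diameter-to-height ratio, recover the (H, D) pair that reproduces BM_S
invert_allometry <- function(BM_S, rho_S, taper, d_to_h) {
  H <- (4 * BM_S / (pi * d_to_h^2 * rho_S * taper))^(1 / 3)
  list(H = H, D = d_to_h * H)
}

#' Simulate a field campaign from configured truth
#'
#' Draws a full campaign table around the configured noise-free truth: for
#' every sampling unit, visit and corner replicate, stalk height and
#' diameter (derived from the truth biomass curve by inverting the biomass
#' equation given the stalk-density trend, leaf trend, taper factor and a
#' configured diameter/height allometry ratio), cane and plant counts, and
#' effective LAI; and for destructive (ESUB) units, plant/cane masses,
#' leaf biomass, stalk density and wet contents. All noise is additive
#' Gaussian at the configured tier's stage sigma, truncated at physical
#' zero by redraw (redraw count in `attr(, "redraws")`). The same seed
#' reproduces the identical table; per-unit substreams keep units
#' independent.
#'
#' @param config A [truth_config()].
#' @return A [campaign] object; the generating config is attached as
#'   `attr(, "truth")`.
#' @export
simulate_campaign <- function(config) {
  stopifnot(inherits(config, "truth_config"))
  tier <- config$noise_tier
  prec <- if (identical(tier, "none")) {
    dplyr::mutate(default_precisions(), sigma = 0)
  } else {
    dplyr::filter(config$precisions, .data$tier == !!tier)
  }
  sig <- function(param, stage) {
    hit <- prec$sigma[prec$parameter == param & prec$stage == as.character(stage)]
    if (length(hit) == 0) 0 else hit[[1]]
  }

  redraws <- 0L
  bio_rows <- list()
  bm_rows <- list()
  for (i in seq_len(nrow(config$density))) {
    u <- config$density[i, ]
    fld <- config$biomass[config$biomass$field_id == u$field_id, ]
    seed_u <- substream_seed(config$seed, u$unit_id)
    set.seed(seed_u)
    for (t in config$schedule) {
      stg <- growth_stage(t)
      BM_C_true <- growth_logistic(t, fld$delta_y, fld$k, fld$t0)
      BM_L_true <- max(truth_leaf(config, t), 0)
      BM_S_true <- max(BM_C_true - BM_L_true, 1e-6)
      rho_true <- truth_rho(config, t)
      hd <- invert_allometry(BM_S_true, rho_true, config$taper, config$d_to_h)
      C_true <- growth_logistic(t, u$delta_y, u$k, u$t0)
      lai_true <- max(truth_lai(config, t), 0)

      n <- config$replicates
      H <- rtrunc0(n, hd$H, sig("H", stg)); redraws <- redraws + H$redraws
      D <- rtrunc0(n, hd$D, sig("D", stg)); redraws <- redraws + D$redraws
      C <- rtrunc0(n, C_true, sig("C_row", stg)); redraws <- redraws + C$redraws
      LAI <- rtrunc0(n, lai_true, sig("LAI", stg)); redraws <- redraws + LAI$redraws
      P <- pmin(C$x / config$canes_per_plant * 4, C$x)  # plants per row-m
      bio_rows[[length(bio_rows) + 1]] <- tibble(
        field_id = u$field_id, unit_id = u$unit_id, unit_kind = u$unit_kind,
        t = t, corner = seq_len(n),
        H = H$x, D = D$x, leaf_len = NA_real_,
        C_row = C$x, P_row = P, LAI_eff = LAI$x,
        x = NA_real_, y = NA_real_
      )
      if (u$unit_kind == "ESUB") {
        cm <- rtrunc0(1, BM_C_true, sig("cane_mass", stg)); redraws <- redraws + cm$redraws
        bl <- rtrunc0(1, BM_L_true, sig("BM_L", stg)); redraws <- redraws + bl$redraws
        rs <- rtrunc0(1, rho_true, sig("rho_S", stg)); redraws <- redraws + rs$redraws
        ws <- min(max(config$wet_stalk["intercept"] + config$wet_stalk["slope"] * t, 0), 1)
        wl <- min(max(config$wet_leaf["intercept"] + config$wet_leaf["slope"] * t, 0), 1)
        bm_rows[[length(bm_rows) + 1]] <- tibble(
          field_id = u$field_id, unit_id = u$unit_id, t = t,
          plant_mass = cm$x * config$canes_per_plant,
          canes_per_plant = config$canes_per_plant,
          cane_mass = cm$x,
          BM_L = bl$x,
          rho_S = rs$x,
          wet_content_stalk = unname(ws),
          wet_content_leaf = unname(wl),
          BM_S_measured = max(cm$x - bl$x, 0)
        )
      }
    }
  }
  fields <- tibble(
    field_id = config$biomass$field_id,
    ratoon_cycle = rep_len(c(1, 1, 2, 9), nrow(config$biomass)),
    area_ha = rep_len(c(58, 115, 25, 59), nrow(config$biomass)),
    start_of_growth = NA_character_, harvest = NA_character_
  )
  out <- campaign(dplyr::bind_rows(bio_rows), dplyr::bind_rows(bm_rows), fields)
  attr(out, "truth") <- config
  attr(out, "redraws") <- redraws
  if (redraws > 0) cane_log("simulate_campaign: %d truncation redraw(s)", redraws, level = 2)
  out
}

#' Simulate intensive replicate measurements
#'
#' Emulates the intensive precision campaigns: at one representative day
#' per growth stage, each parameter is measured `reps` times consecutively,
#' once at the instrument-operation tier (same plant, same instrument) and
#' once at the idealization tier (neighbouring plants within GPS accuracy).
#' The idealization draw nests the instrument noise: replicate = truth +
#' local-variability noise + instrument noise, with local variance
#' `ideal^2 - instr^2`, so recovered instrument precisions sit below
#' idealization ones on average.
#'
#' @param config A [truth_config()].
#' @param n_sets Replicate sets per parameter/stage/tier.
#' @param reps Measurements per set (default 5).
#' @param stage_days Representative day per stage; default
#'   [stage_midpoints()].
#' @return Tibble with columns `parameter`, `stage`, `tier`, `set`, `rep`,
#'   `value`.
#' @export
simulate_intensive <- function(config, n_sets = 3, reps = 5,
                               stage_days = stage_midpoints()) {
  stopifnot(inherits(config, "truth_config"))
  prec <- config$precisions
  fld <- config$biomass[1, ]
  set.seed(substream_seed(config$seed, "intensive"))
  params <- c("D", "H", "C_row", "LAI", "rho_S", "BM_L", "cane_mass")
  rows <- list()
  for (stg in names(stage_days)) {
    t <- stage_days[[stg]]
    BM_C_true <- growth_logistic(t, fld$delta_y, fld$k, fld$t0)
    BM_L_true <- max(truth_leaf(config, t), 0)
    rho_true <- truth_rho(config, t)
    hd <- invert_allometry(max(BM_C_true - BM_L_true, 1e-6), rho_true,
                           config$taper, config$d_to_h)
    truth <- c(
      D = hd$D, H = hd$H,
      C_row = mean(growth_logistic(t, config$density$delta_y,
                                   config$density$k, config$density$t0)),
      LAI = max(truth_lai(config, t), 0),
      rho_S = rho_true, BM_L = BM_L_true, cane_mass = BM_C_true
    )
    for (p in params) {
      s_in <- sigma_lookup(prec, p, "instrument", stg)
      s_id <- max(sigma_lookup(prec, p, "idealization", stg), s_in)
      s_local <- sqrt(max(s_id^2 - s_in^2, 0))
      for (set_i in seq_len(n_sets)) {
        inst <- rtrunc0(reps, truth[[p]], s_in)$x
        ideal <- rtrunc0(reps, truth[[p]] + rnorm(reps, 0, s_local), s_in)$x
        rows[[length(rows) + 1]] <- tibble(
          parameter = p, stage = stg,
          tier = rep(c("instrument", "idealization"), each = reps),
          set = set_i, rep = rep(seq_len(reps), 2),
          value = c(inst, ideal)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
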