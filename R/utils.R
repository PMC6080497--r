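# internal helpers shared across modules

# stop with a consistent domain-error class
stop_domain <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "canemass_domain_error")
}

stop_input <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "canemass_input_error")
}

check_nonneg <- function(x, name) {
  if (any(!is.na(x) & x < 0)) {
    stop_domain("`%s` must be non-negative", name)
  }
  invisible(x)
}

check_pos <- function(x, name) {
  if (any(!is.na(x) & x <= 0)) {
    stop_domain("`%s` must be strictly positive", name)
  }
  invisible(x)
}

# deterministic 31-bit string hash used to derive per-unit RNG substreams,
# so adding a sampling unit never perturbs the draws of existing units
hash31 <- function(s) {
  ints <- utf8ToInt(s)
  h <- 0
  for (i in ints) h <- (h * 31 + i) %% 2147483647
  h
}

substream_seed <- function(master_seed, key) {
  (as.numeric(master_seed) * 48271 + hash31(key)) %% 2147483647
}

#' Emit a timestamped log message
#'
#' Logging for the campaign pipeline. Verbosity is controlled by
#' `options(canemass.verbosity =)`: 0 silences everything, 1 (default)
#' prints informational messages, 2 adds debug detail.
#'
#' @param msg Message (sprintf format string).
#' @param ... Values interpolated into `msg`.
#' @param level Message level; printed when `level <=` the verbosity option.
#' @return `msg`, invisibly.
#' @export
cane_log <- function(msg, ..., level = 1) {
  verbosity <- getOption("canemass.verbosity", 1)
  if (level <= verbosity) {
    inform(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(msg, ...)))
  }
  invisible(msg)
}

#' Default pipeline configuration
#'
#' Nested configuration used across the pipeline, with sections `io`
#' (delimiter), `fitting` (optimizer tolerances, origin-forcing weight,
#' bound-expansion convention), `uncertainty` (second-order combination
#' rule, ensemble sizes) and `simulation` (noise tier). A YAML file with
#' the same section layout can override any subset of entries.
#'
#' @param path Optional YAML file whose entries override the defaults.
#' @return A nested list of configuration sections.
#' @export
campaign_config <- function(path = NULL) {
  cfg <- list(
    io = list(delim = ","),
    fitting = list(
      ftol = 1e-10, ptol = 1e-10, maxfev = 10000,
      origin_weight = 1, expansion = 0.10, expansion_mode = "halfwidth",
      force_origin = TRUE
    ),
    uncertainty = list(second_order = "quadrature", n_biomass = 100, n_density = 100),
    simulation = list(tier = "idealization")
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (sec in intersect(names(user), names(cfg))) {
      cfg[[sec]][names(user[[sec]])] <- user[[sec]]
    }
  }
  cfg
}
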