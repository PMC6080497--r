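# Campaign container and delimited-text IO.
#
# A campaign is a list of three tibbles:
#   biometrics  one row per non-destructive observation (per corner point)
#   biomass     one row per destructive observation at an ESUB
#   fields      one row per field
# Internal units are strictly SI (m, kg, kg/m^3, fractions); cane counts
# stay per row-metre. Files may carry a "#units" row naming the unit of
# each column; values are converted to SI on read.

biometric_cols <- c(
  field_id = "character", unit_id = "character", unit_kind = "character",
  t = "numeric", corner = "numeric", H = "numeric", D = "numeric",
  leaf_len = "numeric", C_row = "numeric", P_row = "numeric",
  LAI_eff = "numeric", x = "numeric", y = "numeric"
)
biomass_cols <- c(
  field_id = "character", unit_id = "character", t = "numeric",
  plant_mass = "numeric", canes_per_plant = "numeric", cane_mass = "numeric",
  BM_L = "numeric", rho_S = "numeric", wet_content_stalk = "numeric",
  wet_content_leaf = "numeric", BM_S_measured = "numeric"
)
field_cols <- c(
  field_id = "character", ratoon_cycle = "numeric", area_ha = "numeric",
  start_of_growth = "character", harvest = "character"
)

mandatory_cols <- list(
  biometrics = c("field_id", "unit_id", "t", "H", "D"),
  biomass = c("field_id", "unit_id", "t", "cane_mass"),
  fields = c("field_id")
)

# multiplicative conversion to the SI unit of each measured column
unit_factors <- c(
  m = 1, cm = 0.01, mm = 0.001,
  kg = 1, g = 0.001, t = 1000,
  `kg/m3` = 1, `kg/m^3` = 1, `g/cm3` = 1000, `g/cm^3` = 1000,
  fraction = 1, `%` = 0.01, percent = 0.01,
  day = 1, days = 1, `canes/m` = 1, `plants/m` = 1, `m2/m2` = 1,
  `m^2/m^2` = 1, ha = 1
)

empty_table <- function(schema) {
  out <- lapply(schema, function(ty) vector(ty, 0))
  as_tibble(out)
}

#' Construct a campaign table
#'
#' Bundles biometric records, destructive biomass records and field
#' metadata into a single `campaign` object. Missing columns are added as
#' `NA` (missing optional quantities are explicit `NA`s, never zeros);
#' unknown columns are retained.
#'
#' @param biometrics Data frame of non-destructive observations: one row
#'   per corner-point measurement with columns `field_id`, `unit_id`,
#'   `unit_kind` (`"ESU"`, `"ESUB"` or `"INTENSIVE"`), `t` (days since
#'   start of growth), `corner`, `H` (stalk height, m), `D` (stalk
#'   diameter, m) and optionally `leaf_len`, `C_row`, `P_row`, `LAI_eff`,
#'   `x`, `y`.
#' @param biomass Data frame of destructive ESUB observations: `field_id`,
#'   `unit_id`, `t`, `plant_mass` (kg), `canes_per_plant`, `cane_mass`
#'   (kg), `BM_L` (leaf biomass per cane, kg), `rho_S` (kg/m^3),
#'   `wet_content_stalk`, `wet_content_leaf` (fractions), `BM_S_measured`.
#' @param fields Data frame of field metadata: `field_id`, `ratoon_cycle`,
#'   `area_ha`, `start_of_growth`, `harvest`.
#' @return An object of class `campaign`.
#' @export
campaign <- function(biometrics = NULL, biomass = NULL, fields = NULL) {
  fill <- function(df, schema) {
    if (is.null(df)) return(empty_table(schema))
    df <- as_tibble(df)
    for (nm in names(schema)) {
      if (!nm %in% names(df)) df[[nm]] <- vector(schema[[nm]], 1)[NA]
    }
    df[, c(names(schema), setdiff(names(df), names(schema)))]
  }
  structure(
    list(
      biometrics = fill(biometrics, biometric_cols),
      biomass = fill(biomass, biomass_cols),
      fields = fill(fields, field_cols)
    ),
    class = "campaign"
  )
}

#' @export
print.campaign <- function(x, ...) {
  cat(sprintf(
    "Sugarcane campaign: %d fields, %d biometric records, %d destructive records\n",
    nrow(x$fields), nrow(x$biometrics), nrow(x$biomass)
  ))
  if (nrow(x$biometrics) > 0) {
    cat(sprintf("  units: %s\n",
                paste(sort(unique(x$biometrics$unit_id)), collapse = ", ")))
  }
  invisible(x)
}

read_table_file <- function(path, delim, schema, table_name) {
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"), progress = FALSE, show_col_types = FALSE
  )
  miss <- setdiff(mandatory_cols[[table_name]], names(raw))
  if (length(miss) > 0) {
    rlang::abort(
      sprintf("%s: missing mandatory column(s): %s", basename(path),
              paste(miss, collapse = ", ")),
      class = "canemass_format_error"
    )
  }
  units <- NULL
  if (nrow(raw) > 0 && !is.na(raw[[1]][1]) && raw[[1]][1] == "#units") {
    units <- as.character(raw[1, ])[-1]
    names(units) <- names(raw)[-1]
    raw <- raw[-1, , drop = FALSE]
  }
  problems <- tibble(table = character(), row = integer(),
                     column = character(), value = character())
  out <- raw
  for (nm in names(raw)) {
    target <- schema[[nm]]
    if (is.null(target) || target != "numeric") next
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- which(is.na(v) & !is.na(raw[[nm]]))
    if (length(bad) > 0) {
      problems <- dplyr::bind_rows(problems, tibble(
        table = table_name, row = bad, column = nm, value = raw[[nm]][bad]
      ))
    }
    u <- units[nm]
    if (!is.null(units) && !is.na(u) && u != "" && u != "SI") {
      f <- unit_factors[u]
      if (is.na(f)) {
        rlang::abort(sprintf("%s: unknown unit '%s' for column '%s'",
                             basename(path), u, nm),
                     class = "canemass_format_error")
      }
      v <- v * unname(f)
    }
    out[[nm]] <- unname(v)
  }
  # rows with any unparseable numeric cell are dropped (reported upstream)
  if (nrow(problems) > 0) out <- out[-unique(problems$row), , drop = FALSE]
  list(table = out, problems = problems)
}

#' Read a campaign from delimited text
#'
#' Reads `biometrics`, `biomass` and `fields` tables (CSV by default, TSV
#' accepted) from a directory. Each file may carry an optional second row
#' whose first cell is `#units`, naming the unit of every column (e.g.
#' `cm`, `g`, `g/cm3`, `%`); values are converted to SI on read. Rows with
#' unparseable numeric cells are dropped and reported, with their
#' locations, in the `"problems"` attribute.
#'
#' @param path Directory containing `biometrics.csv`, `biomass.csv`,
#'   `fields.csv` (or `.tsv` with `delim = "\t"`).
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return A [campaign] object; invalid-row report in `attr(, "problems")`.
#' @seealso [write_campaign()], [validate_campaign()]
#' @export
read_campaign <- function(path, delim = ",") {
  if (!dir.exists(path)) stop_input("campaign directory '%s' does not exist", path)
  ext <- if (delim == "\t") "tsv" else "csv"
  parts <- list()
  probs <- list()
  for (nm in c("biometrics", "biomass", "fields")) {
    f <- file.path(path, paste0(nm, ".", ext))
    if (file.exists(f)) {
      schema <- switch(nm, biometrics = biometric_cols,
                       biomass = biomass_cols, fields = field_cols)
      got <- read_table_file(f, delim, schema, nm)
      parts[[nm]] <- got$table
      probs[[nm]] <- got$problems
    }
  }
  if (length(parts) == 0) {
    stop_input("no campaign tables found under '%s'", path)
  }
  out <- campaign(parts$biometrics, parts$biomass, parts$fields)
  attr(out, "problems") <- dplyr::bind_rows(probs)
  n_bad <- nrow(attr(out, "problems"))
  if (n_bad > 0) cane_log("read_campaign: dropped %d invalid row(s)", n_bad)
  out
}

#' Write a campaign to delimited text
#'
#' Writes the three campaign tables in SI units to `biometrics.csv`,
#' `biomass.csv` and `fields.csv` under `path` (created if needed).
#' Numeric columns are written at full precision, so
#' `read_campaign(write_campaign(x))` reproduces `x` exactly.
#'
#' @param x A [campaign] object.
#' @param path Output directory.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_campaign <- function(x, path, delim = ",") {
  stopifnot(inherits(x, "campaign"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  ext <- if (delim == "\t") "tsv" else "csv"
  for (nm in c("biometrics", "biomass", "fields")) {
    readr::write_delim(x[[nm]], file.path(path, paste0(nm, ".", ext)),
                       delim = delim, na = "NA")
  }
  invisible(path)
}

violation <- function(table, key, rule, message) {
  tibble(table = table, key = key, rule = rule, message = message)
}

#' Validate a campaign against its physical invariants
#'
#' Checks every record against the domain invariants (non-negative heights,
#' diameters and masses; wet contents in `[0, 1]`; cane count at least the
#' plant count; positive stalk density; positive field area; harvest after
#' start of growth; referential integrity of `field_id`). Validation is
#' total: any campaign yields a report, never an error.
#'
#' @param x A [campaign] object.
#' @return A tibble with one row per violation (columns `table`, `key`,
#'   `rule`, `message`); zero rows for a clean campaign.
#' @export
validate_campaign <- function(x) {
  stopifnot(inherits(x, "campaign"))
  out <- list()
  bio <- x$biometrics
  key_bio <- sprintf("%s/%s/t=%s/corner=%s", bio$field_id, bio$unit_id,
                     bio$t, bio$corner)
  chk <- function(tbl, idx, table, keys, rule, msg) {
    if (any(idx, na.rm = TRUE)) {
      violation(table, keys[which(idx)], rule, msg)
    } else NULL
  }
  out$h <- chk(bio, bio$H < 0, "biometrics", key_bio, "H_nonneg",
               "stalk height must be >= 0")
  out$d <- chk(bio, bio$D < 0, "biometrics", key_bio, "D_nonneg",
               "stalk diameter must be >= 0")
  out$t <- chk(bio, bio$t < 0, "biometrics", key_bio, "t_nonneg",
               "days since start of growth must be >= 0")
  out$cp <- chk(bio, !is.na(bio$C_row) & !is.na(bio$P_row) &
                  (bio$C_row < bio$P_row | bio$P_row < 0),
                "biometrics", key_bio, "count_order",
                "need C_row >= P_row >= 0")
  bm <- x$biomass
  key_bm <- sprintf("%s/%s/t=%s", bm$field_id, bm$unit_id, bm$t)
  for (col in c("plant_mass", "cane_mass", "BM_L", "BM_S_measured")) {
    out[[col]] <- chk(bm, bm[[col]] < 0, "biomass", key_bm,
                      paste0(col, "_nonneg"),
                      sprintf("%s must be >= 0", col))
  }
  for (col in c("wet_content_stalk", "wet_content_leaf")) {
    out[[col]] <- chk(bm, bm[[col]] < 0 | bm[[col]] > 1, "biomass", key_bm,
                      paste0(col, "_range"),
                      sprintf("%s must lie in [0, 1]", col))
  }
  out$rho <- chk(bm, bm$rho_S <= 0, "biomass", key_bm, "rho_pos",
                 "stalk density must be > 0 when present")
  fl <- x$fields
  out$area <- chk(fl, fl$area_ha <= 0, "fields", fl$field_id, "area_pos",
                  "field area must be > 0")
  if (all(c("start_of_growth", "harvest") %in% names(fl)) && nrow(fl) > 0) {
    sog <- suppressWarnings(as.Date(fl$start_of_growth))
    hv <- suppressWarnings(as.Date(fl$harvest))
    out$dates <- chk(fl, !is.na(sog) & !is.na(hv) & hv <= sog, "fields",
                     fl$field_id, "harvest_after_start",
                     "harvest must postdate start of growth")
  }
  known <- fl$field_id
  for (tbl in c("biometrics", "biomass")) {
    ids <- x[[tbl]]$field_id
    bad <- !is.na(ids) & !(ids %in% known)
    if (any(bad)) {
      out[[paste0(tbl, "_ref")]] <- violation(
        tbl, unique(ids[bad]), "field_ref",
        "record references a field_id absent from the fields table"
      )
    }
  }
  dplyr::bind_rows(out)
}
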