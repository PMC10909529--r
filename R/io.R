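#' Typed delimited-text readers and writers
#'
#' All pipeline inputs and outputs are UTF-8 comma-separated files with a
#' mandatory header row and "." decimal mark. Missing values are empty cells
#' and surface as `NA` gaps — never as zero. `read_records()` parses a file
#' against a named schema, validates every row against the record type's
#' invariants, and raises a structured error naming the offending row(s);
#' `write_records()` is its inverse, and a write-then-read round trip
#' preserves every field.
#'
#' Available schemas:
#' \describe{
#'   \item{`burned_area`}{`year, level, code, category, protection, area_ha,
#'     source` — one source's report of area burned for a year x geography x
#'     category. `level` is `national`/`region`/`state`; region codes are
#'     restricted to the four-region partition. Key: all columns except
#'     `area_ha`.}
#'   \item{`landcover`}{`year, state, class, ownership, area_ha` — satellite
#'     land-cover class summaries.}
#'   \item{`fuel_profile`}{`region, category, compartment, load_t_dm_ha` —
#'     compartment fuel loads (t dry matter/ha).}
#'   \item{`fuel_coefficients`}{`region, year, compartment, coefficient` —
#'     yearly multiplicative fuel-dynamics change factors (must be > 0).}
#'   \item{`completeness`}{`region, year, compartment, completeness` —
#'     combustion-completeness fractions in \[0, 1\].}
#'   \item{`severity_completeness`}{`severity, compartment, completeness` —
#'     static literature completeness sets (`low`/`moderate`/`high`).}
#'   \item{`removal_series`}{`geography, component, year, value_tc` — annual
#'     removal fluxes (`fire`/`harvest`/`grazing`), tC/yr;
#'     `harvest_stem` marks the pre-expansion stem series.}
#'   \item{`stock_points`}{`time, level, code, forest_area_ha,
#'     stock_density_tc_ha, total_stock_tc` — inventory-time forest area and
#'     biomass carbon; `total = area x density` is enforced to 1e-6 relative.}
#'   \item{`annual_series`}{`year, value` — a bare annual series.}
#' }
#'
#' @param path File to read or write.
#' @param schema One of the schema names above.
#' @return `read_records()`: a validated tibble with the schema's columns.
#' @export
read_records <- function(path, schema) {
  sch <- get_schema(schema)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  # readr warns about parse problems; they are escalated to errors below
  df <- suppressWarnings(
    readr::read_csv(path, col_types = sch$col_types, na = "",
                    progress = FALSE, show_col_types = FALSE))
  extra <- setdiff(names(df), names(sch$columns))
  if (length(extra)) {
    abort(paste0("unknown column(s) in ", path, ": ",
                 paste(extra, collapse = ", ")))
  }
  missing_cols <- setdiff(names(sch$columns), names(df))
  if (length(missing_cols)) {
    abort(paste0("missing column(s) in ", path, ": ",
                 paste(missing_cols, collapse = ", ")))
  }
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(paste0("parse failure in ", path, " at row(s) ",
                 paste(head(unique(probs$row), 5), collapse = ", "),
                 " (e.g. non-numeric value in a numeric column)"))
  }
  validate_records(df, schema, context = path)
}

#' @rdname read_records
#' @param records A tibble conforming to the schema.
#' @return `write_records()`: the input, invisibly.
#' @export
write_records <- function(records, path, schema) {
  records <- validate_records(records, schema)
  readr::write_csv(records, path, na = "")
  invisible(records)
}

#' @rdname read_records
#' @param context Label used in error messages (defaults to "records").
#' @export
validate_records <- function(records, schema, context = "records") {
  sch <- get_schema(schema)
  records <- as_tibble(records)
  missing_cols <- setdiff(names(sch$columns), names(records))
  if (length(missing_cols)) {
    abort(paste0(context, " lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  records <- records[names(sch$columns)]
  sch$validate(records, context)
  if (!is.null(sch$key)) {
    dup <- which(duplicated(records[sch$key]))
    if (length(dup)) {
      abort(paste0(context, ": duplicate key at row(s) ",
                   paste(head(dup, 5), collapse = ", "),
                   " (key: ", paste(sch$key, collapse = ", "), ")"))
    }
  }
  records
}

row_check <- function(bad, context, message) {
  if (any(bad, na.rm = TRUE)) {
    abort(paste0(context, ": ", message, " at row(s) ",
                 paste(head(which(bad), 5), collapse = ", ")))
  }
}

check_year_col <- function(x, context, col = "year") {
  row_check(is.na(x) | x != floor(x), context,
            paste0("`", col, "` must be a whole calendar year"))
}

get_schema <- function(schema) {
  if (!schema %in% names(fc_schemas)) {
    abort(paste0("unknown schema `", schema, "`; available: ",
                 paste(names(fc_schemas), collapse = ", ")))
  }
  fc_schemas[[schema]]
}

fc_schemas <- list(
  burned_area = list(
    columns = c(year = "i", level = "c", code = "c", category = "c",
                protection = "c", area_ha = "d", source = "c"),
    col_types = readr::cols(
      year = readr::col_integer(), level = readr::col_character(),
      code = readr::col_character(), category = readr::col_character(),
      protection = readr::col_character(), area_ha = readr::col_double(),
      source = readr::col_character()),
    key = c("year", "level", "code", "category", "protection", "source"),
    validate = function(df, context) {
      check_year_col(df$year, context)
      row_check(!df$level %in% c("national", "region", "state"), context,
                "`level` must be national/region/state")
      row_check(df$level == "region" & !df$code %in% region_codes(), context,
                "region `code` must be one of NE/SE/RM/PC")
      row_check(!df$category %in% c(forest_categories(), "total"), context,
                "unknown `category`")
      row_check(!df$protection %in%
                  c("protected", "unprotected", "unspecified"), context,
                "`protection` must be protected/unprotected/unspecified")
      row_check(df$area_ha < 0, context, "`area_ha` must be >= 0")
    }
  ),
  landcover = list(
    columns = c(year = "i", state = "c", class = "c", ownership = "c",
                area_ha = "d"),
    col_types = readr::cols(
      year = readr::col_integer(), state = readr::col_character(),
      class = readr::col_character(), ownership = readr::col_character(),
      area_ha = readr::col_double()),
    key = c("year", "state", "class", "ownership"),
    validate = function(df, context) {
      check_year_col(df$year, context)
      row_check(df$area_ha < 0, context, "`area_ha` must be >= 0")
    }
  ),
  fuel_profile = list(
    columns = c(region = "c", category = "c", compartment = "c",
                load_t_dm_ha = "d"),
    col_types = readr::cols(
      region = readr::col_character(), category = readr::col_character(),
      compartment = readr::col_character(),
      load_t_dm_ha = readr::col_double()),
    key = c("region", "category", "compartment"),
    validate = function(df, context) {
      row_check(!df$region %in% c(region_codes(), "national"), context,
                "unknown `region`")
      row_check(!df$category %in% c(forest_categories(), "all"), context,
                "unknown `category`")
      row_check(!df$compartment %in% fuel_compartments(), context,
                "unknown fuel `compartment`")
      row_check(df$load_t_dm_ha < 0, context, "`load_t_dm_ha` must be >= 0")
    }
  ),
  fuel_coefficients = list(
    columns = c(region = "c", year = "i", compartment = "c",
                coefficient = "d"),
    col_types = readr::cols(
      region = readr::col_character(), year = readr::col_integer(),
      compartment = readr::col_character(),
      coefficient = readr::col_double()),
    key = c("region", "year", "compartment"),
    validate = function(df, context) {
      check_year_col(df$year, context)
      row_check(!df$compartment %in% fuel_compartments(), context,
                "unknown fuel `compartment`")
      row_check(df$coefficient <= 0, context, "`coefficient` must be > 0")
    }
  ),
  completeness = list(
    columns = c(region = "c", year = "i", compartment = "c",
                completeness = "d"),
    col_types = readr::cols(
      region = readr::col_character(), year = readr::col_integer(),
      compartment = readr::col_character(),
      completeness = readr::col_double()),
    key = c("region", "year", "compartment"),
    validate = function(df, context) {
      check_year_col(df$year, context)
      row_check(df$completeness < 0 | df$completeness > 1, context,
                "`completeness` must lie in [0, 1]")
    }
  ),
  severity_completeness = list(
    columns = c(severity = "c", compartment = "c", completeness = "d"),
    col_types = readr::cols(
      severity = readr::col_character(),
      compartment = readr::col_character(),
      completeness = readr::col_double()),
    key = c("severity", "compartment"),
    validate = function(df, context) {
      row_check(!df$severity %in% c("low", "moderate", "high"), context,
                "`severity` must be low/moderate/high")
      row_check(df$completeness < 0 | df$completeness > 1, context,
                "`completeness` must lie in [0, 1]")
    }
  ),
  removal_series = list(
    columns = c(geography = "c", component = "c", year = "i",
                value_tc = "d"),
    col_types = readr::cols(
      geography = readr::col_character(),
      component = readr::col_character(), year = readr::col_integer(),
      value_tc = readr::col_double()),
    key = c("geography", "component", "year"),
    validate = function(df, context) {
      check_year_col(df$year, context)
      row_check(!df$component %in%
                  c("fire", "harvest", "grazing", "harvest_stem"), context,
                "`component` must be fire/harvest/grazing/harvest_stem")
      row_check(df$value_tc < 0, context, "`value_tc` must be >= 0")
    }
  ),
  stock_points = list(
    columns = c(time = "i", level = "c", code = "c", forest_area_ha = "d",
                stock_density_tc_ha = "d", total_stock_tc = "d"),
    col_types = readr::cols(
      time = readr::col_integer(), level = readr::col_character(),
      code = readr::col_character(),
      forest_area_ha = readr::col_double(),
      stock_density_tc_ha = readr::col_double(),
      total_stock_tc = readr::col_double()),
    key = c("time", "level", "code"),
    validate = function(df, context) {
      check_year_col(df$time, context, "time")
      row_check(df$forest_area_ha < 0 | df$stock_density_tc_ha < 0 |
                  df$total_stock_tc < 0, context, "stock values must be >= 0")
      expected <- df$forest_area_ha * df$stock_density_tc_ha
      rel <- abs(df$total_stock_tc - expected) / pmax(abs(expected), 1)
      row_check(rel > 1e-6, context,
                "`total_stock_tc` != forest_area_ha * stock_density_tc_ha")
    }
  ),
  annual_series = list(
    columns = c(year = "i", value = "d"),
    col_types = readr::cols(year = readr::col_integer(),
                            value = readr::col_double()),
    key = "year",
    validate = function(df, context) check_year_col(df$year, context)
  )
)
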