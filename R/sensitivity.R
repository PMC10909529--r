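#' Enumerate the factorial sensitivity design
#'
#' The burned-biomass uncertainty design crosses two fuel-load sources
#' (field-measured vs. modeled) with two fuel dynamics (static
#' reference-period mean vs. dynamic coefficient-scaled) — the four main
#' variations — and three static combustion-completeness severity sets
#' (low, moderate, high) — the sub-variants. Over the four study regions
#' this yields 4 x 2 x 2 x 3 = 48 regional burned-biomass series.
#'
#' @param regions Character vector of distinct region codes.
#' @return Tibble with columns `region, fuel_source, fuel_dynamics, cc_mode`
#'   in deterministic order, `12 * length(regions)` rows.
#' @export
#' @examples
#' nrow(enumerate_variants(region_codes()))  # 48
enumerate_variants <- function(regions) {
  if (length(regions) == 0) abort("`regions` must be non-empty")
  if (anyDuplicated(regions)) {
    abort(paste0("duplicate region(s): ",
                 paste(unique(regions[duplicated(regions)]), collapse = ", ")))
  }
  expand_grid(
    region = regions,
    fuel_source = c("field_measured", "modeled"),
    fuel_dynamics = c("static", "dynamic"),
    cc_mode = c("low", "moderate", "high")
  )
}

#' Plausible ordered severity completeness sets
#'
#' Static literature-style combustion-completeness fractions by compartment
#' for low, moderate and high fire severity. Fine fuels (duff/litter, 1-hr
#' dead, herbs) burn most completely; coarse dead wood and canopy least.
#' The sets are ordered: low <= moderate <= high in every compartment.
#'
#' @return Tibble with schema `severity_completeness`.
#' @export
default_severity_completeness <- function() {
  comps <- fuel_compartments()
  low <- c(duff_litter = 0.30, dead_1hr = 0.40, dead_10hr = 0.20,
           dead_100hr = 0.10, dead_1000hr = 0.05, herb = 0.50,
           canopy = 0.02)
  moderate <- c(duff_litter = 0.55, dead_1hr = 0.70, dead_10hr = 0.45,
                dead_100hr = 0.25, dead_1000hr = 0.12, herb = 0.80,
                canopy = 0.10)
  high <- c(duff_litter = 0.85, dead_1hr = 0.95, dead_10hr = 0.75,
            dead_100hr = 0.55, dead_1000hr = 0.35, herb = 0.99,
            canopy = 0.40)
  bind_rows(
    tibble(severity = "low", compartment = comps,
           completeness = unname(low[comps])),
    tibble(severity = "moderate", compartment = comps,
           completeness = unname(moderate[comps])),
    tibble(severity = "high", compartment = comps,
           completeness = unname(high[comps]))
  )
}

#' Run one sensitivity variant of regional burned biomass
#'
#' Re-estimates a region's burned-biomass series under one factorial
#' combination: fuel loads from the chosen source, held static at the
#' reference-period base or scaled dynamically by the yearly change
#' coefficients, combined with the chosen static severity completeness set,
#' and summed over forest categories with the category allocation rule.
#'
#' @param spec One-row tibble (or list) with `region, fuel_source,
#'   fuel_dynamics, cc_mode`.
#' @param inputs Named list with:
#'   \describe{
#'     \item{`field_profile`, `modeled_profile`}{Fuel profiles
#'       (`region, category, compartment, load_t_dm_ha`).}
#'     \item{`coefficients`}{`region, year, compartment, coefficient`.}
#'     \item{`severity`}{Severity completeness sets (schema
#'       `severity_completeness`).}
#'     \item{`area`}{Regional burned area, `region, category, year, value`
#'       (ha).}
#'     \item{`reference_period`}{`c(first, last)` years of the base loads.}
#'   }
#' @param carbon_fraction Carbon content of dry matter.
#' @return Annual-series tibble of regional burned biomass (tC).
#' @export
run_variant <- function(spec, inputs, carbon_fraction = 0.5) {
  spec <- as.list(as_tibble(spec)[1, ])
  profile_tbl <- switch(spec$fuel_source,
                        field_measured = inputs$field_profile,
                        modeled = inputs$modeled_profile,
                        abort(paste0("unknown fuel_source: ",
                                     spec$fuel_source)))
  if (is.null(profile_tbl)) {
    abort(paste0("fuel table for source `", spec$fuel_source,
                 "` not provided"))
  }
  sev <- filter(inputs$severity, .data$severity == spec$cc_mode)
  if (nrow(sev) == 0) {
    abort(paste0("severity completeness set `", spec$cc_mode, "` missing"))
  }
  area_region <- filter(inputs$area, .data$region == spec$region)
  if (nrow(area_region) == 0) {
    abort(paste0("no burned-area series for region ", spec$region))
  }
  years <- sort(unique(area_region$year))
  ref <- inputs$reference_period %||% c(2003L, 2015L)

  per_category <- map(forest_categories(), function(cat) {
    base <- profile_tbl |>
      filter(.data$region == spec$region, .data$category == cat) |>
      select("compartment", "load_t_dm_ha")
    if (nrow(base) == 0) {
      abort(paste0("fuel profile missing for region ", spec$region,
                   ", category ", cat))
    }
    loads <- if (spec$fuel_dynamics == "static") {
      expand_grid(year = years, compartment = base$compartment) |>
        left_join(base, by = "compartment")
    } else {
      coefs <- filter(inputs$coefficients, .data$region == spec$region)
      anchor <- coefs |>
        filter(.data$year %in% ref[1]:ref[2]) |>
        group_by(.data$compartment) |>
        summarise(ref_mean = mean(.data$coefficient), .groups = "drop")
      coefs |>
        filter(.data$year %in% years) |>
        inner_join(anchor, by = "compartment") |>
        inner_join(base, by = "compartment") |>
        mutate(load_t_dm_ha = .data$load_t_dm_ha * .data$coefficient /
                 .data$ref_mean) |>
        select("year", "compartment", "load_t_dm_ha")
    }
    timeline <- loads |>
      left_join(select(sev, "compartment", "completeness"),
                by = "compartment")
    area_series <- area_region |>
      filter(.data$category == cat) |>
      select("year", "value")
    burned_biomass(area_series, timeline, cat,
                   carbon_fraction = carbon_fraction)
  })

  per_category |>
    list_rbind() |>
    group_by(.data$year) |>
    summarise(value = if (all(is.na(.data$value))) NA_real_ else
      sum(.data$value, na.rm = TRUE), .groups = "drop") |>
    annual_series()
}

#' Run the full factorial variant family
#'
#' @inheritParams run_variant
#' @param regions Region codes to enumerate (default all four).
#' @return An `fc_sensitivity` tibble: one row per variant x year with the
#'   spec columns and `value` (tC).
#' @export
run_sensitivity <- function(inputs, regions = region_codes(),
                            carbon_fraction = 0.5) {
  specs <- enumerate_variants(regions)
  out <- map(seq_len(nrow(specs)), function(i) {
    row <- specs[i, ]
    run_variant(row, inputs, carbon_fraction) |>
      mutate(region = row$region, fuel_source = row$fuel_source,
             fuel_dynamics = row$fuel_dynamics, cc_mode = row$cc_mode,
             .before = 1)
  }) |>
    list_rbind()
  structure(out, class = c("fc_sensitivity", class(out)))
}

#' Pointwise min/max envelope over sensitivity variants
#'
#' The uncertainty representation is purely factorial: the envelope's lower
#' and upper bounds are the pointwise minimum and maximum over all variant
#' series. The central estimate is carried alongside and *not* clipped into
#' the envelope — the extreme severity variants are understood as
#' unrealistic bounds, not a credible interval around the central value.
#'
#' @param variants A list of annual-series tibbles, or a long tibble with a
#'   grouping column and `year`/`value`.
#' @param central Annual series of the central estimate on the same span.
#' @param component Label (`"fire"`, `"harvest"`, `"grazing"`, `"total"`).
#' @return An `fc_envelope` object: tibble `year, low, central, high` with a
#'   `component` attribute.
#' @export
envelope <- function(variants, central, component = "fire") {
  if (is.data.frame(variants)) {
    long <- as_tibble(variants)
    stopifnot(all(c("year", "value") %in% names(long)))
  } else {
    if (length(variants) < 2) abort("need at least two variant series")
    long <- imap(variants, function(s, i) mutate(annual_series(s),
                                                 .variant = i)) |>
      list_rbind()
  }
  central <- annual_series(central)
  bounds <- long |>
    group_by(.data$year) |>
    summarise(
      low = if (all(is.na(.data$value))) NA_real_ else
        min(.data$value, na.rm = TRUE),
      high = if (all(is.na(.data$value))) NA_real_ else
        max(.data$value, na.rm = TRUE),
      .groups = "drop")
  out <- bounds |>
    left_join(rename(central, central = "value"), by = "year") |>
    select("year", "low", "central", "high") |>
    arrange(.data$year)
  structure(out, component = component,
            class = c("fc_envelope", class(out)))
}

#' Deviation summary of an envelope around its central estimate
#'
#' Reports the average and extreme deviations of the envelope bounds from
#' the central series: positive deviation `high - central`, negative
#' deviation `low - central` (non-positive). Values stay in the input unit;
#' divide by 1e6 to express tC as TgC.
#'
#' @param env An `fc_envelope` object (or tibble `year, low, central,
#'   high`).
#' @return One-row tibble: `mean_plus, max_plus, max_plus_year, mean_minus,
#'   min_minus, min_minus_year, n_years`.
#' @export
range_summary <- function(env) {
  env <- as_tibble(env)
  stopifnot(all(c("year", "low", "central", "high") %in% names(env)))
  ok <- !is.na(env$low) & !is.na(env$high) & !is.na(env$central)
  if (!any(ok)) abort("envelope and central share no non-gap year")
  e <- env[ok, ]
  plus <- e$high - e$central
  minus <- e$low - e$central
  tibble(
    mean_plus = mean(plus),
    max_plus = max(plus),
    max_plus_year = e$year[which.max(plus)],
    mean_minus = mean(minus),
    min_minus = min(minus),
    min_minus_year = e$year[which.min(minus)],
    n_years = nrow(e)
  )
}

#' @export
autoplot.fc_envelope <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$low, ymax = .data$high),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$central)) +
    ggplot2::labs(x = "Year", y = "Flux",
                  title = paste0("Sensitivity envelope (",
                                 attr(object, "component"), ")"),
                  subtitle = "ribbon: variant min/max; line: central") +
    ggplot2::theme_minimal()
}
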