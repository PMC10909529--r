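#' Allocate fuel compartments to a forest category
#'
#' Productive forests (state & private, federal) carry all seven fuel
#' compartments, from duff/litter to canopy. Sparse "other forest"
#' (wood-, shrub- and scrubland) is assumed to hold only duff/litter, 1-hr
#' dead fuels (small dead branches) and grasses/herbs; the remaining
#' compartments are structurally absent — removed, not zeroed.
#'
#' @param profile Tibble with columns `compartment` and `load_t_dm_ha`
#'   (additional columns pass through).
#' @param category One of [forest_categories()].
#' @return The profile filtered to the compartments present in `category`.
#' @export
#' @examples
#' prof <- tibble::tibble(
#'   compartment = c("duff_litter", "dead_1hr", "herb", "canopy"),
#'   load_t_dm_ha = c(5, 1, 0.5, 20))
#' allocate_fuels(prof, "other_forest")
allocate_fuels <- function(profile, category) {
  stopifnot(is.data.frame(profile), "compartment" %in% names(profile))
  if (!category %in% forest_categories()) {
    abort(paste0("unknown forest category: ", category))
  }
  bad <- setdiff(unique(profile$compartment), fuel_compartments())
  if (length(bad)) {
    abort(paste0("unknown fuel compartment(s): ", paste(bad, collapse = ", ")))
  }
  keep <- if (category == "other_forest") other_forest_compartments()
          else fuel_compartments()
  filter(profile, .data$compartment %in% keep)
}

#' Build a dynamic fuel timeline from a contemporary base profile
#'
#' Contemporary field-measured fuel loads (reference period 2003-2015 in the
#' default configuration) are scaled backward and forward in time with yearly
#' multiplicative change coefficients from a fire-enabled vegetation model,
#' which are consumed as inputs here. Coefficients are relative to the
#' reference period: the timeline is anchored so its reference-period mean
#' equals the base load in every compartment. Combustion-completeness
#' fractions for the same years are carried alongside the loads.
#'
#' @param base Tibble `compartment, load_t_dm_ha` — reference-period loads.
#' @param coefficients Tibble `year, compartment, coefficient`, all
#'   coefficients strictly positive.
#' @param completeness Tibble `year, compartment, completeness` in \[0, 1\].
#' @param reference_period `c(first, last)` years of the base measurements.
#' @return A fuel-timeline tibble `year, compartment, load_t_dm_ha,
#'   completeness`.
#' @export
build_fuel_timeline <- function(base, coefficients, completeness,
                                reference_period = c(2003L, 2015L)) {
  stopifnot(is.data.frame(base),
            all(c("compartment", "load_t_dm_ha") %in% names(base)))
  stopifnot(all(c("year", "compartment", "coefficient") %in%
                  names(coefficients)))
  stopifnot(all(c("year", "compartment", "completeness") %in%
                  names(completeness)))
  if (any(coefficients$coefficient <= 0, na.rm = TRUE) ||
      anyNA(coefficients$coefficient)) {
    abort("fuel change coefficients must all be > 0 and non-missing")
  }
  if (any(completeness$completeness < 0 | completeness$completeness > 1,
          na.rm = TRUE)) {
    abort("combustion completeness must lie in [0, 1]")
  }
  ref_years <- reference_period[1]:reference_period[2]
  anchor <- coefficients |>
    filter(.data$year %in% ref_years) |>
    group_by(.data$compartment) |>
    summarise(ref_mean = mean(.data$coefficient), .groups = "drop")
  if (nrow(anchor) == 0) {
    abort("coefficients do not cover any reference-period year")
  }
  loads <- coefficients |>
    inner_join(anchor, by = "compartment") |>
    inner_join(select(base, "compartment", "load_t_dm_ha"),
               by = "compartment") |>
    mutate(load_t_dm_ha = .data$load_t_dm_ha * .data$coefficient /
             .data$ref_mean) |>
    select("year", "compartment", "load_t_dm_ha")
  loads |>
    inner_join(select(completeness, "year", "compartment", "completeness"),
               by = c("year", "compartment")) |>
    arrange(.data$year, .data$compartment)
}

#' Extend a fuel timeline backward by constant extrapolation
#'
#' The modeled fuel record begins in 1941 while the national burned-area
#' record begins in 1926; the earlier national years reuse the first modeled
#' year's loads and completeness values unchanged.
#'
#' @param timeline Fuel-timeline tibble (`year, compartment, load_t_dm_ha,
#'   completeness`).
#' @param back_to First year of the extended timeline; must precede the first
#'   modeled year.
#' @param first_modeled_year Year whose values are copied back (defaults to
#'   the earliest year in `timeline`).
#' @return The timeline with years `back_to, ..., first_modeled_year - 1`
#'   prepended.
#' @export
extrapolate_pre_span <- function(timeline, back_to,
                                 first_modeled_year = min(timeline$year)) {
  stopifnot(is.data.frame(timeline), "year" %in% names(timeline))
  back_to <- as.integer(back_to)
  first_modeled_year <- as.integer(first_modeled_year)
  if (back_to >= first_modeled_year) {
    abort("`back_to` must precede `first_modeled_year`")
  }
  template <- filter(timeline, .data$year == first_modeled_year)
  if (nrow(template) == 0) {
    abort(paste0("timeline has no rows for first modeled year ",
                 first_modeled_year))
  }
  pre <- map(back_to:(first_modeled_year - 1L),
             function(y) mutate(template, year = as.integer(y))) |>
    list_rbind()
  bind_rows(pre, timeline) |> arrange(.data$year, .data$compartment)
}

#' Burned biomass carbon from area, fuel loads and combustion completeness
#'
#' The paper-level product: burned biomass
#' `B(y) = BA(y) * sum_c FL_c(y) * CC_c(y) * carbon_fraction`, in tons
#' carbon, with completeness applied per compartment before summation.
#' Compartments are filtered by the forest category's allocation rule, so an
#' "other forest" hectare burns only its sparse-fuel compartments. Gap years
#' in the burned-area series stay gaps; no imputation.
#'
#' @param area Annual series of burned area (ha).
#' @param timeline Fuel-timeline tibble covering the area years.
#' @param category One of [forest_categories()].
#' @param carbon_fraction Carbon content of dry matter (default 0.5).
#' @return Annual-series tibble in tC.
#' @export
burned_biomass <- function(area, timeline, category,
                           carbon_fraction = 0.5) {
  area <- annual_series(area)
  stopifnot(all(c("year", "compartment", "load_t_dm_ha", "completeness")
                %in% names(timeline)))
  if (any(timeline$completeness < 0 | timeline$completeness > 1,
          na.rm = TRUE)) {
    abort("combustion completeness must lie in [0, 1]")
  }
  alloc <- allocate_fuels(timeline, category)
  missing_years <- setdiff(area$year[!is.na(area$value)],
                           unique(alloc$year))
  if (length(missing_years)) {
    abort(paste0("fuel timeline does not cover year(s): ",
                 paste(head(missing_years, 5), collapse = ", ")))
  }
  consumed <- alloc |>
    group_by(.data$year) |>
    summarise(dm_per_ha = sum(.data$load_t_dm_ha * .data$completeness),
              .groups = "drop")
  out <- left_join(area, consumed, by = "year") |>
    mutate(value = dm_to_carbon(
      replace_na(.data$dm_per_ha, 0), carbon_fraction) * .data$value) |>
    select("year", "value")
  annual_series(out)
}
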