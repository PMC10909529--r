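#' Splice a historical and a satellite national series at a switch year
#'
#' The continuous national burned-area record is built from two sources: a
#' historical statistical compilation covering the early span and a
#' satellite-derived series from `switch_year` onward (1985 in the default
#' configuration, where census-era statistics end in 1984). The satellite
#' source is authoritative from `switch_year` on; historical values reported
#' for those years are logged as overlap diagnostics, never averaged in.
#'
#' @param historical,satellite Annual-series tibbles in hectares.
#' @param switch_year First year taken from the satellite source.
#' @return An annual-series tibble with an additional `source` column
#'   (`"historical"` or `"satellite"`, the per-year provenance) and a
#'   `diagnostics` attribute listing overlap years.
#' @export
splice_national <- function(historical, satellite, switch_year) {
  historical <- annual_series(historical)
  satellite <- annual_series(satellite)
  switch_year <- as.integer(switch_year)
  start <- min(historical$year)
  seam_years <- seq(start, switch_year - 1L)
  covered <- historical$year[!is.na(historical$value)]
  missing <- setdiff(seam_years, covered)
  if (length(missing)) {
    abort(paste0("historical source does not reach the seam; missing year(s): ",
                 paste(missing, collapse = ", ")))
  }
  overlap <- intersect(historical$year[!is.na(historical$value)],
                       satellite$year[satellite$year >= switch_year])
  hist_part <- historical |>
    filter(.data$year < switch_year) |>
    mutate(source = "historical")
  sat_part <- satellite |>
    filter(.data$year >= switch_year) |>
    mutate(source = "satellite")
  out <- bind_rows(hist_part, sat_part) |> arrange(.data$year)
  diagnostics <- tibble(
    event = rep("overlap_discarded", length(overlap)),
    year = as.integer(overlap),
    detail = rep("historical value superseded by satellite source",
                 length(overlap))
  )
  structure(out, diagnostics = diagnostics,
            class = c("fc_spliced", class(out)))
}

#' Aggregate state-level burned-area records to the four regions
#'
#' Sums state agency reports to region x category annual series. Protection
#' status (protected/unprotected) is aggregated away, matching the use of
#' totals in the balance. Gap semantics: a region x category x year is a gap
#' only when *every* member state lacks a report that year (absent row or
#' empty cell); otherwise the available states are summed.
#'
#' @param records Burned-area records (schema `burned_area`) at state level.
#' @param membership State-to-region table with columns `state`, `region`.
#' @param span Optional `c(first, last)` years over which to complete the
#'   output (defaults to the range of years present in `records`).
#' @return Tibble `region, category, year, value` (hectares; `NA` = gap).
#' @export
aggregate_states_to_regions <- function(records, membership,
                                        span = NULL) {
  records <- validate_records(records, "burned_area")
  validate_membership(membership)
  records <- filter(records, .data$level == "state")
  if (nrow(records) == 0) abort("no state-level records to aggregate")
  unmapped <- setdiff(unique(records$code), membership$state)
  if (length(unmapped)) {
    abort(paste0("state(s) not in membership table: ",
                 paste(unmapped, collapse = ", ")))
  }
  span <- span %||% range(records$year)
  joined <- left_join(records, membership, by = c(code = "state"))
  agg <- joined |>
    group_by(.data$region, .data$category, .data$year) |>
    summarise(value = if (all(is.na(.data$area_ha))) NA_real_ else
      sum(.data$area_ha, na.rm = TRUE), .groups = "drop")
  agg |>
    complete(region = unique(agg$region),
             category = unique(agg$category),
             year = span[1]:span[2]) |>
    arrange(.data$region, .data$category, .data$year)
}

#' Infer the unreported state & private burned area by subtraction
#'
#' After 1960 the state agency reports stopped covering state & private
#' forests, while an independent regional compilation still reported burned
#' area in total forest ecosystems. Subtracting the still-covered components
#' from the regional total recovers the missing state & private fraction.
#' Because burned area cannot be negative and the sources agree closely over
#' their overlaps, small negative residuals are treated as reporting noise:
#' clamped to zero and logged as diagnostics.
#'
#' @param regional_total Annual series of total forest burned area (ha).
#' @param covered Annual series summing the components still reported (ha).
#' @return Annual-series tibble; years missing in either input are gaps.
#'   Attribute `diagnostics` lists clamped years with their raw differences.
#' @export
infer_missing_state_private <- function(regional_total, covered) {
  regional_total <- annual_series(regional_total)
  covered <- annual_series(covered)
  joined <- full_join(regional_total, covered, by = "year",
                      suffix = c("_total", "_covered")) |>
    arrange(.data$year)
  raw <- joined$value_total - joined$value_covered
  clamped <- !is.na(raw) & raw < 0
  out <- tibble(year = joined$year, value = pmax(raw, 0))
  diagnostics <- tibble(
    event = rep("negative_difference_clamped", sum(clamped)),
    year = joined$year[clamped],
    detail = sprintf("raw difference %.6g ha set to 0", raw[clamped])
  )
  structure(out, diagnostics = diagnostics,
            class = c("fc_inferred", class(out)))
}

#' Default mapping from satellite land-cover classes to forest categories
#'
#' Tree-covered classes (deciduous, evergreen, mixed) are forest whose
#' category is taken from the intersected ownership column; shrub/scrub maps
#' to the low-productivity "other forest" category. Herbaceous and
#' agricultural classes are excluded from the forest reconstruction.
#'
#' @return A tibble `class, category` where category `"by_ownership"` means
#'   the record's ownership column supplies the forest category.
#' @export
default_class_map <- function() {
  tibble(
    class = c("deciduous", "evergreen", "mixed", "shrub_scrub"),
    category = c("by_ownership", "by_ownership", "by_ownership",
                 "other_forest")
  )
}

#' Aggregate satellite land-cover class tables into burned-area records
#'
#' Collapses per-class burned-area summaries (year x state x class x
#' ownership) onto the three forest categories. Classes mapped to
#' `"by_ownership"` take their category from the ownership column
#' (`state_private` or `federal`); classes mapped directly (shrub/scrub ->
#' other_forest) ignore ownership. Classes listed in `excluded` are dropped
#' and their total area logged; any other unmapped class is an error.
#'
#' @param class_table Records with schema `landcover`.
#' @param class_map Tibble `class, category` (see [default_class_map()]).
#' @param excluded Character vector of class names to drop (default
#'   `"herbaceous"`).
#' @param source Source tag stamped on the output records.
#' @return Burned-area records (schema `burned_area`, state level,
#'   protection `"unspecified"`), with attribute `excluded_area` summarising
#'   dropped classes.
#' @export
aggregate_landcover_classes <- function(class_table,
                                        class_map = default_class_map(),
                                        excluded = "herbaceous",
                                        source = "landsat") {
  class_table <- validate_records(class_table, "landcover")
  known <- c(class_map$class, excluded)
  unknown <- setdiff(unique(class_table$class), known)
  if (length(unknown)) {
    abort(paste0("land-cover class(es) neither mapped nor excluded: ",
                 paste(unknown, collapse = ", ")))
  }
  dropped <- class_table |>
    filter(.data$class %in% excluded) |>
    group_by(.data$class) |>
    summarise(total_area_ha = sum(.data$area_ha), .groups = "drop")
  kept <- class_table |>
    filter(!.data$class %in% excluded) |>
    left_join(class_map, by = "class") |>
    mutate(category = if_else(.data$category == "by_ownership",
                              .data$ownership, .data$category))
  bad_own <- setdiff(unique(kept$category), forest_categories())
  if (length(bad_own)) {
    abort(paste0("ownership value(s) not a forest category: ",
                 paste(bad_own, collapse = ", ")))
  }
  out <- kept |>
    group_by(.data$year, .data$state, .data$category) |>
    summarise(area_ha = sum(.data$area_ha), .groups = "drop") |>
    mutate(level = "state", code = .data$state, protection = "unspecified",
           source = .env$source) |>
    select("year", "level", "code", "category", "protection", "area_ha",
           "source")
  structure(validate_records(out, "burned_area"), excluded_area = dropped)
}

#' Reconstruct continuous national and regional burned-area series
#'
#' End-to-end harmonisation of the four source families into one national
#' series (historical statistics spliced with satellite data at
#' `switch_year`) and region x category series (state agency reports,
#' subtraction against regional totals where state & private coverage was
#' discontinued, satellite class summaries from `switch_year` on). Years in
#' the configured excluded window and years no source reports remain explicit
#' gaps — they are never interpolated, and balance computations skip them.
#'
#' @param sources Named list with elements:
#'   \describe{
#'     \item{`national_historical`}{Annual series for the early national
#'       record; unit set by `national_unit`.}
#'     \item{`agency`}{State-level burned-area records (schema
#'       `burned_area`), hectares.}
#'     \item{`regional_totals`}{Region-level records with category
#'       `"total"`, hectares.}
#'     \item{`landcover`}{Satellite class table (schema `landcover`),
#'       hectares.}
#'   }
#' @param membership State-to-region table (`state`, `region`).
#' @param span National study span `c(first, last)`.
#' @param switch_year First satellite year (default 1985).
#' @param excluded_window `c(first, last)` years excluded from the regional
#'   analysis (default `c(1980, 1984)`), or `NULL` for none.
#' @param sp_cutoff Last year state & private forests appear in the agency
#'   reports (default 1960); later years are inferred by subtraction.
#' @param regional_start First year of the regional reconstruction
#'   (default 1941).
#' @param national_unit `"acres"` (historical statistics, converted) or
#'   `"hectares"`.
#' @param class_map,excluded_classes Passed to
#'   [aggregate_landcover_classes()].
#' @return An object of class `fc_reconstruction`: a list with elements
#'   `national` (year, value, source), `regional` (region, category, year,
#'   value), and `diagnostics`. Methods: [tidy()], [glance()], [autoplot()].
#' @export
reconstruct_burned_area <- function(sources,
                                    membership = default_state_membership(),
                                    span = c(1926L, 2017L),
                                    switch_year = 1985L,
                                    excluded_window = c(1980L, 1984L),
                                    sp_cutoff = 1960L,
                                    regional_start = 1941L,
                                    national_unit = c("acres", "hectares"),
                                    class_map = default_class_map(),
                                    excluded_classes = "herbaceous") {
  national_unit <- match.arg(national_unit)
  needed <- c("national_historical", "agency", "regional_totals", "landcover")
  missing_src <- setdiff(needed, names(sources))
  if (length(missing_src)) {
    abort(paste0("sources list lacks: ", paste(missing_src, collapse = ", ")))
  }
  span <- as.integer(span)
  switch_year <- as.integer(switch_year)
  diagnostics <- list()

  hist <- annual_series(sources$national_historical)
  if (national_unit == "acres") {
    hist$value <- convert_area(hist$value)
  }

  sat_records <- aggregate_landcover_classes(
    sources$landcover, class_map = class_map, excluded = excluded_classes)
  excluded_log <- attr(sat_records, "excluded_area")
  if (nrow(excluded_log)) {
    diagnostics <- c(diagnostics, list(tibble(
      event = "landcover_class_excluded",
      year = NA_integer_,
      detail = sprintf("%s: %.6g ha excluded", excluded_log$class,
                       excluded_log$total_area_ha))))
  }
  sat_national <- sat_records |>
    group_by(.data$year) |>
    summarise(value = sum(.data$area_ha), .groups = "drop") |>
    complete_span(c(switch_year, span[2]))

  national <- splice_national(hist, sat_national, switch_year)
  diagnostics <- c(diagnostics, list(attr(national, "diagnostics")))

  # regional, historical segment: agency reports up to the satellite era
  agency <- validate_records(sources$agency, "burned_area")
  early_span <- c(regional_start, switch_year - 1L)
  agency_reg <- aggregate_states_to_regions(agency, membership,
                                            span = early_span)

  totals <- validate_records(sources$regional_totals, "burned_area") |>
    filter(.data$level == "region", .data$category == "total") |>
    mutate(region = .data$code) |>
    group_by(.data$region, .data$year) |>
    summarise(total = sum(.data$area_ha), .groups = "drop")

  early <- agency_reg |>
    pivot_wider(names_from = "category", values_from = "value") |>
    left_join(totals, by = c("region", "year"))
  for (cat in forest_categories()) {
    if (!cat %in% names(early)) early[[cat]] <- NA_real_
  }
  covered <- rowSums(cbind(early$federal, early$other_forest))
  need_infer <- early$year > sp_cutoff & is.na(early$state_private)
  raw <- early$total - covered
  inferred <- pmax(raw, 0)
  clamp <- need_infer & !is.na(raw) & raw < 0
  if (any(clamp)) {
    diagnostics <- c(diagnostics, list(tibble(
      event = "negative_difference_clamped",
      year = early$year[clamp],
      detail = sprintf("%s: raw state&private difference %.6g ha set to 0",
                       early$region[clamp], raw[clamp]))))
  }
  early$state_private[need_infer] <- inferred[need_infer]
  early_long <- early |>
    select(-"total") |>
    pivot_longer(all_of(forest_categories()),
                 names_to = "category", values_to = "value")

  # regional, satellite segment
  sat_reg <- aggregate_states_to_regions(sat_records, membership,
                                         span = c(switch_year, span[2]))

  regional <- bind_rows(early_long, sat_reg) |>
    complete(region = region_codes(), category = forest_categories(),
             year = regional_start:span[2]) |>
    arrange(.data$region, .data$category, .data$year)

  if (!is.null(excluded_window)) {
    win <- excluded_window[1]:excluded_window[2]
    regional$value[regional$year %in% win] <- NA_real_
    diagnostics <- c(diagnostics, list(tibble(
      event = "excluded_window",
      year = as.integer(win),
      detail = "regional year excluded from analysis by configuration")))
  }

  structure(
    list(
      national = as_tibble(national),
      regional = regional,
      diagnostics = bind_rows(diagnostics),
      span = span,
      switch_year = switch_year,
      excluded_window = excluded_window
    ),
    class = "fc_reconstruction"
  )
}

#' @export
print.fc_reconstruction <- function(x, ...) {
  cat("<fc_reconstruction>\n")
  cat("  national:", nrow(x$national), "years (",
      min(x$national$year), "-", max(x$national$year), ")\n")
  cat("  regional:", length(unique(x$regional$region)), "regions x",
      length(unique(x$regional$category)), "categories\n")
  cat("  diagnostics:", nrow(x$diagnostics), "events\n")
  invisible(x)
}

#' @export
tidy.fc_reconstruction <- function(x, ...) {
  bind_rows(
    x$national |>
      mutate(region = "national", category = "total") |>
      select("region", "category", "year", "value"),
    x$regional
  )
}

#' @export
glance.fc_reconstruction <- function(x, ...) {
  tibble(
    national_years = sum(!is.na(x$national$value)),
    regional_gap_years = sum(is.na(x$regional$value)),
    diagnostics = nrow(x$diagnostics),
    total_burned_mha = sum(x$national$value, na.rm = TRUE) / 1e6
  )
}

#' @export
autoplot.fc_reconstruction <- function(object, ...) {
  nat <- object$national
  smooth <- moving_average(annual_series(nat$year, nat$value), 5)
  ggplot2::ggplot(nat, ggplot2::aes(x = .data$year, y = .data$value / 1e6)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_line(data = smooth, colour = "black") +
    ggplot2::labs(x = "Year", y = "Burned forest area (Mha)",
                  title = "Reconstructed national burned area",
                  subtitle = "grey: annual; black: 5-year moving average") +
    ggplot2::theme_minimal()
}
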