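#' Estimate regional and national burned biomass from a reconstruction
#'
#' The central burned-biomass estimate: modeled fuel profiles scaled by the
#' dynamic change coefficients (anchored to the reference period) with
#' modeled combustion completeness, applied per region and forest category
#' to the reconstructed burned area and summed. The national series sums the
#' regional estimates in years where every region reports; in earlier years
#' covered only by the national burned-area record it falls back to
#' region-area-weighted mean fuel consumption with a configured category
#' mix.
#'
#' @param recon An `fc_reconstruction`.
#' @param fuel Named list of fuel tables: `modeled_profile`,
#'   `coefficients`, `completeness`, `reference_period`.
#' @param region_weights Named per-region forest areas (ha) used as weights
#'   for the national fallback.
#' @param category_mix Per-region named category shares for the national
#'   fallback (defaults to equal thirds when `NULL`).
#' @param carbon_fraction Carbon content of dry matter.
#' @return List with `regional` (tibble `region, year, value` in tC),
#'   `national` (annual series, tC) and `timelines` (per-region fuel
#'   timelines).
#' @export
estimate_burned_biomass <- function(recon, fuel, region_weights,
                                    category_mix = NULL,
                                    carbon_fraction = 0.5) {
  stopifnot(inherits(recon, "fc_reconstruction"))
  regions <- sort(unique(recon$regional$region))
  ref <- fuel$reference_period %||% c(2003L, 2015L)
  timelines <- map(regions, function(reg) {
    cat_tl <- map(forest_categories(), function(cat) {
      tl <- build_fuel_timeline(
        base = fuel$modeled_profile |>
          filter(.data$region == reg, .data$category == cat) |>
          select("compartment", "load_t_dm_ha"),
        coefficients = filter(fuel$coefficients, .data$region == reg),
        completeness = filter(fuel$completeness, .data$region == reg),
        reference_period = ref)
      if (recon$span[1] < min(tl$year)) {
        tl <- extrapolate_pre_span(tl, back_to = recon$span[1])
      }
      tl
    })
    setNames(cat_tl, forest_categories())
  }) |> setNames(regions)

  regional <- map(regions, function(reg) {
    map(forest_categories(), function(cat) {
      area <- recon$regional |>
        filter(.data$region == reg, .data$category == cat) |>
        select("year", "value")
      burned_biomass(area, timelines[[reg]][[cat]], cat, carbon_fraction)
    }) |>
      list_rbind() |>
      group_by(.data$year) |>
      summarise(value = if (all(is.na(.data$value))) NA_real_ else
        sum(.data$value, na.rm = TRUE), .groups = "drop") |>
      mutate(region = reg, .before = 1)
  }) |> list_rbind()

  # national: sum of regional estimates where complete, else weighted fuel
  # consumption applied to the national burned-area record
  reg_sum <- regional |>
    group_by(.data$year) |>
    summarise(value = if (any(is.na(.data$value))) NA_real_ else
      sum(.data$value), .groups = "drop")
  w <- region_weights[regions] / sum(region_weights[regions])
  mix <- category_mix %||%
    setNames(rep(list(setNames(rep(1 / 3, 3), forest_categories())),
                 length(regions)), regions)
  consumption <- map(regions, function(reg) {
    map(forest_categories(), function(cat) {
      allocate_fuels(timelines[[reg]][[cat]], cat) |>
        group_by(.data$year) |>
        summarise(dm = sum(.data$load_t_dm_ha * .data$completeness),
                  .groups = "drop") |>
        mutate(dm = .data$dm * mix[[reg]][[cat]] * w[[reg]])
    }) |> list_rbind()
  }) |>
    list_rbind() |>
    group_by(.data$year) |>
    summarise(dm_per_ha = sum(.data$dm), .groups = "drop")
  national <- recon$national |>
    select("year", "value") |>
    left_join(reg_sum, by = "year", suffix = c("_ba", "_reg")) |>
    left_join(consumption, by = "year") |>
    mutate(value = if_else(
      !is.na(.data$value_reg), .data$value_reg,
      .data$value_ba * .data$dm_per_ha * carbon_fraction)) |>
    select("year", "value")

  list(regional = regional, national = annual_series(national),
       timelines = timelines)
}

#' Run the full pipeline on a synthetic-world configuration
#'
#' Chains the five stages — simulate (generate the world and render its
#' multi-source inputs), reconstruct (burned-area harmonisation),
#' burnbiomass (fuel-load x completeness conversion), balance (interval
#' carbon balances per geography) and sensitivity (factorial envelope) —
#' and returns every stage result plus a run manifest (config hash, seed,
#' stage list, diagnostics counts, emitted files). With `outdir` set, all
#' stage outputs are written as delimited text under it.
#'
#' @param config An [world_config()] object, or a path to a YAML file of
#'   [world_config()] arguments (see [read_run_config()]).
#' @param outdir Optional output directory; created if needed.
#' @param sensitivity Run the factorial sensitivity stage (default `TRUE`;
#'   disable for fast replicate studies that only need the central
#'   estimate).
#' @return An `fc_pipeline` list: `world`, `sources`, `reconstruction`,
#'   `burned`, `balances` (tibble over geographies), `sensitivity`,
#'   `envelope`, `recovery`, `manifest`.
#' @export
fc_run_pipeline <- function(config, outdir = NULL, sensitivity = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "fc_world_config"))
  cfg <- config
  emitted <- character()
  stage <- "simulate"
  result <- tryCatch({
    world <- generate_world(cfg)
    sources <- render_sources(world)

    stage <- "reconstruct"
    recon <- reconstruct_burned_area(
      sources[c("national_historical", "agency", "regional_totals",
                "landcover")],
      membership = cfg$membership, span = cfg$span,
      switch_year = cfg$switch_year,
      excluded_window = cfg$excluded_window,
      sp_cutoff = cfg$sp_cutoff, regional_start = cfg$regional_start,
      national_unit = "acres")

    stage <- "burnbiomass"
    burned <- estimate_burned_biomass(
      recon,
      fuel = c(sources[c("modeled_profile", "coefficients",
                         "completeness")],
               list(reference_period = cfg$reference_period)),
      region_weights = cfg$forest_area_ha,
      category_mix = cfg$category_shares,
      carbon_fraction = cfg$carbon_fraction)

    stage <- "balance"
    factors <- default_expansion_factors("central")
    balances <- map(c(region_codes(), "national"), function(g) {
      if (g == "national") {
        fire <- rename(burned$national, value_tc = "value")
        stem <- sources$harvest_stem |>
          group_by(.data$year) |>
          summarise(value_tc = sum(.data$value_tc), .groups = "drop")
        graz <- sources$grazing |>
          group_by(.data$year) |>
          summarise(value_tc = sum(.data$value_tc), .groups = "drop")
        breaks <- cfg$inventory_years
      } else {
        fire <- burned$regional |>
          filter(.data$region == g) |>
          select("year", value_tc = "value")
        stem <- sources$harvest_stem |>
          filter(.data$geography == g) |>
          select("year", value_tc = "value_tc")
        graz <- sources$grazing |>
          filter(.data$geography == g) |>
          select("year", value_tc = "value_tc")
        breaks <- cfg$inventory_years[cfg$inventory_years >=
                                        cfg$regional_start - 1L]
      }
      harvest <- expand_harvest(rename(stem, value = "value_tc"),
                                factors, cfg$fuelwood_share) |>
        rename(value_tc = "value")
      removals <- bind_rows(
        mutate(fire, component = "fire"),
        mutate(harvest, component = "harvest"),
        mutate(graz, component = "grazing"))
      code <- if (g == "national") "US" else g
      stocks <- filter(world$truth$stocks, .data$code == .env$code)
      balance_table(stocks, removals, breaks, geography = g)
    }) |> list_rbind()

    stage <- "sensitivity"
    sens <- if (!sensitivity) NULL else run_sensitivity(
      inputs = list(
        field_profile = sources$field_profile,
        modeled_profile = sources$modeled_profile,
        coefficients = sources$coefficients,
        severity = sources$severity,
        area = recon$regional,
        reference_period = cfg$reference_period),
      regions = region_codes(),
      carbon_fraction = cfg$carbon_fraction)
    env <- if (!sensitivity) NULL else {
      national_variants <- sens |>
        group_by(.data$fuel_source, .data$fuel_dynamics, .data$cc_mode,
                 .data$year) |>
        summarise(value = if (any(is.na(.data$value))) NA_real_ else
          sum(.data$value), .groups = "drop")
      envelope(national_variants,
               central = burned$national, component = "fire")
    }

    stage <- "report"
    recovery <- recovery_report(world, recon, burned = burned$regional,
                                balances = filter(balances,
                                                  .data$geography != "national"))

    list(world = world, sources = sources, reconstruction = recon,
         burned = burned, balances = balances, sensitivity = sens,
         envelope = env, recovery = recovery)
  }, error = function(e) {
    abort(paste0("pipeline failed in stage `", stage, "`: ",
                 conditionMessage(e)))
  })

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    emit <- function(df, name, schema = NULL) {
      path <- file.path(outdir, name)
      if (is.null(schema)) readr::write_csv(df, path, na = "")
      else write_records(df, path, schema)
      emitted <<- c(emitted, path)
    }
    emit(result$sources$agency, "sources_agency.csv", "burned_area")
    emit(result$sources$regional_totals, "sources_regional_totals.csv",
         "burned_area")
    emit(result$sources$landcover, "sources_landcover.csv", "landcover")
    emit(annual_series(result$sources$national_historical),
         "sources_national_historical_acres.csv", "annual_series")
    emit(result$reconstruction$national, "reconstruction_national.csv")
    emit(result$reconstruction$regional, "reconstruction_regional.csv")
    emit(result$reconstruction$diagnostics, "diagnostics.csv")
    emit(result$burned$regional, "burned_biomass_regional.csv")
    emit(result$burned$national, "burned_biomass_national.csv")
    emit(moving_average(result$burned$national, 5),
         "burned_biomass_national_ma5.csv")
    emit(result$balances, "balances.csv")
    if (!is.null(result$envelope)) {
      emit(as_tibble(result$envelope), "sensitivity_envelope_national.csv")
    }
    emit(result$recovery, "recovery_report.csv")
  }

  manifest <- structure(list(
    config_hash = digest::digest(unclass(cfg)),
    seed = cfg$seed,
    stages = c("simulate", "reconstruct", "burnbiomass", "balance",
               "sensitivity", "report"),
    outputs = emitted,
    diagnostics_count = nrow(result$reconstruction$diagnostics),
    identity_residual = max(abs(result$balances$nep -
      (result$balances$stock_change_rate + result$balances$fire +
         result$balances$harvest + result$balances$grazing)))
  ), class = "fc_manifest")
  result$manifest <- manifest
  structure(result, class = "fc_pipeline")
}

#' @export
print.fc_manifest <- function(x, ...) {
  cat("<fc_manifest> seed", x$seed, "hash", substr(x$config_hash, 1, 12),
      "\n  stages:", paste(x$stages, collapse = " -> "),
      "\n  outputs:", length(x$outputs), "files;",
      x$diagnostics_count, "diagnostic events\n")
  invisible(x)
}

#' Read a run configuration from a YAML file
#'
#' Scientific parameters live in a config file, not in flags: the file maps
#' directly onto [world_config()] arguments (`seed`, `span`, `membership`
#' as a list of `state: region` pairs, trend/noise/coverage parameters, and
#' so on). Unknown keys are an error.
#'
#' @param path YAML file path.
#' @return An `fc_world_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(world_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  to_named <- function(x) if (is.list(x)) unlist(x) else x
  for (key in c("fire_base", "underreporting", "forest_area_ha",
                "initial_density", "nep_start", "nep_end")) {
    if (!is.null(raw[[key]])) raw[[key]] <- to_named(raw[[key]])
  }
  if (!is.null(raw$membership)) {
    raw$membership <- tibble(state = names(raw$membership),
                             region = unlist(raw$membership))
  }
  if (!is.null(raw$category_shares)) {
    raw$category_shares <- map(raw$category_shares, to_named)
  }
  do.call(world_config, raw)
}
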