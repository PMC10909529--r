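#' Configuration of a synthetic study world
#'
#' Bundles every parameter of the seeded world generator: study span and
#' geography, trend and noise parameters of the true burned-area process,
#' the multi-source coverage model (which years each emulated source
#' reports, which categories it drops, reporting noise and category
#' underreporting), fuel-load and combustion-completeness processes, removal
#' trajectories, and the prescribed per-region NEP trajectory from which
#' stock densities are constructed so the balance identity holds exactly.
#'
#' The defaults describe a "paper-shaped" world: a 92-year span, four
#' regions dominated early by south-eastern state & private fires, strongly
#' declining burned area with a recent uptick, a mid-century harvest peak,
#' eastern stock recovery, agency reports that drop state & private coverage
#' after 1960, a regional-totals source ending in 1979, satellite class
#' tables from 1985, the 1980-1984 regional exclusion window and the listed
#' missing federal/other years. It is a structural emulation for smoke tests
#' and documentation, with no claim of reproducing real magnitudes.
#'
#' @param seed Integer seed (mandatory); all randomness derives from it via
#'   fixed per-component sub-seeds, so re-generating with one component's
#'   parameters changed leaves the other components' draws untouched.
#' @param span National study span `c(first, last)`.
#' @param membership State-to-region table.
#' @param regional_start First year of regional coverage.
#' @param switch_year First satellite year.
#' @param sp_cutoff Last year the agency source reports state & private.
#' @param totals_span Coverage of the regional-totals source.
#' @param excluded_window Regional years excluded from analysis (`NULL` for
#'   none).
#' @param missing_years Agency years with no federal/other_forest reports.
#' @param fire_base Named per-region burned area per state in the first year
#'   (ha/yr).
#' @param fire_decline Exponential decline rate of burned area per year.
#' @param fire_recovery Post-2000 exponential increase rate.
#' @param fire_sd Lognormal standard deviation of true year-to-year
#'   variation.
#' @param category_shares Per-region list of category shares of burned area
#'   (must each sum to 1).
#' @param reporting_noise_sd Lognormal sd of multiplicative reporting noise
#'   applied to rendered (not true) values; the factors have unit mean, so
#'   reporting is unbiased on average. Default 0 (sources consistent).
#' @param underreporting Named fractions in \[0, 1\) by category; reported
#'   values for that category are scaled by `1 - u` in every source.
#' @param forest_area_ha Named per-region constant forest area (ha).
#' @param initial_density Named per-region initial stock density (tC/ha).
#' @param nep_start,nep_end Named per-region prescribed NEP density at the
#'   span ends (tC/ha/yr); the trajectory is linear between them.
#' @param harvest_base,harvest_peak Stem-harvest density (tC/ha/yr):
#'   baseline plus a Gaussian mid-century bump (center 1965, width 25 yr).
#' @param grazing_start Initial grazing density (tC/ha/yr), decaying at 3%
#'   per year.
#' @param fuelwood_share Fuelwood fraction of stem harvest.
#' @param reference_period Reference years of the contemporary fuel loads.
#' @param carbon_fraction Carbon content of dry matter.
#' @param inventory_years Stock inventory years (default
#'   [default_breaks()]`("national")` clipped to the span).
#' @return An `fc_world_config` list.
#' @export
world_config <- function(seed,
                         span = c(1926L, 2017L),
                         membership = default_state_membership(),
                         regional_start = 1941L,
                         switch_year = 1985L,
                         sp_cutoff = 1960L,
                         totals_span = c(1938L, 1979L),
                         excluded_window = c(1980L, 1984L),
                         missing_years = c(1943L, 1944L, 1952L, 1953L,
                                           1957L, 1959L, 1967L, 1968L,
                                           1970L),
                         fire_base = c(NE = 3.5e5, SE = 2.3e6,
                                       RM = 5e5, PC = 4e5),
                         fire_decline = 0.05,
                         fire_recovery = 0.02,
                         fire_sd = 0.4,
                         category_shares = list(
                           NE = c(state_private = 0.95, federal = 0.03,
                                  other_forest = 0.02),
                           SE = c(state_private = 0.95, federal = 0.03,
                                  other_forest = 0.02),
                           RM = c(state_private = 0.50, federal = 0.35,
                                  other_forest = 0.15),
                           PC = c(state_private = 0.50, federal = 0.35,
                                  other_forest = 0.15)),
                         reporting_noise_sd = 0,
                         underreporting = c(state_private = 0,
                                            federal = 0,
                                            other_forest = 0),
                         forest_area_ha = c(NE = 7e7, SE = 8e7,
                                            RM = 6e7, PC = 4e7),
                         initial_density = c(NE = 25, SE = 20,
                                             RM = 30, PC = 40),
                         nep_start = c(NE = 1.0, SE = 1.3,
                                       RM = 0.7, PC = 1.1),
                         nep_end = c(NE = 1.8, SE = 2.4,
                                     RM = 0.9, PC = 1.3),
                         harvest_base = 0.18,
                         harvest_peak = 0.25,
                         grazing_start = 0.10,
                         fuelwood_share = 0.3,
                         reference_period = c(2003L, 2015L),
                         carbon_fraction = 0.5,
                         inventory_years = NULL) {
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory")
  seed <- as.integer(seed)
  span <- as.integer(span)
  validate_membership(membership)
  if (any(underreporting < 0 | underreporting >= 1)) {
    abort("underreporting fractions must lie in [0, 1)")
  }
  for (r in names(category_shares)) {
    if (abs(sum(category_shares[[r]]) - 1) > 1e-9) {
      abort(paste0("category shares for ", r, " must sum to 1"))
    }
  }
  inventory_years <- inventory_years %||%
    unique(pmin(pmax(default_breaks("national"), span[1]), span[2]))
  inventory_years <- sort(unique(as.integer(inventory_years)))
  if (length(inventory_years) < 2) {
    abort("need at least two inventory years inside the span")
  }
  if (min(inventory_years) < span[1] || max(inventory_years) > span[2]) {
    abort("inventory years must lie inside the span")
  }
  structure(list(
    seed = seed, span = span, membership = membership,
    regional_start = as.integer(regional_start),
    switch_year = as.integer(switch_year),
    sp_cutoff = as.integer(sp_cutoff),
    totals_span = as.integer(totals_span),
    excluded_window = if (is.null(excluded_window)) NULL
                      else as.integer(excluded_window),
    missing_years = as.integer(missing_years),
    fire_base = fire_base, fire_decline = fire_decline,
    fire_recovery = fire_recovery, fire_sd = fire_sd,
    category_shares = category_shares,
    reporting_noise_sd = reporting_noise_sd,
    underreporting = underreporting,
    forest_area_ha = forest_area_ha,
    initial_density = initial_density,
    nep_start = nep_start, nep_end = nep_end,
    harvest_base = harvest_base, harvest_peak = harvest_peak,
    grazing_start = grazing_start, fuelwood_share = fuelwood_share,
    reference_period = as.integer(reference_period),
    carbon_fraction = carbon_fraction,
    inventory_years = inventory_years
  ), class = "fc_world_config")
}

# fixed per-component sub-seed derivation (fire / fuels / removals / noise)
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483647)
}

with_sub_seed <- function(seed, k, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(sub_seed(seed, k))
  force(expr)
}

# smooth [0,1]-valued process: moving-averaged uniforms
smooth_unit <- function(n) {
  u <- runif(n + 4)
  stats::filter(u, rep(1 / 5, 5), sides = 2)[3:(n + 2)] |> as.double()
}

#' Default contemporary fuel-load profiles for the synthetic world
#'
#' Field-style compartment loads (t DM/ha) by region and category, with
#' heavier canopy and coarse-wood loads in the western regions and sparse
#' loads in "other forest". The modeled-source profile used by the
#' sensitivity design is a region-scaled variant of the field profile.
#'
#' @param source `"field_measured"` or `"modeled"`.
#' @return Fuel-profile tibble (`region, category, compartment,
#'   load_t_dm_ha`).
#' @export
default_fuel_profile <- function(source = c("field_measured", "modeled")) {
  source <- match.arg(source)
  base <- c(duff_litter = 15, dead_1hr = 0.5, dead_10hr = 1.5,
            dead_100hr = 3, dead_1000hr = 8, herb = 0.3, canopy = 45)
  sparse <- c(duff_litter = 4, dead_1hr = 0.4, dead_10hr = 0.6,
              dead_100hr = 0.8, dead_1000hr = 1.0, herb = 0.8, canopy = 6)
  region_factor <- c(NE = 0.9, SE = 0.8, RM = 1.1, PC = 1.4)
  source_factor <- if (source == "modeled") {
    c(NE = 0.92, SE = 1.05, RM = 0.88, PC = 0.95)
  } else c(NE = 1, SE = 1, RM = 1, PC = 1)
  rows <- expand_grid(region = region_codes(),
                      category = forest_categories(),
                      compartment = fuel_compartments())
  rows |>
    mutate(load_t_dm_ha = map_dbl(seq_len(n()), function(i) {
      comp <- rows$compartment[i]
      reg <- rows$region[i]
      lv <- if (rows$category[i] == "other_forest") sparse[[comp]]
            else base[[comp]]
      lv * region_factor[[reg]] * source_factor[[reg]]
    }))
}

#' Generate a complete synthetic world with known ground truth
#'
#' Draws the true burned-area process (declining trend with lognormal
#' year-to-year variation), fuel-dynamics coefficients and modeled
#' combustion completeness, harvest/grazing removal trajectories, and
#' constructs regional stock densities forward from the prescribed NEP
#' trajectory minus the generated removals — so the truth satisfies the
#' balance identity `NEP = dC + fire + harvest + grazing` exactly, before
#' any observation noise. Deterministic for a fixed config and seed.
#'
#' @param config An [world_config()] object.
#' @return An `fc_world` list with elements `config`, `truth` (burned area
#'   by state/category, regional and national series, fuel timeline, burned
#'   biomass, removals, stocks, prescribed NEP) and `fuel_inputs` (the fuel
#'   tables a pipeline run consumes).
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "fc_world_config"))
  cfg <- config
  years <- cfg$span[1]:cfg$span[2]
  ny <- length(years)
  regions <- region_codes()
  states <- cfg$membership

  # --- true burned area per state x category x year ------------------------
  trend <- exp(-cfg$fire_decline * pmin(years - cfg$span[1], 52)) *
    exp(cfg$fire_recovery * pmax(years - 2000, 0))
  ba <- with_sub_seed(cfg$seed, 1, {
    map(seq_len(nrow(states)), function(i) {
      st <- states$state[i]; reg <- states$region[i]
      shocks <- rlnorm(ny, meanlog = -cfg$fire_sd^2 / 2, sdlog = cfg$fire_sd)
      state_total <- cfg$fire_base[[reg]] * trend * shocks
      shares <- cfg$category_shares[[reg]]
      map(forest_categories(), function(cat) {
        tibble(state = st, region = reg, category = cat, year = years,
               area_ha = state_total * shares[[cat]])
      }) |> list_rbind()
    }) |> list_rbind()
  })

  regional_series <- ba |>
    group_by(.data$region, .data$category, .data$year) |>
    summarise(value = sum(.data$area_ha), .groups = "drop")
  national_series <- ba |>
    group_by(.data$year) |>
    summarise(value = sum(.data$area_ha), .groups = "drop")

  # --- fuel truth: coefficients, completeness, anchored timeline -----------
  field_profile <- default_fuel_profile("field_measured")
  modeled_profile <- default_fuel_profile("modeled")
  modeled_years <- cfg$regional_start:cfg$span[2]
  fuel_tables <- with_sub_seed(cfg$seed, 2, {
    coefficients <- map(regions, function(reg) {
      map(fuel_compartments(), function(comp) {
        wiggle <- 0.15 * sin(2 * pi * (modeled_years - modeled_years[1]) / 70)
        noise <- 0.05 * (smooth_unit(length(modeled_years)) - 0.5)
        tibble(region = reg, year = modeled_years, compartment = comp,
               coefficient = exp(wiggle + noise))
      }) |> list_rbind()
    }) |> list_rbind()
    moderate <- default_severity_completeness() |>
      filter(.data$severity == "moderate")
    completeness <- map(regions, function(reg) {
      map(fuel_compartments(), function(comp) {
        cc0 <- moderate$completeness[moderate$compartment == comp]
        u <- smooth_unit(length(modeled_years))
        tibble(region = reg, year = modeled_years, compartment = comp,
               completeness = pmin(pmax(cc0 * (0.8 + 0.4 * u), 0), 1))
      }) |> list_rbind()
    }) |> list_rbind()
    list(coefficients = coefficients, completeness = completeness)
  })

  # central-estimate fuel basis: modeled profile, per category, dynamic
  fuel_timeline <- map(regions, function(reg) {
    map(forest_categories(), function(cat) {
      tl <- build_fuel_timeline(
        base = modeled_profile |>
          filter(.data$region == reg, .data$category == cat) |>
          select("compartment", "load_t_dm_ha"),
        coefficients = filter(fuel_tables$coefficients,
                              .data$region == reg),
        completeness = filter(fuel_tables$completeness,
                              .data$region == reg),
        reference_period = cfg$reference_period)
      if (cfg$span[1] < min(tl$year)) {
        tl <- extrapolate_pre_span(tl, back_to = cfg$span[1])
      }
      mutate(tl, region = reg, category = cat, .before = 1)
    }) |> list_rbind()
  }) |> list_rbind()

  # --- true burned biomass per region (tC) ---------------------------------
  burned_biomass_truth <- map(regions, function(reg) {
    per_cat <- map(forest_categories(), function(cat) {
      tl <- fuel_timeline |>
        filter(.data$region == reg, .data$category == cat) |>
        select(-"region", -"category")
      area <- regional_series |>
        filter(.data$region == reg, .data$category == cat) |>
        select("year", "value")
      burned_biomass(area, tl, cat, cfg$carbon_fraction)
    }) |> list_rbind()
    per_cat |>
      group_by(.data$year) |>
      summarise(value = sum(.data$value), .groups = "drop") |>
      mutate(region = reg, .before = 1)
  }) |> list_rbind()

  # --- removal trajectories (per-area densities, then totals) --------------
  removals <- with_sub_seed(cfg$seed, 3, {
    map(regions, function(reg) {
      area <- cfg$forest_area_ha[[reg]]
      harvest_density <- cfg$harvest_base +
        cfg$harvest_peak * exp(-((years - 1965) / 25)^2) *
          (0.9 + 0.2 * smooth_unit(ny))
      grazing_density <- cfg$grazing_start *
        exp(-0.03 * (years - cfg$span[1]))
      fire_total <- burned_biomass_truth |>
        filter(.data$region == reg) |>
        pull("value")
      bind_rows(
        tibble(geography = reg, component = "harvest_stem", year = years,
               value_tc = harvest_density * area),
        tibble(geography = reg, component = "grazing", year = years,
               value_tc = grazing_density * area),
        tibble(geography = reg, component = "fire", year = years,
               value_tc = fire_total)
      )
    }) |> list_rbind()
  })

  # expanded harvest truth (central factors)
  factors <- default_expansion_factors("central")
  harvest_expanded <- removals |>
    filter(.data$component == "harvest_stem") |>
    group_by(.data$geography) |>
    group_split() |>
    map(function(df) {
      expand_harvest(select(df, "year", value = "value_tc"), factors,
                     cfg$fuelwood_share) |>
        mutate(geography = df$geography[1], component = "harvest",
               value_tc = .data$value, .keep = "unused")
    }) |>
    list_rbind() |>
    select("geography", "component", "year", "value_tc")
  removals <- bind_rows(removals, harvest_expanded)

  # --- prescribed NEP and constructed stock densities ----------------------
  frac <- (years - cfg$span[1]) / (cfg$span[2] - cfg$span[1])
  nep <- map(regions, function(reg) {
    tibble(region = reg, year = years,
           nep_tc_ha_yr = cfg$nep_start[[reg]] +
             (cfg$nep_end[[reg]] - cfg$nep_start[[reg]]) * frac)
  }) |> list_rbind()

  stocks <- map(regions, function(reg) {
    area <- cfg$forest_area_ha[[reg]]
    removal_density <- removals |>
      filter(.data$geography == reg,
             .data$component %in% c("fire", "harvest", "grazing")) |>
      group_by(.data$year) |>
      summarise(r = sum(.data$value_tc) / area, .groups = "drop") |>
      pull("r")
    nep_r <- nep$nep_tc_ha_yr[nep$region == reg]
    # density(y) - density(y-1) = nep(y) - removals(y); flux year y belongs
    # to the interval (y-1, y]
    density <- cfg$initial_density[[reg]] +
      cumsum(c(0, (nep_r - removal_density)[-1]))
    if (any(density < 0)) {
      abort(paste0("constructed stock density fell below zero in ", reg,
                   "; choose a larger initial_density or NEP"))
    }
    tibble(time = years, level = "region", code = reg,
           forest_area_ha = area, stock_density_tc_ha = density,
           total_stock_tc = area * density)
  }) |> list_rbind()

  national_area <- sum(cfg$forest_area_ha)
  national_stocks <- stocks |>
    group_by(.data$time) |>
    summarise(total_stock_tc = sum(.data$total_stock_tc), .groups = "drop") |>
    mutate(level = "national", code = "US",
           forest_area_ha = national_area,
           stock_density_tc_ha = .data$total_stock_tc / national_area) |>
    select("time", "level", "code", "forest_area_ha",
           "stock_density_tc_ha", "total_stock_tc")
  national_removals <- removals |>
    group_by(.data$component, .data$year) |>
    summarise(value_tc = sum(.data$value_tc), .groups = "drop") |>
    mutate(geography = "national", .before = 1)
  national_nep <- nep |>
    left_join(tibble(region = names(cfg$forest_area_ha),
                     w = unname(cfg$forest_area_ha)), by = "region") |>
    group_by(.data$year) |>
    summarise(nep_tc_ha_yr = sum(.data$nep_tc_ha_yr * .data$w) / sum(.data$w),
              .groups = "drop") |>
    mutate(region = "national", .before = 1)

  inventory <- bind_rows(stocks, national_stocks) |>
    filter(.data$time %in% cfg$inventory_years)

  structure(list(
    config = cfg,
    truth = list(
      burned_area = ba,
      national_series = national_series,
      regional_series = regional_series,
      fuel_timeline = fuel_timeline,
      burned_biomass = burned_biomass_truth,
      removals = bind_rows(removals, national_removals),
      nep = bind_rows(nep, national_nep),
      stocks_annual = bind_rows(stocks, national_stocks),
      stocks = inventory
    ),
    fuel_inputs = list(
      field_profile = field_profile,
      modeled_profile = modeled_profile,
      coefficients = fuel_tables$coefficients,
      completeness = fuel_tables$completeness,
      severity = default_severity_completeness(),
      reference_period = cfg$reference_period
    )
  ), class = "fc_world")
}

#' @export
print.fc_world <- function(x, ...) {
  cat("<fc_world> span", paste(x$config$span, collapse = "-"),
      "| seed", x$config$seed, "\n")
  cat("  truth series:", length(x$truth), "tables;",
      nrow(x$truth$burned_area), "burned-area rows\n")
  invisible(x)
}

#' Render a world into the multi-source input tables
#'
#' Applies the coverage model (source spans, discontinued categories,
#' missing years), per-category underreporting and multiplicative reporting
#' noise to the truth and emits the tables the reconstruction consumes:
#' a national historical series (in acres, like census-era statistics),
#' state-level agency records, a regional-totals source, and a
#' satellite-style land-cover class table. With zero noise, zero
#' underreporting and full coverage the rendered sources are mutually
#' consistent and the reconstruction recovers the truth exactly.
#'
#' @param world An `fc_world` object.
#' @return Named list of tibbles: `national_historical` (annual series,
#'   acres), `agency` and `regional_totals` (schema `burned_area`),
#'   `landcover` (schema `landcover`), plus `harvest_stem`, `grazing`
#'   (schema `removal_series` shaped), `stocks` (schema `stock_points`) and
#'   the fuel tables.
#' @export
render_sources <- function(world) {
  stopifnot(inherits(world, "fc_world"))
  cfg <- world$config
  under <- cfg$underreporting
  noise_factor <- function(n, k) {
    if (cfg$reporting_noise_sd <= 0) return(rep(1, n))
    with_sub_seed(cfg$seed, 100 + k,
                  rlnorm(n, meanlog = -cfg$reporting_noise_sd^2 / 2,
                         sdlog = cfg$reporting_noise_sd))
  }
  reported <- world$truth$burned_area |>
    mutate(area_ha = .data$area_ha *
             (1 - unname(under[.data$category])))

  # (i) national historical series, full early coverage, in acres
  nat <- reported |>
    filter(.data$year <= cfg$switch_year - 1L) |>
    group_by(.data$year) |>
    summarise(value = sum(.data$area_ha), .groups = "drop")
  nat$value <- nat$value * noise_factor(nrow(nat), 1) / ACRE_TO_HA

  # (ii) state-level agency records; state & private discontinued after the
  # cutoff, federal/other absent in the listed missing years
  agency <- reported |>
    filter(.data$year >= cfg$regional_start,
           .data$year <= cfg$switch_year - 1L) |>
    filter(!(.data$category == "state_private" &
               .data$year > cfg$sp_cutoff)) |>
    filter(!(.data$category %in% c("federal", "other_forest") &
               .data$year %in% cfg$missing_years))
  agency <- agency |>
    mutate(area_ha = .data$area_ha * noise_factor(nrow(agency), 2),
           level = "state", code = .data$state,
           protection = "unspecified", source = "usfs_reports") |>
    select("year", "level", "code", "category", "protection", "area_ha",
           "source")

  # (iii) regional totals source (total forest ecosystems)
  totals <- reported |>
    filter(.data$year >= cfg$totals_span[1],
           .data$year <= cfg$totals_span[2]) |>
    group_by(.data$region, .data$year) |>
    summarise(area_ha = sum(.data$area_ha), .groups = "drop")
  totals <- totals |>
    mutate(area_ha = .data$area_ha * noise_factor(nrow(totals), 3),
           level = "region", code = .data$region, category = "total",
           protection = "unspecified", source = "regional_totals") |>
    select("year", "level", "code", "category", "protection", "area_ha",
           "source")

  # (iv) satellite class table from the switch year; forest classes split by
  # fixed fractions and intersected ownership, shrub = other forest, plus an
  # excluded herbaceous class
  class_fracs <- c(deciduous = 0.4, evergreen = 0.45, mixed = 0.15)
  sat <- reported |> filter(.data$year >= cfg$switch_year)
  forest_part <- sat |>
    filter(.data$category %in% c("state_private", "federal"))
  forest_rows <- map(names(class_fracs), function(cl) {
    forest_part |>
      mutate(class = cl, ownership = .data$category,
             area_ha = .data$area_ha * class_fracs[[cl]]) |>
      select("year", "state", "class", "ownership", "area_ha")
  }) |> list_rbind()
  shrub_rows <- sat |>
    filter(.data$category == "other_forest") |>
    mutate(class = "shrub_scrub", ownership = "aggregated") |>
    select("year", "state", "class", "ownership", "area_ha")
  herb_rows <- sat |>
    filter(.data$category == "other_forest") |>
    mutate(class = "herbaceous", ownership = "aggregated",
           area_ha = 0.2 * .data$area_ha) |>
    select("year", "state", "class", "ownership", "area_ha")
  landcover <- bind_rows(forest_rows, shrub_rows, herb_rows)
  landcover$area_ha <- landcover$area_ha * noise_factor(nrow(landcover), 4)
  landcover <- arrange(landcover, .data$year, .data$state, .data$class,
                       .data$ownership)

  harvest_stem <- world$truth$removals |>
    filter(.data$component == "harvest_stem",
           .data$geography %in% region_codes())
  grazing <- world$truth$removals |>
    filter(.data$component == "grazing",
           .data$geography %in% region_codes())

  list(
    national_historical = nat,
    agency = agency,
    regional_totals = totals,
    landcover = landcover,
    harvest_stem = harvest_stem,
    grazing = grazing,
    stocks = world$truth$stocks,
    field_profile = world$fuel_inputs$field_profile,
    modeled_profile = world$fuel_inputs$modeled_profile,
    coefficients = world$fuel_inputs$coefficients,
    completeness = world$fuel_inputs$completeness,
    severity = world$fuel_inputs$severity
  )
}

#' Error metrics of a pipeline run against the generating truth
#'
#' Compares reconstructed burned area (national and regional totals),
#' burned biomass and recovered interval NEP against the world's ground
#' truth, reporting RMSE and mean bias per series. Years that are gaps in
#' the reconstruction are excluded (they carry no estimate).
#'
#' @param world The `fc_world` the sources were rendered from.
#' @param recon An `fc_reconstruction` from the rendered sources.
#' @param burned An optional tibble `region, year, value` of estimated
#'   burned biomass (tC).
#' @param balances An optional tibble of balance rows with a `geography`
#'   column, compared against the prescribed interval NEP.
#' @return Tibble `series, n, rmse, bias`.
#' @export
recovery_report <- function(world, recon, burned = NULL, balances = NULL) {
  stopifnot(inherits(world, "fc_world"), inherits(recon, "fc_reconstruction"))
  metrics <- function(est, truth) {
    d <- est - truth
    d <- d[!is.na(d)]
    tibble(n = length(d),
           rmse = if (length(d)) sqrt(mean(d^2)) else NA_real_,
           bias = if (length(d)) mean(d) else NA_real_)
  }
  rows <- list()

  nat <- recon$national |>
    left_join(world$truth$national_series, by = "year",
              suffix = c("_est", "_truth"))
  rows$national_burned_area <- metrics(nat$value_est, nat$value_truth)

  reg <- recon$regional |>
    group_by(.data$region, .data$year) |>
    summarise(value = if (all(is.na(.data$value))) NA_real_ else
      sum(.data$value, na.rm = TRUE), .groups = "drop") |>
    left_join(
      world$truth$regional_series |>
        group_by(.data$region, .data$year) |>
        summarise(truth = sum(.data$value), .groups = "drop"),
      by = c("region", "year"))
  rows$regional_burned_area <- metrics(reg$value, reg$truth)

  if (!is.null(burned)) {
    bb <- burned |>
      left_join(rename(world$truth$burned_biomass, truth = "value"),
                by = c("region", "year"))
    rows$burned_biomass <- metrics(bb$value, bb$truth)
  }

  if (!is.null(balances)) {
    truth_nep <- world$truth$nep
    bal <- as_tibble(balances) |>
      mutate(prescribed = map_dbl(seq_len(n()), function(i) {
        g <- balances$geography[i]
        yrs <- (balances$t0[i] + 1L):balances$t1[i]
        mean(truth_nep$nep_tc_ha_yr[truth_nep$region == g &
                                      truth_nep$year %in% yrs])
      }))
    rows$interval_nep <- metrics(bal$nep, bal$prescribed)
  }

  imap(rows, function(m, nm) mutate(m, series = nm, .before = 1)) |>
    list_rbind()
}
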