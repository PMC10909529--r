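#' Expand harvested stem carbon to total biomass destroyed
#'
#' Harvest statistics report extracted stem volume; the biomass actually
#' removed from the forest also includes bark, branches, twigs, leaves and
#' belowground biomass. Expansion factors convert stems to whole-tree
#' biomass: `total = stem * (1 + bark + crown) * (1 + root_shoot)`, applied
#' separately to fuelwood and industrial wood with class-specific ratios and
#' combined via the annual fuelwood share of the product mix.
#'
#' @param stem Annual series of harvested stem carbon (tC/yr).
#' @param factors A list (or data frame) with elements `fuelwood` and
#'   `industrial`, each a list with numeric `bark`, `crown`, `root_shoot`
#'   ratios (all `>= 0`). See [default_expansion_factors()].
#' @param fuelwood_share Either a single number in \[0, 1\] or an annual
#'   series of the fuelwood fraction of harvest.
#' @return Annual-series tibble of expanded harvest removals (tC/yr).
#' @export
#' @examples
#' s <- annual_series(2000:2001, c(100, 100))
#' f <- list(fuelwood = list(bark = 0.1, crown = 0.2, root_shoot = 0.25),
#'           industrial = list(bark = 0.1, crown = 0.2, root_shoot = 0.25))
#' expand_harvest(s, f, fuelwood_share = 0.3)   # 100 * 1.3 * 1.25 = 162.5
expand_harvest <- function(stem, factors, fuelwood_share = 0.5) {
  stem <- annual_series(stem)
  check_nonnegative(stem$value, "stem")
  for (cls in c("fuelwood", "industrial")) {
    f <- factors[[cls]]
    if (is.null(f) ||
        !all(c("bark", "crown", "root_shoot") %in% names(f))) {
      abort(paste0("`factors$", cls,
                   "` needs numeric bark, crown, root_shoot"))
    }
    check_nonnegative(unlist(f[c("bark", "crown", "root_shoot")]),
                      paste0("factors$", cls))
  }
  if (is.data.frame(fuelwood_share)) {
    share <- annual_series(fuelwood_share)
    joined <- left_join(stem, share, by = "year",
                        suffix = c("", "_share"))
    share_vec <- joined$value_share
  } else {
    share_vec <- rep(fuelwood_share, nrow(stem))
  }
  if (any(share_vec < 0 | share_vec > 1, na.rm = TRUE)) {
    abort("fuelwood share must lie in [0, 1]")
  }
  mult <- function(f) (1 + f$bark + f$crown) * (1 + f$root_shoot)
  m_fw <- mult(factors$fuelwood)
  m_iw <- mult(factors$industrial)
  tibble(year = stem$year,
         value = stem$value * (share_vec * m_fw + (1 - share_vec) * m_iw))
}

#' Central, minimum and maximum biomass expansion factors
#'
#' Plausible U.S. whole-tree expansion ratios (bark, crown = twigs/leaves,
#' root:shoot) for fuelwood and industrial roundwood, with the min/max
#' variants used by the harvest sensitivity range. Each ratio satisfies
#' `min <= central <= max`.
#'
#' @param variant `"central"`, `"min"` or `"max"`.
#' @return A list with elements `fuelwood` and `industrial`.
#' @export
default_expansion_factors <- function(variant = c("central", "min", "max")) {
  variant <- match.arg(variant)
  pick <- function(lo, mid, hi) switch(variant, min = lo, central = mid,
                                       max = hi)
  list(
    fuelwood = list(bark = pick(0.08, 0.12, 0.18),
                    crown = pick(0.10, 0.20, 0.35),
                    root_shoot = pick(0.18, 0.25, 0.32)),
    industrial = list(bark = pick(0.07, 0.11, 0.16),
                      crown = pick(0.15, 0.25, 0.40),
                      root_shoot = pick(0.18, 0.24, 0.30))
  )
}

#' Express a total annual flux per hectare of forest
#'
#' All balance components are compared per unit forest area (tC/ha/yr), so
#' that pressures on differently sized regions are commensurable.
#'
#' @param total Annual series (tC/yr) or numeric vector.
#' @param denominator_area Forest area in hectares (scalar or vector matching
#'   `total`); must be strictly positive.
#' @return Same shape as `total`, in tC/ha/yr.
#' @export
per_area_flux <- function(total, denominator_area) {
  if (any(denominator_area <= 0, na.rm = TRUE) ||
      anyNA(denominator_area)) {
    abort("`denominator_area` must be > 0")
  }
  if (is.data.frame(total)) {
    total <- annual_series(total)
    total$value <- total$value / denominator_area
    total
  } else {
    total / denominator_area
  }
}

#' Carbon balance of one inventory interval
#'
#' The bookkeeping identity at the heart of the analysis: over an interval
#' `[t0, t1]` bounded by forest inventories, the net-ecosystem-productivity
#' proxy is the observed change in biomass carbon stock density plus every
#' quantified removal,
#' `NEP = dC + fire + harvest + grazing` (tC/ha/yr).
#' Stock-change rate is the density difference divided by the interval
#' length; each removal term is the mean annual per-area flux over the years
#' `(t0, t1]`, skipping gap years. Negative stock change (net loss) is
#' permitted and signals disturbances beyond the quantified removals.
#'
#' @param stocks Stock-point tibble (schema `stock_points`) containing rows
#'   at `t0` and `t1` for one geography.
#' @param removals Removal series tibble with columns `component`
#'   (`fire`/`harvest`/`grazing`), `year`, `value_tc` (tC/yr, total).
#' @param t0,t1 Interval endpoint years (`t1 > t0`), closed on both ends.
#' @param denominator One of `"mean"`, `"start"`, `"end"`: which inventory
#'   forest area normalises the fluxes (default mean of the two endpoints).
#' @return One-row tibble with `t0, t1, stock_change_rate, fire, harvest,
#'   grazing, nep, denominator_area`.
#' @export
interval_balance <- function(stocks, removals, t0, t1,
                             denominator = c("mean", "start", "end")) {
  denominator <- match.arg(denominator)
  t0 <- as.integer(t0); t1 <- as.integer(t1)
  if (t1 <= t0) abort("`t1` must exceed `t0`")
  stocks <- as_tibble(stocks)
  s0 <- filter(stocks, .data$time == t0)
  s1 <- filter(stocks, .data$time == t1)
  if (nrow(s0) != 1 || nrow(s1) != 1) {
    abort(paste0("need exactly one stock point at each of ", t0, " and ", t1))
  }
  area <- switch(denominator,
                 start = s0$forest_area_ha,
                 end = s1$forest_area_ha,
                 mean = (s0$forest_area_ha + s1$forest_area_ha) / 2)
  dC <- (s1$stock_density_tc_ha - s0$stock_density_tc_ha) / (t1 - t0)
  yrs <- (t0 + 1L):t1
  comp_mean <- function(comp) {
    v <- removals |>
      filter(.data$component == comp, .data$year %in% yrs) |>
      pull("value_tc")
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      abort(paste0("removal component `", comp,
                   "` has no non-gap year in (", t0, ", ", t1, "]"))
    }
    mean(v) / area
  }
  fire <- comp_mean("fire")
  harvest <- comp_mean("harvest")
  grazing <- comp_mean("grazing")
  tibble(t0 = t0, t1 = t1,
         stock_change_rate = dC,
         fire = fire, harvest = harvest, grazing = grazing,
         nep = dC + fire + harvest + grazing,
         denominator_area = area)
}

#' Balance table over a sequence of intervals
#'
#' Applies [interval_balance()] to each consecutive pair of break years
#' (decadal by default, with the study's irregular early and 1970s
#' intervals) and returns an `fc_balance` object with [tidy()], [glance()]
#' and [autoplot()] methods.
#'
#' @inheritParams interval_balance
#' @param breaks Increasing vector of interval endpoint years.
#' @param geography Label stored on the result.
#' @return An `fc_balance` object (tibble of intervals plus metadata).
#' @export
balance_table <- function(stocks, removals, breaks,
                          geography = "national",
                          denominator = c("mean", "start", "end")) {
  denominator <- match.arg(denominator)
  breaks <- sort(as.integer(unique(breaks)))
  if (length(breaks) < 2) abort("need at least two break years")
  rows <- map2(head(breaks, -1), tail(breaks, -1),
               function(a, b) interval_balance(stocks, removals, a, b,
                                               denominator)) |>
    list_rbind()
  structure(mutate(rows, geography = geography, .before = 1),
            class = c("fc_balance", class(rows)),
            denominator = denominator)
}

#' Default interval break years
#'
#' Decadal intervals with the study's exceptions: the short first national
#' interval 1926-1930 and the 1970-1977 interval at all scales (inventory
#' timing). The regional series starts in 1940.
#'
#' @param scale `"national"` or `"regional"`.
#' @return Integer vector of break years.
#' @export
default_breaks <- function(scale = c("national", "regional")) {
  scale <- match.arg(scale)
  common <- c(1940L, 1950L, 1960L, 1970L, 1977L, 1987L, 1997L, 2007L, 2017L)
  if (scale == "national") c(1926L, 1930L, common) else common
}

#' Duration-weighted average of balance intervals
#'
#' Averages each balance component over intervals, weighting by interval
#' length so that the average preserves the NEP identity exactly (the
#' weighted mean is linear in the components).
#'
#' @param intervals An `fc_balance` object or tibble of balance rows for one
#'   geography.
#' @return A one-row tibble with the same columns, `t0`/`t1` spanning the
#'   whole period.
#' @export
period_average_balance <- function(intervals) {
  intervals <- as_tibble(intervals)
  if (nrow(intervals) < 1) abort("need at least one interval")
  if ("geography" %in% names(intervals) &&
      length(unique(intervals$geography)) > 1) {
    abort("intervals mix geographies; average one geography at a time")
  }
  w <- intervals$t1 - intervals$t0
  avg <- function(x) weighted.mean(x, w)
  out <- tibble(
    t0 = min(intervals$t0), t1 = max(intervals$t1),
    stock_change_rate = avg(intervals$stock_change_rate),
    fire = avg(intervals$fire),
    harvest = avg(intervals$harvest),
    grazing = avg(intervals$grazing),
    nep = avg(intervals$nep),
    denominator_area = avg(intervals$denominator_area)
  )
  if ("geography" %in% names(intervals)) {
    out <- mutate(out, geography = intervals$geography[1], .before = 1)
  }
  out
}

#' Share of cumulative NEP offset by each removal component
#'
#' Integrates each component over the intervals (flux x duration) and
#' expresses it as a percentage of cumulative NEP. The removal shares plus
#' the stock-change share sum to 100%: every unit of NEP either stayed in
#' the forest or left through a quantified removal.
#'
#' @param intervals Balance rows for one geography.
#' @return Tibble `component, share_pct` for fire, harvest, grazing and
#'   stock_change.
#' @export
cumulative_offsets <- function(intervals) {
  intervals <- as_tibble(intervals)
  w <- intervals$t1 - intervals$t0
  cum_nep <- sum(intervals$nep * w)
  if (cum_nep <= 0) abort("cumulative NEP must be positive")
  share <- function(x) 100 * sum(x * w) / cum_nep
  tibble(
    component = c("fire", "harvest", "grazing", "stock_change"),
    share_pct = c(share(intervals$fire), share(intervals$harvest),
                  share(intervals$grazing),
                  share(intervals$stock_change_rate))
  )
}

#' @export
tidy.fc_balance <- function(x, ...) {
  as_tibble(x) |>
    pivot_longer(c("stock_change_rate", "fire", "harvest", "grazing", "nep"),
                 names_to = "component", values_to = "flux_tc_ha_yr")
}

#' @export
glance.fc_balance <- function(x, ...) {
  avg <- period_average_balance(x)
  tibble(
    geography = if ("geography" %in% names(avg)) avg$geography else NA,
    n_intervals = nrow(x),
    t0 = avg$t0, t1 = avg$t1,
    mean_nep = avg$nep,
    mean_stock_change = avg$stock_change_rate,
    mean_fire = avg$fire,
    mean_harvest = avg$harvest,
    mean_grazing = avg$grazing,
    max_identity_residual = max(abs(x$nep - (x$stock_change_rate +
      x$fire + x$harvest + x$grazing)))
  )
}

#' @export
autoplot.fc_balance <- function(object, ...) {
  long <- tidy(object) |>
    mutate(mid = (.data$t0 + .data$t1) / 2,
           flux = if_else(.data$component %in%
                            c("fire", "harvest", "grazing"),
                          -.data$flux_tc_ha_yr, .data$flux_tc_ha_yr))
  ggplot2::ggplot(filter(long, .data$component != "nep"),
                  ggplot2::aes(x = .data$mid, y = .data$flux,
                               fill = .data$component)) +
    ggplot2::geom_col(position = "stack",
                      ggplot2::aes(width = .data$t1 - .data$t0 - 1)) +
    ggplot2::geom_point(data = filter(long, .data$component == "nep"),
                        ggplot2::aes(y = .data$flux_tc_ha_yr), fill = NA) +
    ggplot2::labs(x = "Year", y = "Flux (tC/ha/yr)",
                  title = "Forest carbon balance by interval",
                  subtitle = "bars: stock change and removals; points: NEP") +
    ggplot2::theme_minimal()
}
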