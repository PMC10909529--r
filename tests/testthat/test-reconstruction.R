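test_that("national splice takes history before and satellite after the seam", {
  hist <- annual_series(1983:1984, c(4, 5))
  sat <- annual_series(1985:1986, c(1, 2))
  out <- splice_national(hist, sat, 1985)
  expect_equal(out$value, c(4, 5, 1, 2))
  expect_identical(out$source, c("historical", "historical",
                                 "satellite", "satellite"))

  # satellite authoritative on overlap years; overlap logged, not averaged
  hist2 <- annual_series(1983:1985, c(4, 5, 99))
  out2 <- splice_national(hist2, sat, 1985)
  expect_equal(out2$value[out2$year == 1985], 1)
  expect_identical(attr(out2, "diagnostics")$year, 1985L)

  # gap at the seam is an error listing the missing years
  expect_error(splice_national(annual_series(1983, 4), sat, 1985), "1984")
})

test_that("state aggregation sums members and keeps all-missing years as gaps", {
  mk <- function(code, year, cat, area) {
    tibble::tibble(year = year, level = "state", code = code,
                   category = cat, protection = "unspecified",
                   area_ha = area, source = "t")
  }
  recs <- dplyr::bind_rows(
    mk("SE1", 1950L, "federal", 3), mk("SE2", 1950L, "federal", 4),
    mk("NE1", 1950L, "federal", 10))
  agg <- aggregate_states_to_regions(recs, default_state_membership())
  expect_equal(agg$value[agg$region == "SE" & agg$category == "federal"], 7)

  # permuting the record order changes nothing
  agg2 <- aggregate_states_to_regions(recs[c(3, 1, 2), ],
                                      default_state_membership())
  expect_equal(agg, agg2)

  # a year with no member-state report is a gap
  agg3 <- aggregate_states_to_regions(recs, default_state_membership(),
                                      span = c(1950L, 1951L))
  expect_true(is.na(agg3$value[agg3$region == "SE" & agg3$year == 1951L][1]))

  expect_error(
    aggregate_states_to_regions(mk("XX9", 1950L, "federal", 1),
                                default_state_membership()),
    "XX9")
})

test_that("state & private inference subtracts, clamps and logs", {
  total <- annual_series(1961:1963, c(100, 50, NA))
  covered <- annual_series(1961:1963, c(60, 55, 10))
  inf <- infer_missing_state_private(total, covered)
  expect_equal(inf$value, c(40, 0, NA))
  d <- attr(inf, "diagnostics")
  expect_identical(d$year, 1962L)
  expect_true(all(inf$value >= 0, na.rm = TRUE))
})

test_that("land-cover aggregation maps classes and reports exclusions", {
  lc <- tibble::tibble(
    year = 1990L, state = "PC1",
    class = c("deciduous", "evergreen", "mixed", "shrub_scrub",
              "herbaceous"),
    ownership = c("state_private", "state_private", "state_private",
                  "aggregated", "aggregated"),
    area_ha = c(2, 3, 1, 4, 9))
  recs <- aggregate_landcover_classes(lc)
  expect_equal(recs$area_ha[recs$category == "state_private"], 6)
  expect_equal(recs$area_ha[recs$category == "other_forest"], 4)
  expect_false("herbaceous" %in% recs$category)
  expect_equal(attr(recs, "excluded_area")$total_area_ha, 9)

  lc_bad <- dplyr::mutate(lc, class = sub("herbaceous", "wetland", class))
  expect_error(aggregate_landcover_classes(lc_bad), "wetland")
})

test_that("complete noise-free sources reconstruct the truth exactly", {
  world <- generate_world(complete_config(101))
  src <- render_sources(world)
  recon <- reconstruct_burned_area(
    src[c("national_historical", "agency", "regional_totals", "landcover")],
    span = world$config$span, switch_year = world$config$switch_year,
    excluded_window = NULL, sp_cutoff = world$config$sp_cutoff,
    regional_start = world$config$regional_start)

  nat <- dplyr::left_join(recon$national, world$truth$national_series,
                          by = "year", suffix = c("_est", "_truth"))
  expect_lt(max(abs(nat$value_est - nat$value_truth)), 1e-9)

  reg <- dplyr::left_join(
    recon$regional,
    dplyr::rename(world$truth$regional_series, truth = value),
    by = c("region", "category", "year"))
  expect_false(anyNA(reg$value))
  expect_lt(max(abs(reg$value - reg$truth)), 1e-9)
})

test_that("regional totals are conserved across categories", {
  world <- generate_world(complete_config(102))
  src <- render_sources(world)
  recon <- reconstruct_burned_area(
    src[c("national_historical", "agency", "regional_totals", "landcover")],
    span = world$config$span, switch_year = world$config$switch_year,
    excluded_window = NULL, sp_cutoff = world$config$sp_cutoff,
    regional_start = world$config$regional_start)
  wide <- tidyr::pivot_wider(recon$regional, names_from = "category",
                             values_from = "value")
  total <- wide$state_private + wide$federal + wide$other_forest
  truth <- world$truth$regional_series |>
    dplyr::group_by(region, year) |>
    dplyr::summarise(truth = sum(value), .groups = "drop")
  joined <- dplyr::left_join(
    dplyr::mutate(wide, total = total), truth, by = c("region", "year"))
  expect_lt(max(abs(joined$total - joined$truth)), 1e-9)
})

test_that("category underreporting produces exactly the expected deficit", {
  u <- 0.3
  world <- generate_world(complete_config(
    103, underreporting = c(state_private = 0, federal = u,
                            other_forest = 0)))
  src <- render_sources(world)
  recon <- reconstruct_burned_area(
    src[c("national_historical", "agency", "regional_totals", "landcover")],
    span = world$config$span, switch_year = world$config$switch_year,
    excluded_window = NULL, sp_cutoff = world$config$sp_cutoff,
    regional_start = world$config$regional_start)
  reg <- dplyr::left_join(
    recon$regional,
    dplyr::rename(world$truth$regional_series, truth = value),
    by = c("region", "category", "year"))
  expect_true(all(reg$value <= reg$truth + 1e-9))
  fed <- dplyr::filter(reg, category == "federal")
  expect_lt(max(abs((fed$truth - fed$value) - u * fed$truth)), 1e-9)
  other <- dplyr::filter(reg, category != "federal")
  expect_lt(max(abs(other$truth - other$value)), 1e-9)
})
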