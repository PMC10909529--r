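prof <- tibble::tibble(
  compartment = fuel_compartments(),
  load_t_dm_ha = c(5, 1, 1.5, 3, 8, 0.5, 20))

test_that("fuel allocation filters compartments by forest category", {
  sparse <- allocate_fuels(prof, "other_forest")
  expect_setequal(sparse$compartment, c("duff_litter", "dead_1hr", "herb"))
  expect_equal(allocate_fuels(prof, "federal"), prof)
  expect_equal(allocate_fuels(prof, "state_private"), prof)
  expect_lte(sum(sparse$load_t_dm_ha), sum(prof$load_t_dm_ha))
  expect_error(allocate_fuels(prof, "wetland"), "unknown forest category")
})

mk_coefs <- function(years, value = 1) {
  tidyr::expand_grid(year = years, compartment = prof$compartment) |>
    dplyr::mutate(coefficient = value)
}
mk_cc <- function(years, value = 0.4) {
  tidyr::expand_grid(year = years, compartment = prof$compartment) |>
    dplyr::mutate(completeness = value)
}

test_that("fuel timeline scales the base by anchored coefficients", {
  years <- 1941:1960
  tl <- build_fuel_timeline(prof, mk_coefs(years), mk_cc(years),
                            reference_period = c(1950, 1955))
  joined <- dplyr::left_join(tl, prof, by = "compartment",
                             suffix = c("", "_base"))
  expect_equal(joined$load_t_dm_ha, joined$load_t_dm_ha_base)

  co <- mk_coefs(years) |>
    dplyr::mutate(coefficient = ifelse(year == 1941, 1.1, 1))
  tl2 <- build_fuel_timeline(prof, co, mk_cc(years),
                             reference_period = c(1950, 1955))
  bumped <- dplyr::filter(tl2, year == 1941) |>
    dplyr::left_join(prof, by = "compartment", suffix = c("", "_base"))
  expect_equal(bumped$load_t_dm_ha, 1.1 * bumped$load_t_dm_ha_base)

  expect_error(
    build_fuel_timeline(prof, dplyr::mutate(mk_coefs(years), coefficient = 0),
                        mk_cc(years)),
    "> 0")
})

test_that("timeline anchoring restores the reference-period mean", {
  set.seed(31)
  years <- 1941:2017
  co <- mk_coefs(years) |>
    dplyr::mutate(coefficient = exp(rnorm(dplyr::n(), 0, 0.3)))
  tl <- build_fuel_timeline(prof, co, mk_cc(years),
                            reference_period = c(2003, 2015))
  ref_mean <- tl |>
    dplyr::filter(year %in% 2003:2015) |>
    dplyr::group_by(compartment) |>
    dplyr::summarise(m = mean(load_t_dm_ha), .groups = "drop") |>
    dplyr::left_join(prof, by = "compartment")
  expect_lt(max(abs(ref_mean$m - ref_mean$load_t_dm_ha)), 1e-9)
})

test_that("pre-span extrapolation copies the first modeled year", {
  years <- 1941:1945
  tl <- build_fuel_timeline(prof, mk_coefs(years, 1.2), mk_cc(years),
                            reference_period = c(1941, 1945))
  ext <- extrapolate_pre_span(tl, back_to = 1926)
  expect_identical(sort(unique(ext$year)), 1926:1945)
  first <- dplyr::filter(tl, year == 1941)
  for (y in 1926:1940) {
    got <- dplyr::filter(ext, year == y)
    expect_equal(got$load_t_dm_ha, first$load_t_dm_ha)
    expect_equal(got$completeness, first$completeness)
  }
  one <- extrapolate_pre_span(tl, back_to = 1940)
  expect_identical(min(one$year), 1940L)
  expect_error(extrapolate_pre_span(tl, back_to = 1941), "precede")
})

test_that("burned biomass multiplies area, loads, completeness and carbon", {
  tl <- tibble::tibble(year = 2000L, compartment = "duff_litter",
                       load_t_dm_ha = 10, completeness = 0.3)
  out <- burned_biomass(annual_series(2000L, 1), tl, "federal")
  expect_equal(out$value, 1.5)
  out0 <- burned_biomass(annual_series(2000L, 0), tl, "federal")
  expect_equal(out0$value, 0)
  expect_error(
    burned_biomass(annual_series(2000L, 1),
                   dplyr::mutate(tl, completeness = 1.4), "federal"),
    "\\[0, 1\\]")
})

test_that("burned biomass matches a per-compartment brute-force oracle", {
  set.seed(32)
  for (rep in 1:20) {
    years <- 1971:2000
    ba <- runif(30, 0, 1e5)
    ba[sample(30, 3)] <- NA
    tl <- tidyr::expand_grid(year = years,
                             compartment = fuel_compartments()) |>
      dplyr::mutate(load_t_dm_ha = runif(dplyr::n(), 0, 50),
                    completeness = runif(dplyr::n()))
    cat <- sample(forest_categories(), 1)
    got <- burned_biomass(annual_series(years, ba), tl, cat,
                          carbon_fraction = 0.5)
    comps <- if (cat == "other_forest") other_forest_compartments()
             else fuel_compartments()
    expected <- vapply(seq_along(years), function(i) {
      if (is.na(ba[i])) return(NA_real_)
      acc <- 0
      for (cmp in comps) {
        row <- tl[tl$year == years[i] & tl$compartment == cmp, ]
        acc <- acc + row$load_t_dm_ha * row$completeness
      }
      ba[i] * acc * 0.5
    }, numeric(1))
    expect_equal(got$value, expected, tolerance = 1e-12)
  }
})

test_that("burned biomass is monotone, scale-equivariant and bounded", {
  set.seed(33)
  years <- 1981:1990
  ba <- runif(10, 0, 1e4)
  tl <- tidyr::expand_grid(year = years,
                           compartment = fuel_compartments()) |>
    dplyr::mutate(load_t_dm_ha = runif(dplyr::n(), 0, 30),
                  completeness = runif(dplyr::n(), 0, 0.9))
  base <- burned_biomass(annual_series(years, ba), tl, "federal")

  up_ba <- burned_biomass(annual_series(years, ba * 1.1), tl, "federal")
  expect_true(all(up_ba$value >= base$value))
  up_fl <- burned_biomass(annual_series(years, ba),
                          dplyr::mutate(tl, load_t_dm_ha =
                                          load_t_dm_ha * 1.05),
                          "federal")
  expect_true(all(up_fl$value >= base$value))
  up_cc <- burned_biomass(annual_series(years, ba),
                          dplyr::mutate(tl, completeness =
                                          pmin(completeness + 0.05, 1)),
                          "federal")
  expect_true(all(up_cc$value >= base$value))

  dbl <- burned_biomass(annual_series(years, ba),
                        dplyr::mutate(tl, load_t_dm_ha = 2 * load_t_dm_ha),
                        "federal")
  expect_equal(dbl$value, 2 * base$value)

  # other forest burns a subset of the compartments of productive forest
  sparse <- burned_biomass(annual_series(years, ba), tl, "other_forest")
  expect_true(all(sparse$value <= base$value))

  # completeness of one bounds the burnable carbon
  cap <- burned_biomass(annual_series(years, ba),
                        dplyr::mutate(tl, completeness = 1), "federal")
  expect_true(all(base$value <= cap$value + 1e-12))
})
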