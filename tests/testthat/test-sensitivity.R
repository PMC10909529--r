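test_that("variant enumeration is the full factorial design", {
  specs <- enumerate_variants(region_codes())
  expect_identical(nrow(specs), 48L)
  expect_identical(nrow(enumerate_variants("NE")), 12L)
  expect_identical(nrow(dplyr::distinct(specs)), nrow(specs))
  expect_setequal(unique(specs$fuel_source), c("field_measured", "modeled"))
  expect_setequal(unique(specs$fuel_dynamics), c("static", "dynamic"))
  expect_setequal(unique(specs$cc_mode), c("low", "moderate", "high"))
  expect_error(enumerate_variants(c("NE", "NE")), "duplicate")
  expect_error(enumerate_variants(character(0)), "non-empty")
})

test_that("severity completeness sets are ordered low <= moderate <= high", {
  sev <- default_severity_completeness()
  wide <- tidyr::pivot_wider(sev, names_from = "severity",
                             values_from = "completeness")
  expect_true(all(wide$low <= wide$moderate))
  expect_true(all(wide$moderate <= wide$high))
})

world <- generate_world(tiny_config(201))
inputs <- variant_inputs(world)

test_that("static fuels equal dynamic fuels under identity coefficients", {
  inputs_id <- inputs
  inputs_id$coefficients <- dplyr::mutate(inputs$coefficients,
                                          coefficient = 1)
  for (reg in c("NE", "PC")) {
    stat <- run_variant(
      tibble::tibble(region = reg, fuel_source = "field_measured",
                     fuel_dynamics = "static", cc_mode = "moderate"),
      inputs_id)
    dyn <- run_variant(
      tibble::tibble(region = reg, fuel_source = "field_measured",
                     fuel_dynamics = "dynamic", cc_mode = "moderate"),
      inputs_id)
    expect_equal(stat$value, dyn$value, tolerance = 1e-12)
  }
})

test_that("fuel source is pure indirection when the tables coincide", {
  inputs_same <- inputs
  inputs_same$modeled_profile <- inputs$field_profile
  a <- run_variant(tibble::tibble(region = "SE",
                                  fuel_source = "field_measured",
                                  fuel_dynamics = "dynamic",
                                  cc_mode = "high"), inputs_same)
  b <- run_variant(tibble::tibble(region = "SE", fuel_source = "modeled",
                                  fuel_dynamics = "dynamic",
                                  cc_mode = "high"), inputs_same)
  expect_identical(a, b)
})

test_that("severity sub-variants are pointwise ordered", {
  for (src in c("field_measured", "modeled")) {
    for (dyn in c("static", "dynamic")) {
      runs <- lapply(c("low", "moderate", "high"), function(cc)
        run_variant(tibble::tibble(region = "RM", fuel_source = src,
                                   fuel_dynamics = dyn, cc_mode = cc),
                    inputs)$value)
      expect_true(all(runs[[1]] <= runs[[2]] + 1e-12, na.rm = TRUE))
      expect_true(all(runs[[2]] <= runs[[3]] + 1e-12, na.rm = TRUE))
    }
  }
})

test_that("the envelope bounds every variant pointwise", {
  sens <- run_sensitivity(inputs)
  expect_identical(nrow(dplyr::distinct(
    sens, region, fuel_source, fuel_dynamics, cc_mode)), 48L)
  for (reg in region_codes()) {
    reg_runs <- dplyr::filter(sens, region == reg)
    central <- run_variant(
      tibble::tibble(region = reg, fuel_source = "modeled",
                     fuel_dynamics = "dynamic", cc_mode = "moderate"),
      inputs)
    env <- envelope(dplyr::select(reg_runs, year, value), central,
                    component = "fire")
    joined <- dplyr::left_join(reg_runs, as_tibble(env), by = "year")
    expect_true(all(joined$value >= joined$low - 1e-9, na.rm = TRUE))
    expect_true(all(joined$value <= joined$high + 1e-9, na.rm = TRUE))
    expect_true(all(env$low <= env$high, na.rm = TRUE))
  }
})

test_that("envelope handles explicit variant lists and degenerate input", {
  a <- annual_series(2000:2002, c(1, 1, 1))
  b <- annual_series(2000:2002, c(3, 3, 3))
  env <- envelope(list(a, b), central = a)
  expect_equal(env$low, c(1, 1, 1))
  expect_equal(env$high, c(3, 3, 3))
  dup <- envelope(list(a, a), central = a)
  expect_equal(dup$low, dup$high)
  expect_error(envelope(list(a), central = a), "at least two")
})

test_that("range summary matches a brute-force loop over years", {
  env <- tibble::tibble(year = 2000:2002, low = c(8, 7, 9),
                        central = c(10, 10, 10), high = c(14, 12, 11))
  rs <- range_summary(env)
  expect_equal(rs$mean_plus, mean(c(4, 2, 1)))
  expect_equal(rs$max_plus, 4)
  expect_equal(rs$mean_minus, mean(c(-2, -3, -1)))
  expect_equal(rs$min_minus, -3)

  flat <- tibble::tibble(year = 2000L, low = 5, central = 5, high = 5)
  expect_equal(range_summary(flat)$mean_plus, 0)
  expect_equal(range_summary(flat)$min_minus, 0)

  set.seed(41)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    central <- runif(n, 0, 100)
    lo <- central - runif(n, 0, 10)
    hi <- central + runif(n, 0, 10)
    e <- tibble::tibble(year = seq_len(n) + 1900L, low = lo,
                        central = central, high = hi)
    rs <- range_summary(e)
    expect_equal(rs$mean_plus, mean(hi - central), tolerance = 1e-12)
    expect_equal(rs$max_plus, max(hi - central), tolerance = 1e-12)
    expect_equal(rs$mean_minus, mean(lo - central), tolerance = 1e-12)
    expect_equal(rs$min_minus, min(lo - central), tolerance = 1e-12)
  }
})
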