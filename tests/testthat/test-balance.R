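test_that("harvest expansion composes bark, crown and root factors", {
  s <- annual_series(2000:2001, c(100, 100))
  zero <- list(bark = 0, crown = 0, root_shoot = 0)
  expect_equal(expand_harvest(s, list(fuelwood = zero, industrial = zero),
                              0.5)$value,
               c(100, 100))
  f <- list(bark = 0.1, crown = 0.2, root_shoot = 0.25)
  out <- expand_harvest(s, list(fuelwood = f, industrial = f), 0.3)
  expect_equal(out$value, c(162.5, 162.5))

  # monotone in every ratio
  for (nm in c("bark", "crown", "root_shoot")) {
    f2 <- f; f2[[nm]] <- f[[nm]] + 0.1
    out2 <- expand_harvest(s, list(fuelwood = f2, industrial = f2), 0.3)
    expect_true(all(out2$value >= out$value))
  }
  expect_error(
    expand_harvest(s, list(fuelwood = f, industrial = f), 1.3),
    "\\[0, 1\\]")
})

test_that("expansion factor variants are ordered min <= central <= max", {
  s <- annual_series(1990:1999, runif(10, 0, 1e6))
  v <- lapply(c("min", "central", "max"), function(x)
    expand_harvest(s, default_expansion_factors(x), 0.3)$value)
  expect_true(all(v[[1]] <= v[[2]]))
  expect_true(all(v[[2]] <= v[[3]]))
})

test_that("per-area flux is plain division with a guarded denominator", {
  expect_equal(per_area_flux(1e6, 1e6), 1)
  s <- annual_series(2000L, 3e6)
  expect_equal(per_area_flux(s, 1e6)$value, 3)
  expect_equal(per_area_flux(s, 2e6)$value, 1.5)
  expect_error(per_area_flux(s, 0), "> 0")
})

mk_stocks <- function(times, densities, area = 1e6, code = "NE") {
  tibble::tibble(time = as.integer(times), level = "region", code = code,
                 forest_area_ha = area, stock_density_tc_ha = densities,
                 total_stock_tc = area * densities)
}
mk_removals <- function(years, fire, harvest, grazing, area = 1e6) {
  dplyr::bind_rows(
    tibble::tibble(component = "fire", year = years,
                   value_tc = fire * area),
    tibble::tibble(component = "harvest", year = years,
                   value_tc = harvest * area),
    tibble::tibble(component = "grazing", year = years,
                   value_tc = grazing * area))
}

test_that("interval balance implements the NEP bookkeeping identity", {
  stocks <- mk_stocks(c(1990, 2000), c(50, 54))
  removals <- mk_removals(1991:2000, 0.20, 0.72, 0.06)
  b <- interval_balance(stocks, removals, 1990, 2000)
  expect_equal(b$stock_change_rate, 0.4)
  expect_equal(b$nep, 1.38)
  expect_equal(b$nep, b$stock_change_rate + b$fire + b$harvest + b$grazing)

  null <- interval_balance(mk_stocks(c(1990, 2000), c(50, 50)),
                           mk_removals(1991:2000, 0, 0, 0), 1990, 2000)
  expect_equal(null$stock_change_rate, 0)
  expect_equal(null$nep, 0)

  expect_error(interval_balance(stocks, removals, 1989, 2000),
               "stock point")
  expect_error(
    interval_balance(stocks, mk_removals(2001:2002, 1, 1, 1), 1990, 2000),
    "no non-gap year")
})

test_that("gap years are excluded from removal means, not zero-filled", {
  stocks <- mk_stocks(c(1990, 2000), c(50, 54))
  removals <- mk_removals(1991:2000, 0.2, 0.7, 0.1)
  removals$value_tc[removals$component == "fire" &
                      removals$year %in% 1995:1999] <- NA
  b <- interval_balance(stocks, removals, 1990, 2000)
  expect_equal(b$fire, 0.2)   # mean over the five reported years
})

test_that("period averages are duration-weighted and identity-preserving", {
  stocks <- mk_stocks(c(1990, 2000, 2010), c(50, 54, 55))
  removals <- mk_removals(1991:2010, 0.1, 0.5, 0.05)
  bt <- balance_table(stocks, removals, c(1990, 2000, 2010),
                      geography = "NE")
  one <- period_average_balance(bt[1, ])
  expect_equal(one$nep, bt$nep[1])

  avg <- period_average_balance(bt)
  expect_equal(avg$stock_change_rate, mean(bt$stock_change_rate))
  resid <- abs(avg$nep - (avg$stock_change_rate + avg$fire + avg$harvest +
                            avg$grazing))
  expect_lt(resid, 1e-12)

  mixed <- dplyr::bind_rows(bt, dplyr::mutate(bt, geography = "SE"))
  expect_error(period_average_balance(mixed), "mix")
})

test_that("cumulative offsets partition NEP into shares summing to 100%", {
  one <- tibble::tibble(t0 = 1990L, t1 = 2000L, stock_change_rate = 0.45,
                        fire = 0.25, harvest = 0.2, grazing = 0.1,
                        nep = 1.0, denominator_area = 1e6)
  sh <- cumulative_offsets(one)
  expect_equal(sh$share_pct[sh$component == "fire"], 25)
  expect_lt(abs(sum(sh$share_pct) - 100), 1e-6)

  nofire <- dplyr::mutate(one, fire = 0, nep = 0.75)
  expect_equal(
    cumulative_offsets(nofire)$share_pct[sh$component == "fire"], 0)

  neg <- dplyr::mutate(one, nep = -1)
  expect_error(cumulative_offsets(neg), "positive")
})

test_that("tidy and glance summarise balance objects", {
  stocks <- mk_stocks(c(1990, 2000), c(50, 54))
  bt <- balance_table(stocks, mk_removals(1991:2000, 0.2, 0.7, 0.06),
                      c(1990, 2000), geography = "NE")
  long <- tidy(bt)
  expect_setequal(unique(long$component),
                  c("stock_change_rate", "fire", "harvest", "grazing",
                    "nep"))
  g <- glance(bt)
  expect_equal(g$n_intervals, 1L)
  expect_lt(g$max_identity_residual, 1e-12)
})
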