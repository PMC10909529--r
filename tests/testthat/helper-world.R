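# Compact world configurations used across the suite.
#
# `complete_config()` renders every source with full coverage and no noise:
# the regime in which the reconstruction must recover the truth exactly.
# State & private coverage is still withheld after `sp_cutoff`, so the
# subtraction inference is exercised on every run. `tiny_config()` shrinks
# the span further for replicate studies.

complete_config <- function(seed, ...) {
  world_config(
    seed = seed,
    span = c(1926L, 1976L),
    regional_start = 1926L,
    switch_year = 1965L,
    sp_cutoff = 1950L,
    totals_span = c(1926L, 1964L),
    missing_years = integer(0),
    excluded_window = NULL,
    reference_period = c(1960L, 1970L),
    inventory_years = seq(1926L, 1976L, 10L),
    ...
  )
}

tiny_config <- function(seed, ...) {
  world_config(
    seed = seed,
    span = c(1926L, 1956L),
    regional_start = 1926L,
    switch_year = 1945L,
    sp_cutoff = 1935L,
    totals_span = c(1926L, 1944L),
    missing_years = integer(0),
    excluded_window = NULL,
    reference_period = c(1945L, 1955L),
    inventory_years = seq(1926L, 1956L, 10L),
    ...
  )
}

# fuel inputs in the shape run_variant()/run_sensitivity() consume
variant_inputs <- function(world, recon = NULL) {
  area <- if (is.null(recon)) {
    world$truth$regional_series
  } else {
    recon$regional
  }
  c(world$fuel_inputs[c("field_profile", "modeled_profile", "coefficients",
                        "severity")],
    list(area = area,
         reference_period = world$config$reference_period))
}
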