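#' Unit conversions: acres to hectares, dry matter to carbon
#'
#' Historical burned-area statistics are published in acres; the pipeline
#' works in hectares throughout. `convert_area()` applies the exact
#' international definition 1 acre = 0.40468564224 ha. `dm_to_carbon()`
#' converts tons of dry-matter biomass to tons of carbon using a carbon
#' fraction (default 0.5, the standard average carbon content of dry woody
#' biomass; configurable for sensitivity runs).
#'
#' Both functions are vectorised and linear, and reject negative inputs:
#' neither a burned area nor a biomass mass can be negative.
#'
#' @param acres Numeric vector of areas in acres, all `>= 0` (`NA` passes
#'   through as `NA`, representing a data gap).
#' @return `convert_area()`: areas in hectares.
#' @export
#' @examples
#' convert_area(c(0, 1, 2471.0538))
#' dm_to_carbon(10)        # 5 tC
#' dm_to_carbon(100, 0.47) # 47 tC
convert_area <- function(acres) {
  check_nonnegative(acres, "acres")
  acres * ACRE_TO_HA
}

ACRE_TO_HA <- 0.40468564224

#' @rdname convert_area
#' @param mass Numeric vector of dry-matter masses (t DM), all `>= 0`.
#' @param carbon_fraction Carbon content of dry matter, in `(0, 1]`.
#' @return `dm_to_carbon()`: masses in tons carbon.
#' @export
dm_to_carbon <- function(mass, carbon_fraction = 0.5) {
  check_nonnegative(mass, "mass")
  if (!is.numeric(carbon_fraction) || length(carbon_fraction) != 1 ||
      is.na(carbon_fraction) || carbon_fraction <= 0 || carbon_fraction > 1) {
    abort("`carbon_fraction` must be a single number in (0, 1]")
  }
  mass * carbon_fraction
}

check_nonnegative <- function(x, what) {
  if (!is.numeric(x)) abort(paste0("`", what, "` must be numeric"))
  if (any(x < 0, na.rm = TRUE)) {
    bad <- which(x < 0)
    abort(paste0("`", what, "` must be >= 0; negative at position(s) ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  invisible(x)
}
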