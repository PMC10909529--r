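#' Study geography: the four-region partition of the contiguous U.S.
#'
#' The analysis partitions the contiguous United States into four broad
#' regions: Northeast (`NE`), Southeast (`SE`), Rocky Mountains (`RM`) and
#' Pacific Coast (`PC`). Every state belongs to exactly one region; the
#' membership table is configuration data, not code, and can be replaced in
#' any [world_config()] or reconstruction call.
#'
#' @return `region_codes()` returns the character vector of the four region
#'   codes, in fixed order.
#' @export
#' @examples
#' region_codes()
region_codes <- function() c("NE", "SE", "RM", "PC")

#' @rdname region_codes
#' @return `forest_categories()` returns the three forest land-cover
#'   categories: commercial state & private timberland, federal forests, and
#'   low-productivity "other forest" (wood-, shrub- and scrubland). Summing
#'   over all three gives total forest.
#' @export
forest_categories <- function() c("state_private", "federal", "other_forest")

#' @rdname region_codes
#' @return `fuel_compartments()` returns the seven fuel compartments: duff and
#'   litter, dead wood by moisture time-lag class (1, 10, 100, 1000 hr),
#'   herbaceous fuels, and canopy fuels.
#' @export
fuel_compartments <- function() {
  c("duff_litter", "dead_1hr", "dead_10hr", "dead_100hr", "dead_1000hr",
    "herb", "canopy")
}

#' @rdname region_codes
#' @return `other_forest_compartments()` returns the compartments assumed
#'   present in sparse "other forest" vegetation: duff/litter, 1-hr dead
#'   fuels (small dead branches), and grasses/herbs. Productive forests carry
#'   all seven compartments.
#' @export
other_forest_compartments <- function() c("duff_litter", "dead_1hr", "herb")

#' Default state-to-region membership
#'
#' A compact synthetic state roster (two states per region) used by the
#' synthetic-world generator and examples. Real applications supply their own
#' membership table; any tibble with columns `state` and `region` (region
#' codes drawn from [region_codes()]) is accepted wherever a membership is
#' needed.
#'
#' @return A tibble with columns `state`, `region`.
#' @export
#' @examples
#' default_state_membership()
default_state_membership <- function() {
  tibble(
    state  = c("NE1", "NE2", "SE1", "SE2", "RM1", "RM2", "PC1", "PC2"),
    region = rep(region_codes(), each = 2)
  )
}

validate_membership <- function(membership) {
  stopifnot(is.data.frame(membership))
  missing_cols <- setdiff(c("state", "region"), names(membership))
  if (length(missing_cols)) {
    abort(paste0("membership table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- setdiff(unique(membership$region), region_codes())
  if (length(bad)) {
    abort(paste0("unknown region code(s) in membership: ",
                 paste(bad, collapse = ", ")))
  }
  dup <- membership$state[duplicated(membership$state)]
  if (length(dup)) {
    abort(paste0("state(s) mapped to more than one region: ",
                 paste(unique(dup), collapse = ", ")))
  }
  invisible(membership)
}
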