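#' Annual series: the tidy time-series currency of the pipeline
#'
#' Every annual quantity (burned area, burned biomass, removal fluxes) is a
#' two-column tibble: `year` (integer calendar label) and `value`. A data gap
#' is an explicit `NA` value — never a silent zero, because the sources
#' distinguish "no data reported" years from years with zero burning.
#'
#' `annual_series()` validates and normalises such a tibble or a pair of
#' vectors; `complete_span()` pads a series to a closed year span, inserting
#' `NA` gaps; `series_gaps()` lists the gap years.
#'
#' @param year Integer-ish vector of calendar years (strictly increasing after
#'   sorting; duplicates are an error), or a data frame with columns
#'   `year`/`value`.
#' @param value Numeric values, same length as `year`; `NA` marks a gap.
#' @return A tibble with columns `year` (integer) and `value` (double),
#'   sorted by year.
#' @export
#' @examples
#' s <- annual_series(1926:1930, c(5, 4, NA, 3, 2))
#' series_gaps(s)
#' complete_span(s, c(1924, 1932))
annual_series <- function(year, value = NULL) {
  if (is.data.frame(year)) {
    df <- year
    if (!all(c("year", "value") %in% names(df))) {
      abort("series data frame needs columns `year` and `value`")
    }
    year <- df$year
    value <- df$value
  }
  if (is.null(value)) abort("`value` is required")
  if (length(year) != length(value)) abort("`year` and `value` lengths differ")
  if (anyNA(year)) abort("`year` must not contain NA")
  yr <- as.integer(year)
  if (any(yr != year)) abort("`year` must be whole calendar years")
  if (anyDuplicated(yr)) {
    abort(paste0("duplicate year(s): ",
                 paste(unique(yr[duplicated(yr)]), collapse = ", ")))
  }
  ord <- order(yr)
  tibble(year = yr[ord], value = as.double(value)[ord])
}

#' @rdname annual_series
#' @param series An annual-series tibble.
#' @param span Length-2 integer vector `c(first, last)`, closed on both ends.
#' @export
complete_span <- function(series, span) {
  series <- annual_series(series)
  span <- as.integer(span)
  if (length(span) != 2 || span[2] < span[1]) {
    abort("`span` must be c(first, last) with last >= first")
  }
  all_years <- tibble(year = span[1]:span[2])
  out <- full_join(all_years, series, by = "year")
  annual_series(out)
}

#' @rdname annual_series
#' @return `series_gaps()`: integer vector of years whose value is `NA`.
#' @export
series_gaps <- function(series) {
  series <- annual_series(series)
  series$year[is.na(series$value)]
}

#' Centered moving average over available years
#'
#' Smooths an annual series with a centered window mean, used to damp the
#' large year-to-year variation in burned biomass before comparing it with
#' decadal-average removals (window of 5 years by default). The window
#' shrinks at the series edges; gap (`NA`) years inside the window are
#' excluded from the mean, and a year stays a gap only when every year in its
#' window is a gap.
#'
#' @param series Annual-series tibble (see [annual_series()]).
#' @param window Odd positive integer window width (default 5).
#' @return An annual-series tibble on the same years.
#' @export
#' @examples
#' moving_average(annual_series(2001:2005, 1:5), window = 5)
moving_average <- function(series, window = 5L) {
  series <- annual_series(series)
  if (!is.numeric(window) || length(window) != 1 || window < 1 ||
      window != as.integer(window)) {
    abort("`window` must be a positive integer")
  }
  window <- as.integer(window)
  if (window %% 2L == 0L) abort("`window` must be odd")
  half <- (window - 1L) %/% 2L
  yrs <- series$year
  vals <- series$value
  out <- map_dbl(seq_along(yrs), function(i) {
    inside <- abs(yrs - yrs[i]) <= half
    v <- vals[inside]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  tibble(year = yrs, value = out)
}

#' Pairwise agreement ratio between two overlapping series
#'
#' Diagnostic used to judge whether two reporting sources can be spliced:
#' for every year both series report, the agreement is
#' `min(a, b) / max(a, b)` in percent (100% = identical, symmetric in its
#' arguments). Historical U.S. burned-area compilations agree to 96%-100%
#' over their overlaps, which justifies treating them as one record.
#'
#' @param a,b Annual-series tibbles.
#' @return A tibble with columns `year`, `ratio_pct`, carrying attributes
#'   `min_pct` and `max_pct`; also retrievable via [glance()].
#' @export
#' @examples
#' a <- annual_series(2000:2002, c(96, 50, 10))
#' b <- annual_series(2000:2002, c(100, 50, 10))
#' source_agreement(a, b)
source_agreement <- function(a, b) {
  a <- annual_series(a)
  b <- annual_series(b)
  ov <- inner_join(a, b, by = "year", suffix = c("_a", "_b")) |>
    filter(!is.na(.data$value_a), !is.na(.data$value_b))
  if (nrow(ov) == 0) abort("series share no overlapping non-gap year")
  ratio <- ifelse(
    ov$value_a == ov$value_b,
    100,
    100 * pmin(ov$value_a, ov$value_b) / pmax(ov$value_a, ov$value_b)
  )
  out <- tibble(year = ov$year, ratio_pct = ratio)
  structure(out,
            min_pct = min(ratio), max_pct = max(ratio),
            class = c("fc_agreement", class(out)))
}

#' @export
glance.fc_agreement <- function(x, ...) {
  tibble(n_years = nrow(x),
         min_pct = attr(x, "min_pct"),
         max_pct = attr(x, "max_pct"))
}
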