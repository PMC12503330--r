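#' Default PM2.5 AQI breakpoint table
#'
#' Returns the piecewise-linear breakpoint table mapping PM2.5 concentration
#' (µg/m³) to the Air Quality Index. The default is the long-standing US EPA
#' PM2.5 table (Good/Moderate cut at 12.0 µg/m³), with segment ends made
#' contiguous so the resulting index is a continuous function of
#' concentration. `revision = "2024"` gives the revised table (cut at
#' 9.0 µg/m³). Any other table can be supplied as JSON via
#' [read_breakpoints()].
#'
#' @param revision `"2012"` (default) or `"2024"`, selecting the EPA revision.
#' @return A tibble with columns `c_low`, `c_high` (µg/m³) and `i_low`,
#'   `i_high` (AQI units), one row per segment, sorted by concentration.
#' @examples
#' aqi_breakpoints()
#' @export
aqi_breakpoints <- function(revision = c("2012", "2024")) {
  revision <- match.arg(revision)
  c_cuts <- switch(revision,
    "2012" = c(0, 12.0, 35.4, 55.4, 150.4, 250.4, 350.4, 500.4),
    "2024" = c(0, 9.0, 35.4, 55.4, 125.4, 225.4, 325.4, 500.4)
  )
  i_cuts <- c(0, 50, 100, 150, 200, 300, 400, 500)
  n <- length(c_cuts) - 1L
  tbl <- tibble::tibble(
    c_low  = c_cuts[seq_len(n)],
    c_high = c_cuts[seq_len(n) + 1L],
    i_low  = i_cuts[seq_len(n)],
    i_high = i_cuts[seq_len(n) + 1L]
  )
  validate_breakpoints(tbl)
}

#' Read or write a breakpoint table as JSON
#'
#' The JSON format is an array of objects with fields `c_low`, `c_high`,
#' `i_low`, `i_high`.
#'
#' @param path File path.
#' @return `read_breakpoints()` returns a validated breakpoint tibble;
#'   `write_breakpoints()` returns `path` invisibly.
#' @export
read_breakpoints <- function(path) {
  tbl <- tibble::as_tibble(jsonlite::fromJSON(path))
  validate_breakpoints(tbl)
}

#' @rdname read_breakpoints
#' @param table A breakpoint tibble as returned by [aqi_breakpoints()].
#' @export
write_breakpoints <- function(table, path) {
  table <- validate_breakpoints(table)
  jsonlite::write_json(table, path, digits = NA)
  invisible(path)
}

validate_breakpoints <- function(table) {
  req <- c("c_low", "c_high", "i_low", "i_high")
  if (!all(req %in% names(table))) {
    stop("breakpoint table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  table <- dplyr::arrange(tibble::as_tibble(table), .data$c_low)
  if (any(table$c_low >= table$c_high) || any(table$i_low >= table$i_high)) {
    stop("each breakpoint segment needs c_low < c_high and i_low < i_high",
         call. = FALSE)
  }
  n <- nrow(table)
  if (n > 1L && any(abs(table$c_high[-n] - table$c_low[-1L]) > 1e-9)) {
    stop("breakpoint segments must be contiguous in concentration",
         call. = FALSE)
  }
  table
}

#' Convert PM2.5 concentration to AQI
#'
#' Linear interpolation within the breakpoint segment containing the
#' concentration: I = (I_high − I_low) / (C_high − C_low) × (C − C_low) +
#' I_low. Concentrations above the table's top segment are extrapolated
#' linearly along that segment, so the map is total on `[0, Inf)`.
#'
#' @param pm25 Numeric vector of PM2.5 concentrations (µg/m³); `NA` passes
#'   through.
#' @param breakpoints A breakpoint table (see [aqi_breakpoints()]).
#' @return Numeric vector of AQI values.
#' @examples
#' pm25_to_aqi(c(12, 35.4, 55.4))
#' @export
pm25_to_aqi <- function(pm25, breakpoints = aqi_breakpoints()) {
  breakpoints <- validate_breakpoints(breakpoints)
  bad <- !is.na(pm25) & pm25 < 0
  if (any(bad)) {
    stop("negative PM2.5 concentration: ",
         paste(format(pm25[bad]), collapse = ", "), call. = FALSE)
  }
  piecewise_map(pm25, breakpoints$c_low, breakpoints$c_high,
                breakpoints$i_low, breakpoints$i_high)
}

#' Invert the AQI map back to PM2.5 concentration
#'
#' Exact inverse of [pm25_to_aqi()] on the covered range (the breakpoint map
#' is strictly increasing, so the inverse is well defined).
#'
#' @inheritParams pm25_to_aqi
#' @param aqi Numeric vector of AQI values; `NA` passes through.
#' @return Numeric vector of PM2.5 concentrations (µg/m³).
#' @export
aqi_to_pm25 <- function(aqi, breakpoints = aqi_breakpoints()) {
  breakpoints <- validate_breakpoints(breakpoints)
  bad <- !is.na(aqi) & aqi < 0
  if (any(bad)) {
    stop("negative AQI value: ", paste(format(aqi[bad]), collapse = ", "),
         call. = FALSE)
  }
  piecewise_map(aqi, breakpoints$i_low, breakpoints$i_high,
                breakpoints$c_low, breakpoints$c_high)
}

# Map x through segments (from_lo, from_hi) -> (to_lo, to_hi); values beyond
# the last segment follow its slope.
piecewise_map <- function(x, from_lo, from_hi, to_lo, to_hi) {
  n <- length(from_lo)
  idx <- findInterval(x, from_lo, rightmost.closed = FALSE)
  idx[!is.na(idx) & idx < 1L] <- 1L
  idx[!is.na(idx) & idx > n] <- n
  slope <- (to_hi - to_lo) / (from_hi - from_lo)
  to_lo[idx] + slope[idx] * (x - from_lo[idx])
}

#' Classify an AQI value into a three-level state
#'
#' States follow the study's scheme: 1 = Good (AQI ≤ 150), 2 = Unhealthy
#' (150 < AQI ≤ 200), 3 = Very Unhealthy (AQI > 200). Boundaries belong to
#' the lower state.
#'
#' @param aqi Numeric vector of AQI values (finite, ≥ 0); `NA` passes through.
#' @return Integer vector of states in `{1, 2, 3}`.
#' @examples
#' aqi_state(c(150, 200, 200.01))
#' @export
aqi_state <- function(aqi) {
  if (any(!is.na(aqi) & !is.finite(aqi))) {
    stop("AQI values must be finite", call. = FALSE)
  }
  if (any(!is.na(aqi) & aqi < 0)) {
    stop("AQI values must be non-negative", call. = FALSE)
  }
  out <- rep(NA_integer_, length(aqi))
  ok <- !is.na(aqi)
  out[ok] <- 1L + (aqi[ok] > 150) + (aqi[ok] > 200)
  out
}

#' Labels for the three AQI states
#'
#' @return Character vector of length 3, named by state code.
#' @export
aqi_state_labels <- function() {
  c(`1` = "Good", `2` = "Unhealthy", `3` = "Very Unhealthy")
}
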