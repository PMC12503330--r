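#' Read a daily PM2.5 series from CSV
#'
#' Expected columns: `country`, `region`, `date` (ISO-8601), `pm25` (µg/m³;
#' empty cells are missing days).
#'
#' @param path CSV file path.
#' @return A tibble with one row per country-day, dates parsed, sorted by
#'   country then date.
#' @export
read_daily_pm25 <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    country = readr::col_character(),
    region = readr::col_character(),
    date = readr::col_date(),
    pm25 = readr::col_double()
  ))
  if (any(!is.na(x$pm25) & x$pm25 < 0)) {
    stop("negative PM2.5 values in ", path, call. = FALSE)
  }
  dplyr::arrange(x, .data$country, .data$date)
}

#' Aggregate daily PM2.5 into a weekly AQI state panel
#'
#' Each daily concentration is first converted to AQI through the breakpoint
#' table, then averaged within consecutive 7-day blocks counted from each
#' country's first date. A week with at least `min_valid_days` non-missing
#' days keeps the mean of its available daily AQI values; sparser weeks are
#' filled by [impute_weekly()] (linear interpolation between the nearest
#' valid weeks, nearest-neighbour fill at the edges) and flagged `imputed`.
#' Weekly averages are finally classified into states with [aqi_state()].
#'
#' @param daily A data frame with columns `country`, `region`, `date`,
#'   `pm25` (missing days as `NA`). Dates must be strictly increasing within
#'   country.
#' @param min_valid_days Minimum number of valid days for a week to stand on
#'   its own (default 4).
#' @param breakpoints Breakpoint table for the PM2.5 → AQI conversion.
#' @return A tibble with columns `country`, `region`, `week`, `aqi`,
#'   `state`, `n_valid_days`, `imputed` — the weekly panel consumed by
#'   [count_transitions()] and [fit_msm()].
#' @export
aggregate_weekly <- function(daily, min_valid_days = 4,
                             breakpoints = aqi_breakpoints()) {
  req <- c("country", "region", "date", "pm25")
  if (!all(req %in% names(daily))) {
    stop("daily data needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(daily) == 0L) stop("empty daily series", call. = FALSE)
  daily <- tibble::as_tibble(daily)

  dup <- daily |>
    dplyr::count(.data$country, .data$date) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop("duplicated dates within country: ",
         paste(dup$country[1], dup$date[1]), call. = FALSE)
  }

  daily |>
    dplyr::mutate(aqi_day = pm25_to_aqi(.data$pm25, breakpoints)) |>
    dplyr::group_by(.data$country, .data$region) |>
    dplyr::group_modify(~ weekly_one_subject(.x, min_valid_days)) |>
    dplyr::ungroup() |>
    dplyr::mutate(state = aqi_state(.data$aqi)) |>
    dplyr::select("country", "region", "week", "aqi", "state",
                  "n_valid_days", "imputed")
}

weekly_one_subject <- function(x, min_valid_days) {
  x <- dplyr::arrange(x, .data$date)
  week <- as.integer(floor(as.numeric(x$date - x$date[1]) / 7)) + 1L
  wk <- tibble::tibble(week = week, aqi_day = x$aqi_day) |>
    dplyr::group_by(.data$week) |>
    dplyr::summarise(
      n_valid_days = sum(!is.na(.data$aqi_day)),
      aqi = ifelse(.data$n_valid_days > 0,
                   mean(.data$aqi_day, na.rm = TRUE), NA_real_),
      .groups = "drop"
    ) |>
    # absent week blocks (all days unrecorded) still occupy a panel slot
    tidyr::complete(week = seq_len(max(week)),
                    fill = list(n_valid_days = 0L, aqi = NA_real_)) |>
    dplyr::mutate(imputed = .data$n_valid_days < min_valid_days)
  obs <- ifelse(wk$imputed, NA_real_, wk$aqi)
  if (all(is.na(obs))) {
    stop("no week reaches the validity threshold; nothing to interpolate from",
         call. = FALSE)
  }
  wk$aqi <- impute_weekly(obs)
  wk
}

#' Fill gaps in a weekly value series
#'
#' Interior runs of `NA` are linearly interpolated between the nearest valid
#' neighbouring weeks; leading and trailing gaps are filled by carrying the
#' nearest valid value. Valid weeks pass through unchanged.
#'
#' @param x Numeric vector of weekly values with `NA` gaps; at least one
#'   value must be present.
#' @return Numeric vector with every entry finite.
#' @examples
#' impute_weekly(c(NA, 90, NA, 110, NA))
#' @export
impute_weekly <- function(x) {
  if (length(x) == 0L) stop("empty weekly series", call. = FALSE)
  if (all(is.na(x))) stop("all weeks missing; nothing to interpolate from",
                          call. = FALSE)
  if (!anyNA(x)) return(x)
  if (sum(!is.na(x)) == 1L) return(rep(x[!is.na(x)], length(x)))
  idx <- seq_along(x)
  stats::approx(idx[!is.na(x)], x[!is.na(x)], xout = idx,
                method = "linear", rule = 2)$y
}

#' Write or read the weekly panel CSV
#'
#' Columns: `country,region,week,aqi,state,n_valid_days,imputed`.
#'
#' @param panel A weekly panel tibble from [aggregate_weekly()].
#' @param path CSV file path.
#' @return `read_weekly_panel()` returns the panel tibble;
#'   `write_weekly_panel()` returns `path` invisibly.
#' @export
write_weekly_panel <- function(panel, path) {
  readr::write_csv(panel, path)
  invisible(path)
}

#' @rdname write_weekly_panel
#' @export
read_weekly_panel <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    country = readr::col_character(),
    region = readr::col_character(),
    week = readr::col_integer(),
    state = readr::col_integer(),
    .default = readr::col_guess()
  ))
}
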