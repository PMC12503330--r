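#' Validate a weekly state panel
#'
#' Checks the longitudinal contract the likelihood relies on: columns
#' `country`, `region`, `week`, `state`; states in `{1,2,3}`; no duplicated
#' (country, week); weeks contiguous within country unless `allow_gaps`.
#'
#' @param panel A data frame of panel observations.
#' @param allow_gaps If `TRUE`, non-contiguous weeks within a country are
#'   tolerated (pairs spanning a gap are simply not adjacent).
#' @return The panel as a tibble, sorted by country and week (invisibly
#'   usable in a pipe).
#' @export
validate_panel <- function(panel, allow_gaps = FALSE) {
  req <- c("country", "region", "week", "state")
  if (!all(req %in% names(panel))) {
    stop("panel needs columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  panel <- dplyr::arrange(tibble::as_tibble(panel), .data$country, .data$week)
  if (!all(panel$state %in% 1:3)) {
    stop("states must be coded 1 (Good), 2 (Unhealthy), 3 (Very Unhealthy)",
         call. = FALSE)
  }
  dup <- panel |>
    dplyr::count(.data$country, .data$week) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop("duplicate (country, week): ", dup$country[1], " week ",
         dup$week[1], call. = FALSE)
  }
  if (!allow_gaps) {
    gaps <- panel |>
      dplyr::group_by(.data$country) |>
      dplyr::summarise(gap = any(diff(.data$week) != 1L), .groups = "drop") |>
      dplyr::filter(.data$gap)
    if (nrow(gaps) > 0L) {
      stop("non-contiguous weeks for country ", gaps$country[1],
           " (set allow_gaps = TRUE to skip broken pairs)", call. = FALSE)
    }
  }
  panel
}

#' Count observed week-to-week state transitions
#'
#' Tabulates consecutive within-country week pairs into a 3×3 matrix:
#' rows index the state at week t, columns the state at week t+1. Pairs
#' never cross country boundaries; with `allow_gaps = TRUE`, pairs spanning
#' a week gap are excluded rather than counted.
#'
#' @inheritParams validate_panel
#' @return A 3×3 integer matrix of transition counts with state labels on
#'   both dimensions.
#' @examples
#' panel <- tibble::tibble(country = "A", region = "Asia",
#'                         week = 1:3, state = c(1L, 1L, 2L))
#' count_transitions(panel)
#' @export
count_transitions <- function(panel, allow_gaps = FALSE) {
  panel <- validate_panel(panel, allow_gaps = allow_gaps)
  pairs <- transition_pairs(panel)
  pairs <- pairs[pairs$dt == 1L, , drop = FALSE]
  counts <- matrix(0L, 3L, 3L,
                   dimnames = list(from = aqi_state_labels(),
                                   to = aqi_state_labels()))
  for (k in seq_len(nrow(pairs))) {
    counts[pairs$from[k], pairs$to[k]] <- counts[pairs$from[k], pairs$to[k]] + 1L
  }
  counts
}

# Consecutive within-country observation pairs with their week lag.
transition_pairs <- function(panel) {
  panel |>
    dplyr::group_by(.data$country, .data$region) |>
    dplyr::reframe(
      from = .data$state[-dplyr::n()],
      to = .data$state[-1L],
      dt = diff(.data$week)
    )
}

#' Empirical transition fractions from a count matrix
#'
#' Divides each row of a transition count matrix by its row total and
#' expresses the result in percent. Rows with no observed pairs are
#' returned as `NA` with a warning.
#'
#' @param counts A 3×3 non-negative count matrix (see [count_transitions()]).
#' @return A 3×3 numeric matrix of row percentages (rows sum to 100 where
#'   defined).
#' @examples
#' transition_fractions(matrix(c(359, 41, 3, 44, 218, 16, 2, 18, 40),
#'                             3, 3, byrow = TRUE))
#' @export
transition_fractions <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    warning("row(s) with no observed transitions: fractions undefined",
            call. = FALSE)
  }
  out <- sweep(counts, 1, totals, "/") * 100
  out[totals == 0, ] <- NA_real_
  dimnames(out) <- dimnames(counts)
  out
}

#' Tidy a transition count matrix into a long tibble
#'
#' @param counts A square count matrix.
#' @return A tibble with columns `from`, `to`, `n`, `percent` (row
#'   percentage, half-up rounded to one decimal as displayed in reports).
#' @export
tidy_transitions <- function(counts) {
  fr <- suppressWarnings(transition_fractions(counts))
  labs <- rownames(counts)
  if (is.null(labs)) {
    labs <- if (nrow(counts) == 3L) unname(aqi_state_labels()) else
      as.character(seq_len(nrow(counts)))
  }
  tibble::tibble(
    from = rep(labs, times = ncol(counts)),
    to = rep(labs, each = nrow(counts)),
    n = as.integer(counts),
    percent = round_half_up(as.numeric(fr), 1)
  ) |>
    dplyr::arrange(match(.data$from, labs), match(.data$to, labs))
}

# round half away from zero, matching printed tables
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
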