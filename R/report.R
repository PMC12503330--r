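#' Persistence probabilities over increasing horizons
#'
#' For each region and state, the probability `P(t)[r, r]` of being found
#' in the same state `t` weeks later — the fitted counterpart of the
#' 10-week probability-decay curves. Note this is the panel-observation
#' quantity (the chain may leave and return within the window), the usual
#' reading of "probability of remaining" for weekly-sampled data.
#'
#' @param fit An [fit_msm()] result.
#' @param regions Regions to evaluate (default: all fitted regions).
#' @param horizon Largest horizon in weeks (default 10).
#' @param include_zero Include the `t = 0` reference point (probability 1)?
#' @return A tibble: `region`, `state`, `state_label`, `weeks`,
#'   `probability`.
#' @export
persistence_curves <- function(fit, regions = fit$regions, horizon = 10,
                               include_zero = FALSE) {
  stopifnot(inherits(fit, "msm_fit"), horizon >= 1)
  ts <- if (include_zero) 0:horizon else seq_len(horizon)
  purrr::map_dfr(regions, function(g) {
    Q <- intensity_matrix(fit, g)
    purrr::map_dfr(ts, function(t) {
      P <- transition_probability(Q, t)
      tibble::tibble(region = g, state = 1:3,
                     state_label = unname(aqi_state_labels()),
                     weeks = t, probability = unname(diag(P)))
    })
  })
}

#' Assemble the result surfaces of a fitted analysis
#'
#' Bundles the observed transition counts and row fractions, the hazard
#' ratio table, the sojourn-time table, requested multi-week transition
#' probability matrices and persistence curves into one list ready for
#' [render_report()].
#'
#' @param fit An [fit_msm()] result.
#' @param counts Optional 3×3 observed transition count matrix (from
#'   [count_transitions()]).
#' @param weeks Horizons (weeks) for the per-region transition probability
#'   matrices; `NULL` to omit.
#' @param horizon Persistence-curve horizon in weeks; `NULL` to omit.
#' @return A list of class `msm_report`.
#' @export
report_bundle <- function(fit, counts = NULL, weeks = 1:4, horizon = 10) {
  stopifnot(inherits(fit, "msm_fit"))
  bundle <- list(fit = fit)
  if (!is.null(counts)) {
    bundle$counts <- counts
    bundle$fractions <- suppressWarnings(transition_fractions(counts))
  }
  if (length(fit$covariate_regions) > 0L) {
    bundle$hazard_ratios <- hazard_ratios(fit)
  }
  bundle$sojourn <- sojourn_times(fit)
  if (!is.null(weeks)) {
    bundle$pt <- purrr::map_dfr(fit$regions, function(g) {
      predict_transitions(fit, weeks = weeks, region = g)
    })
  }
  if (!is.null(horizon)) {
    bundle$persistence <- persistence_curves(fit, horizon = horizon)
  }
  structure(bundle, class = "msm_report")
}

#' Write a report bundle to disk
#'
#' Emits deterministic CSV files (`counts.csv`, `fractions.csv`,
#' `hazard_ratios.csv`, `sojourn.csv`, `pt_<region>_<t>.csv`,
#' `persistence.csv`) plus a `manifest.json` listing what was written.
#' Sections absent from the bundle are omitted. Re-rendering the same
#' bundle produces byte-identical files.
#'
#' @param bundle An `msm_report` from [report_bundle()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest (character vector of file names).
#' @export
render_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "msm_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character()
  emit <- function(x, name) {
    readr::write_csv(x, file.path(dir, name))
    written <<- c(written, name)
  }
  if (!is.null(bundle$counts)) {
    emit(tidy_transitions(bundle$counts), "counts.csv")
    fr <- tidy_transitions(bundle$counts) |>
      dplyr::select("from", "to", "percent")
    emit(fr, "fractions.csv")
  }
  if (!is.null(bundle$hazard_ratios)) {
    emit(bundle$hazard_ratios, "hazard_ratios.csv")
  }
  if (!is.null(bundle$sojourn)) emit(bundle$sojourn, "sojourn.csv")
  if (!is.null(bundle$pt)) {
    for (g in unique(bundle$pt$region)) {
      for (t in unique(bundle$pt$weeks)) {
        emit(dplyr::filter(bundle$pt, .data$region == g, .data$weeks == t),
             sprintf("pt_%s_%s.csv", g, t))
      }
    }
  }
  if (!is.null(bundle$persistence)) emit(bundle$persistence, "persistence.csv")
  jsonlite::write_json(list(files = written), file.path(dir, "manifest.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(written)
}

#' Plot persistence curves
#'
#' One panel per state, one line per region: the probability of being
#' found in the same state after `t` weeks.
#'
#' @param curves Output of [persistence_curves()].
#' @return A ggplot object.
#' @export
plot_persistence <- function(curves) {
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$weeks, y = .data$probability,
                               colour = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~state_label) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Weeks", y = "P(same state)", colour = "Region") +
    ggplot2::theme_minimal()
}

#' Plot weekly AQI series by country
#'
#' Convenience line plot of weekly AQI panels with the state cut-offs
#' (150, 200) marked.
#'
#' @param weekly A weekly panel tibble with columns `country`, `week`,
#'   `aqi`.
#' @return A ggplot object.
#' @export
plot_weekly_aqi <- function(weekly) {
  ggplot2::ggplot(weekly, ggplot2::aes(x = .data$week, y = .data$aqi,
                                       colour = .data$country)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(150, 200), linetype = "dashed",
                        colour = c("blue", "red")) +
    ggplot2::labs(x = "Week", y = "Weekly mean AQI", colour = "Country") +
    ggplot2::theme_minimal()
}

#' Autoplot method for multi-state model fits
#'
#' Plots the fitted persistence curves for all regions over a 10-week
#' horizon.
#'
#' @param object An [fit_msm()] result.
#' @param horizon Largest horizon in weeks (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.msm_fit <- function(object, horizon = 10, ...) {
  plot_persistence(persistence_curves(object, horizon = horizon))
}
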