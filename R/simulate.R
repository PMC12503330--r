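#' Study-scale intensity matrices for the three regions
#'
#' Region-specific generators whose mean sojourn times match the magnitudes
#' reported for weekly air-quality panels: long Good and Unhealthy stays in
#' Asia with persistent Very Unhealthy episodes, quick recovery from poor
#' states in Europe, short Very Unhealthy episodes in Africa, and an
#' Unhealthy-to-Good rate in Asia (and Africa) well below Europe's.
#'
#' @return Named list of 3×3 intensity matrices (`Asia`, `Africa`,
#'   `Europe`).
#' @export
region_intensities <- function() {
  make_Q <- function(rates) {
    Q <- matrix(0, 3, 3, dimnames = list(aqi_state_labels(),
                                         aqi_state_labels()))
    Q[cbind(rep(1:3, each = 2), c(2, 3, 1, 3, 1, 2))] <-
      rates[c("q12", "q13", "q21", "q23", "q31", "q32")]
    diag(Q) <- -rowSums(Q)
    Q
  }
  list(
    # Good sojourn 6.8 wk, Unhealthy 6.64 wk, Very Unhealthy 3.36 wk
    Asia = make_Q(c(q12 = 0.1371, q13 = 0.0100, q21 = 0.0900, q23 = 0.0606,
                    q31 = 0.0060, q32 = 0.2916)),
    # Good 4.57 wk, Unhealthy 2.66 wk, Very Unhealthy 0.95 wk
    Africa = make_Q(c(q12 = 0.2000, q13 = 0.0188, q21 = 0.2500, q23 = 0.1259,
                      q31 = 0.0300, q32 = 1.0226)),
    # Good 7.68 wk, Unhealthy 0.90 wk, Very Unhealthy 0.68 wk
    Europe = make_Q(c(q12 = 0.1250, q13 = 0.0052, q21 = 1.0000, q23 = 0.1111,
                      q31 = 0.0500, q32 = 1.4206))
  )
}

#' Simulation configuration
#'
#' Describes a synthetic study: per-region subject counts and true
#' intensity matrices, the number of weekly observation times, and the
#' optional daily layer (latent weekly AQI expanded to noisy daily PM2.5
#' with missing days). Defaults mirror the study shape: 9 Asia + 3 Africa +
#' 7 Europe countries observed at 40 weekly times.
#'
#' @param regions Named list; each element a list with `n_subjects` and
#'   optionally `Q` (3×3 intensity matrix; defaults to
#'   [region_intensities()] for known region names).
#' @param n_weeks Number of weekly observation times (≥ 2), default 40.
#' @param daily_mode Generate a daily PM2.5 layer via [expand_to_daily()]?
#' @param daily_noise_sd Standard deviation of daily AQI noise around the
#'   latent weekly value (AQI units), default 10.
#' @param missing_day_rate Probability a day is dropped, default 0.
#' @param breakpoints Breakpoint table used to invert AQI to PM2.5 in daily
#'   mode.
#' @return A `sim_config` list.
#' @export
sim_config <- function(regions = list(Asia = list(n_subjects = 9),
                                      Africa = list(n_subjects = 3),
                                      Europe = list(n_subjects = 7)),
                       n_weeks = 40, daily_mode = FALSE,
                       daily_noise_sd = 10, missing_day_rate = 0,
                       breakpoints = aqi_breakpoints()) {
  stopifnot(n_weeks >= 2, missing_day_rate >= 0, missing_day_rate < 1)
  defaults <- region_intensities()
  regions <- purrr::imap(regions, function(r, name) {
    if (is.null(r$Q)) {
      if (!name %in% names(defaults)) {
        stop("no default intensity matrix for region '", name,
             "'; supply Q", call. = FALSE)
      }
      r$Q <- defaults[[name]]
    }
    stopifnot(is.matrix(r$Q), nrow(r$Q) == 3, ncol(r$Q) == 3,
              max(abs(rowSums(r$Q))) < 1e-8,
              all(r$Q[row(r$Q) != col(r$Q)] >= 0))
    r
  })
  structure(list(regions = regions, n_weeks = n_weeks,
                 daily_mode = daily_mode, daily_noise_sd = daily_noise_sd,
                 missing_day_rate = missing_day_rate,
                 breakpoints = breakpoints),
            class = "sim_config")
}

#' Simulate one continuous-time Markov chain trajectory
#'
#' Gillespie-style exact simulation: the holding time in state `r` is
#' exponential with rate `-q_rr`, and the next state is drawn from the
#' embedded jump chain with probabilities `q_rs / (-q_rr)`. The returned
#' trajectory is right-continuous on `[0, horizon]`.
#'
#' @param Q Intensity matrix.
#' @param horizon Length of the observation window (weeks), > 0.
#' @param initial_state Starting state (default 1).
#' @param seed Optional integer seed for this path.
#' @return A tibble with columns `time` (jump entry times, starting at 0)
#'   and `state`.
#' @export
simulate_ctmc_path <- function(Q, horizon, initial_state = 1L, seed = NULL) {
  stopifnot(horizon > 0, initial_state %in% seq_len(nrow(Q)))
  if (!is.null(seed)) set.seed(seed)
  cap <- 256L
  times <- numeric(cap)
  states <- integer(cap)
  n <- 1L
  states[1] <- as.integer(initial_state)
  t_now <- 0
  s <- as.integer(initial_state)
  repeat {
    rate <- -Q[s, s]
    if (rate <= 0) break  # absorbing row: path stays put
    t_now <- t_now + stats::rexp(1, rate)
    if (t_now >= horizon) break
    probs <- Q[s, ]
    probs[s] <- 0
    s <- sample.int(nrow(Q), 1, prob = probs)
    if (n == cap) {  # grow geometrically
      cap <- cap * 2L
      length(times) <- cap
      length(states) <- cap
    }
    n <- n + 1L
    times[n] <- t_now
    states[n] <- s
  }
  tibble::tibble(time = times[seq_len(n)], state = states[seq_len(n)])
}

#' Sample a trajectory at integer week times
#'
#' Panel observation: the state is recorded at weeks `1..n_weeks` and
#' intermediate jumps are discarded.
#'
#' @param path A trajectory from [simulate_ctmc_path()].
#' @param n_weeks Number of weekly observation times; the trajectory's
#'   horizon must cover them.
#' @return An integer vector of length `n_weeks`.
#' @export
sample_weekly <- function(path, n_weeks) {
  stopifnot(n_weeks >= 1)
  idx <- findInterval(seq_len(n_weeks), path$time)
  if (any(idx < 1L)) stop("trajectory does not cover week 1", call. = FALSE)
  path$state[idx]
}

# stationary distribution of a CTMC: left null vector of Q, normalised
stationary_distribution <- function(Q) {
  A <- rbind(t(Q), rep(1, nrow(Q)))
  b <- c(rep(0, nrow(Q)), 1)
  pi <- qr.solve(A, b)
  pmax(pi, 0) / sum(pmax(pi, 0))
}

#' Simulate a weekly state panel
#'
#' Draws one exact trajectory per subject from its region's intensity
#' matrix and records the state at each integer week. Initial states are
#' drawn from each region's stationary distribution (overridable), so the
#' panel starts in steady state.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; all randomness derives from it.
#' @param initial_states Optional named list (by region) of fixed initial
#'   states; default draws from the stationary distribution.
#' @return A weekly panel tibble (`country`, `region`, `week`, `state`)
#'   ready for [count_transitions()] and [fit_msm()].
#' @export
simulate_panel <- function(config, seed, initial_states = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  purrr::imap_dfr(config$regions, function(r, region) {
    fixed_start <- initial_states[[region]]
    # reducible generators have no unique stationary law; only solve for it
    # when the start is actually drawn from it
    pi0 <- if (is.null(fixed_start)) stationary_distribution(r$Q)
    purrr::map_dfr(seq_len(r$n_subjects), function(i) {
      s0 <- if (!is.null(fixed_start)) {
        fixed_start
      } else {
        sample.int(3L, 1, prob = pi0)
      }
      path <- simulate_ctmc_path(r$Q, horizon = config$n_weeks + 1, s0)
      tibble::tibble(
        country = sprintf("%s_%02d", region, i),
        region = region,
        week = seq_len(config$n_weeks),
        state = sample_weekly(path, config$n_weeks)
      )
    })
  })
}

#' Expand a weekly state panel to daily PM2.5 series
#'
#' For each country-week, a latent weekly AQI value is drawn uniformly
#' within the state's AQI band (Good `[0, 150]`, Unhealthy `(150, 200]`,
#' Very Unhealthy `(200, 500]`), seven daily AQI values are generated as
#' the latent value plus independent Gaussian noise (truncated at 0), each
#' day's AQI is inverted through the breakpoint table to a PM2.5
#' concentration, and days are dropped independently at the configured
#' missing rate. The result exercises the full preprocessing path.
#'
#' @param panel A weekly state panel (`country`, `region`, `week`,
#'   `state`).
#' @param config A [sim_config()] (supplies noise sd, missing rate and
#'   breakpoints).
#' @param seed Integer seed.
#' @param start_date First calendar day (default 2024-01-01).
#' @return A list with `daily` (tibble `country`, `region`, `date`,
#'   `pm25`) and `latent` (tibble `country`, `region`, `week`,
#'   `latent_aqi`).
#' @export
expand_to_daily <- function(panel, config, seed,
                            start_date = as.Date("2024-01-01")) {
  stopifnot(inherits(config, "sim_config"))
  panel <- validate_panel(panel)
  set.seed(seed)
  bands <- list(`1` = c(0, 150), `2` = c(150.01, 200), `3` = c(200.01, 500))
  latent <- panel |>
    dplyr::mutate(latent_aqi = purrr::map_dbl(.data$state, function(s) {
      b <- bands[[as.character(s)]]
      stats::runif(1, b[1], b[2])
    }))
  daily <- latent |>
    dplyr::group_by(.data$country, .data$region) |>
    dplyr::group_modify(function(x, key) {
      x <- dplyr::arrange(x, .data$week)
      aqi_day <- rep(x$latent_aqi, each = 7L) +
        stats::rnorm(7L * nrow(x), 0, config$daily_noise_sd)
      aqi_day <- pmax(aqi_day, 0)
      pm25 <- aqi_to_pm25(aqi_day, config$breakpoints)
      drop <- stats::runif(length(pm25)) < config$missing_day_rate
      pm25[drop] <- NA_real_
      tibble::tibble(
        date = start_date + seq_along(pm25) - 1L,
        pm25 = pm25
      )
    }) |>
    dplyr::ungroup()
  list(daily = daily,
       latent = dplyr::select(latent, "country", "region", "week",
                              "latent_aqi"))
}
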