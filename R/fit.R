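#' Fit the panel-observed multi-state Markov model
#'
#' Maximum-likelihood fit of a time-homogeneous three-state continuous-time
#' Markov chain observed at weekly panel times, with region entering each
#' transition intensity log-linearly (proportional intensities):
#' `q_rs(z) = exp(log q_rs + beta_rs' z)`, where `z` holds indicator columns
#' for every non-reference region. Estimation maximises the sum over
#' consecutive within-country week pairs of `log P(dt)[state_t, state_{t+1}]`
#' by bounded quasi-Newton iteration (L-BFGS-B); the covariance of the
#' estimates is the inverse of the observed information, evaluated by
#' central finite differences at the optimum.
#'
#' @inheritParams validate_panel
#' @param reference Reference region (zero covariate vector). Defaults to
#'   `"Europe"` when present, otherwise the first region alphabetically.
#' @param transitions Tibble of allowed transitions (`from`, `to`);
#'   defaults to all six off-diagonal pairs.
#' @param control List of optimizer settings: `maxit` (default 500),
#'   `factr` (relative log-likelihood tolerance factor, default 1e7, i.e.
#'   about 2e-9 relative), `pgtol` (gradient max-norm, default 1e-5),
#'   `rate_floor` (floor for crude initial rates, default 1e-3).
#' @return An object of class `msm_fit`: parameter estimates and standard
#'   errors, covariance matrix, log-likelihood, convergence diagnostics and
#'   bookkeeping. Use [tidy()], [glance()], [hazard_ratios()],
#'   [sojourn_times()], [intensity_matrix()] and [predict_transitions()] to
#'   interrogate it.
#' @examples
#' cfg <- sim_config(n_weeks = 30, regions = list(
#'   Asia = list(n_subjects = 4), Europe = list(n_subjects = 4)))
#' panel <- simulate_panel(cfg, seed = 1)
#' fit <- fit_msm(panel)
#' glance(fit)
#' @export
fit_msm <- function(panel, reference = NULL, transitions = all_transitions(),
                    allow_gaps = FALSE, control = list()) {
  ctl <- utils::modifyList(
    list(maxit = 500L, factr = 1e7, pgtol = 1e-5, rate_floor = 1e-3),
    control
  )
  panel <- validate_panel(panel, allow_gaps = allow_gaps)
  groups <- panel_count_groups(panel, allow_gaps = allow_gaps)
  regions <- sort(unique(as.character(panel$region)))
  if (is.null(reference)) {
    reference <- if ("Europe" %in% regions) "Europe" else regions[1]
  }
  if (!reference %in% regions) {
    stop("reference region '", reference, "' not present in the panel",
         call. = FALSE)
  }
  covariate_regions <- setdiff(regions, reference)
  k <- nrow(transitions)

  # observed support: total transitions per allowed pair and time at risk
  pooled <- Reduce(`+`, groups$counts)
  pairs <- transition_pairs(panel)
  at_risk <- vapply(1:3, function(r) sum(pairs$dt[pairs$from == r]),
                    numeric(1))
  n_obs_trans <- pooled[cbind(transitions$from, transitions$to)]
  nonidentified <- n_obs_trans == 0

  # crude count-based start, floored so log is finite
  q0 <- pmax(n_obs_trans / pmax(at_risk[transitions$from], 1), ctl$rate_floor)
  par0 <- c(log(q0), rep(0, k * length(covariate_regions)))
  par_names <- c(
    paste0("logq_", transitions$from, transitions$to),
    unlist(lapply(covariate_regions, function(g) {
      paste0("beta_", g, "_", transitions$from, transitions$to)
    }))
  )
  names(par0) <- par_names

  unpack <- function(par) {
    logq <- par[seq_len(k)]
    beta <- NULL
    if (length(covariate_regions) > 0L) {
      beta <- matrix(par[-seq_len(k)], nrow = k)
      colnames(beta) <- covariate_regions
    }
    list(logq = logq, beta = beta)
  }
  z_of <- function(region) {
    as.numeric(covariate_regions == region)
  }
  Q_list <- function(par) {
    p <- unpack(par)
    stats::setNames(lapply(regions, function(g) {
      build_Q(p$logq, p$beta, z_of(g), transitions)
    }), regions)
  }
  negll <- function(par) {
    ll <- loglik_from_groups(groups, Q_list(par))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  # bounds keep rates in a range weekly panel data can speak to
  lower <- c(rep(log(1e-8), k), rep(-20, k * length(covariate_regions)))
  upper <- c(rep(log(50), k), rep(20, k * length(covariate_regions)))
  opt <- stats::optim(
    par0, negll, method = "L-BFGS-B", lower = lower, upper = upper,
    control = list(maxit = ctl$maxit, factr = ctl$factr, pgtol = ctl$pgtol)
  )
  est <- opt$par
  at_lower <- est[seq_len(k)] <= lower[seq_len(k)] + 1e-6
  nonidentified <- nonidentified | at_lower

  H <- numeric_hessian(negll, est)  # observed information of -loglik
  vc <- try(solve(H), silent = TRUE)
  degenerate <- inherits(vc, "try-error") || any(!is.finite(vc)) ||
    any(diag(vc) < 0)
  if (degenerate) {
    vc <- MASS::ginv(H)
  }
  vc <- (vc + t(vc)) / 2
  dimnames(vc) <- list(par_names, par_names)
  se <- sqrt(pmax(diag(vc), 0))

  out <- structure(list(
    estimates = est,
    std_errors = se,
    vcov = vc,
    log_likelihood = -opt$value,
    converged = opt$convergence == 0L,
    n_iterations = opt$counts[["function"]],
    message = opt$message,
    transitions = transitions,
    regions = regions,
    reference = reference,
    covariate_regions = covariate_regions,
    nonidentified = stats::setNames(nonidentified,
                                    transition_label(transitions$from,
                                                     transitions$to)),
    degenerate = degenerate,
    n_obs = nrow(panel),
    n_pairs = nrow(pairs),
    counts = pooled,
    groups = groups,
    control = ctl
  ), class = "msm_fit")
  if (!out$converged) {
    warning("optimizer did not converge: ", opt$message, call. = FALSE)
  }
  out
}

# Central-difference Hessian, step 1e-5 relative to parameter magnitude.
numeric_hessian <- function(f, x, rel_step = 1e-5) {
  n <- length(x)
  h <- rel_step * pmax(abs(x), 1)
  H <- matrix(0, n, n)
  f0 <- f(x)
  for (i in seq_len(n)) {
    ei <- replace(numeric(n), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < n) {
      for (j in seq((i + 1), n)) {
        ej <- replace(numeric(n), j, h[j])
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
             f(x - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

region_z <- function(fit, region) {
  if (!region %in% fit$regions) {
    stop("unknown region '", region, "'; fitted regions: ",
         paste(fit$regions, collapse = ", "), call. = FALSE)
  }
  as.numeric(fit$covariate_regions == region)
}

fit_beta_matrix <- function(fit) {
  k <- nrow(fit$transitions)
  if (length(fit$covariate_regions) == 0L) return(NULL)
  matrix(fit$estimates[-seq_len(k)], nrow = k,
         dimnames = list(NULL, fit$covariate_regions))
}

#' Fitted intensity matrix for a region
#'
#' @param fit An [fit_msm()] result.
#' @param region Region label; defaults to the reference region.
#' @return The fitted 3×3 intensity matrix at that region's covariates.
#' @export
intensity_matrix <- function(fit, region = fit$reference) {
  stopifnot(inherits(fit, "msm_fit"))
  k <- nrow(fit$transitions)
  build_Q(fit$estimates[seq_len(k)], fit_beta_matrix(fit),
          region_z(fit, region), fit$transitions)
}

#' Fitted multi-week transition probabilities
#'
#' Evaluates `P(t) = expm(t * Q̂(region))` for each requested horizon.
#'
#' @inheritParams intensity_matrix
#' @param weeks Numeric vector of horizons in weeks (each ≥ 0).
#' @return A tibble with columns `region`, `weeks`, `from`, `to`,
#'   `probability`.
#' @export
predict_transitions <- function(fit, weeks = 1:4, region = fit$reference) {
  stopifnot(inherits(fit, "msm_fit"))
  Q <- intensity_matrix(fit, region)
  labs <- aqi_state_labels()
  purrr::map_dfr(weeks, function(t) {
    P <- transition_probability(Q, t)
    tibble::tibble(
      region = region, weeks = t,
      from = rep(labs, times = 3L), to = rep(labs, each = 3L),
      probability = as.numeric(P)
    )
  })
}

#' Hazard ratios of region effects on transition intensities
#'
#' For each allowed transition and each non-reference region, the hazard
#' ratio `exp(beta)` with a 95% Wald interval
#' `exp(beta ± 1.959964 · se(beta))`. A non-finite standard error yields an
#' unbounded interval and sets `degenerate`, mirroring the numerically
#' unstable intervals that rare transitions produce.
#'
#' @param fit An [fit_msm()] result.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble: `region`, `from`, `to`, `transition`, `hr`, `ci_low`,
#'   `ci_high`, `log_hr`, `se_log_hr`, `degenerate`.
#' @export
hazard_ratios <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "msm_fit"))
  if (!fit$converged) {
    warning("hazard ratios from a non-converged fit", call. = FALSE)
  }
  if (length(fit$covariate_regions) == 0L) {
    stop("single-region fit has no covariate effects", call. = FALSE)
  }
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
  k <- nrow(fit$transitions)
  purrr::map_dfr(fit$covariate_regions, function(g) {
    idx <- which(names(fit$estimates) ==
                   paste0("beta_", g, "_", fit$transitions$from,
                          fit$transitions$to))
    b <- unname(fit$estimates[idx])
    s <- unname(fit$std_errors[idx])
    bad <- !is.finite(s)
    tibble::tibble(
      region = g,
      from = fit$transitions$from,
      to = fit$transitions$to,
      transition = transition_label(fit$transitions$from,
                                    fit$transitions$to),
      hr = exp(b),
      ci_low = ifelse(bad, 0, exp(b - zcrit * s)),
      ci_high = ifelse(bad, Inf, exp(b + zcrit * s)),
      log_hr = b,
      se_log_hr = s,
      degenerate = bad | s == 0 & fit$degenerate
    )
  })
}

#' Mean sojourn times with delta-method standard errors
#'
#' The mean sojourn time in state `r` at covariates `z` is `-1/q_rr(z)`,
#' the expected length of a single stay before any transition. Standard
#' errors propagate the parameter covariance through this transformation
#' to first order (delta method).
#'
#' @param fit An [fit_msm()] result.
#' @param regions Character vector of regions to evaluate; defaults to all
#'   fitted regions.
#' @return A tibble: `region`, `state`, `state_label`, `mean` (weeks),
#'   `se` (weeks). An exit rate of zero reports an infinite mean.
#' @export
sojourn_times <- function(fit, regions = fit$regions) {
  stopifnot(inherits(fit, "msm_fit"))
  k <- nrow(fit$transitions)
  tr <- fit$transitions
  purrr::map_dfr(regions, function(g) {
    z <- region_z(fit, g)
    Q <- intensity_matrix(fit, g)
    q_rates <- Q[cbind(tr$from, tr$to)]
    purrr::map_dfr(1:3, function(r) {
      rows <- which(tr$from == r)
      q_exit <- -Q[r, r]
      if (q_exit <= 0) {
        return(tibble::tibble(region = g, state = r,
                              state_label = unname(aqi_state_labels()[r]),
                              mean = Inf, se = NA_real_))
      }
      # gradient of 1/q_exit wrt (logq, beta): dq_rs/dlogq_rs = q_rs,
      # dq_rs/dbeta_g_rs = q_rs * z_g
      grad <- numeric(length(fit$estimates))
      grad[rows] <- q_rates[rows]
      if (length(fit$covariate_regions) > 0L) {
        for (j in seq_along(fit$covariate_regions)) {
          grad[k * j + rows] <- q_rates[rows] * z[j]
        }
      }
      grad <- -grad / q_exit^2
      se <- sqrt(max(drop(t(grad) %*% fit$vcov %*% grad), 0))
      tibble::tibble(region = g, state = r,
                     state_label = unname(aqi_state_labels()[r]),
                     mean = 1 / q_exit, se = se)
    })
  })
}

#' Likelihood-ratio check of time homogeneity
#'
#' Splits the panel at its midpoint week, fits the model separately on the
#' early and late halves and once jointly, and compares via a
#' likelihood-ratio statistic with degrees of freedom equal to the number
#' of free parameters. Under time homogeneity the two half-period intensity
#' matrices estimate the same quantity and the statistic is asymptotically
#' chi-squared.
#'
#' @inheritParams fit_msm
#' @param min_pairs Minimum number of transition pairs a half must contain
#'   to attempt the test (default 12); below this the check is flagged
#'   underpowered and no statistic is reported.
#' @return An object of class `msm_homogeneity`: fitted intensity matrices
#'   per half and region, the statistic, degrees of freedom and p-value (or
#'   `NA` with `underpowered = TRUE`).
#' @export
time_homogeneity_check <- function(panel, reference = NULL,
                                   transitions = all_transitions(),
                                   min_pairs = 12, control = list()) {
  panel <- validate_panel(panel)
  mid <- floor((min(panel$week) + max(panel$week)) / 2)
  early <- dplyr::filter(panel, .data$week <= mid)
  late <- dplyr::filter(panel, .data$week > mid) |>
    dplyr::mutate(week = .data$week - mid)
  n_early <- nrow(early) - dplyr::n_distinct(early$country)
  n_late <- nrow(late) - dplyr::n_distinct(late$country)
  underpowered <- n_early < min_pairs || n_late < min_pairs
  # the joint fit uses each half as its own series segment, so joint and
  # split fits see exactly the same transition pairs and the LR is properly
  # nested (the pair spanning the midpoint belongs to neither period)
  segmented <- dplyr::bind_rows(
    early, dplyr::mutate(late, country = paste0(.data$country, ".late"))
  )
  fit_joint <- fit_msm(segmented, reference = reference,
                       transitions = transitions, control = control)
  out <- list(midpoint = mid, underpowered = underpowered,
              fit_joint = fit_joint, df = length(fit_joint$estimates),
              statistic = NA_real_, p_value = NA_real_,
              Q_early = NULL, Q_late = NULL)
  if (!underpowered) {
    fit_early <- fit_msm(early, reference = reference,
                         transitions = transitions, control = control)
    fit_late <- fit_msm(late, reference = reference,
                        transitions = transitions, control = control)
    out$fit_early <- fit_early
    out$fit_late <- fit_late
    out$Q_early <- stats::setNames(
      lapply(fit_early$regions, intensity_matrix, fit = fit_early),
      fit_early$regions)
    out$Q_late <- stats::setNames(
      lapply(fit_late$regions, intensity_matrix, fit = fit_late),
      fit_late$regions)
    # clamp optimizer-tolerance negatives; the statistic is >= 0 in theory
    out$statistic <- max(0, 2 * (fit_early$log_likelihood +
                                   fit_late$log_likelihood -
                                   fit_joint$log_likelihood))
    out$p_value <- stats::pchisq(out$statistic, df = out$df,
                                 lower.tail = FALSE)
  }
  structure(out, class = "msm_homogeneity")
}

#' @exportS3Method base::print
print.msm_homogeneity <- function(x, ...) {
  cat("Time-homogeneity check (split at week", x$midpoint, ")\n")
  if (x$underpowered) {
    cat("  underpowered: too few transitions in a half; no statistic\n")
  } else {
    cat(sprintf("  LR statistic %.3f on %d df, p = %.4g\n",
                x$statistic, x$df, x$p_value))
  }
  invisible(x)
}

#' @exportS3Method base::print
print.msm_fit <- function(x, ...) {
  cat("Panel-observed 3-state Markov model\n")
  cat(sprintf("  %d observations, %d transition pairs, regions: %s (ref %s)\n",
              x$n_obs, x$n_pairs, paste(x$regions, collapse = ", "),
              x$reference))
  cat(sprintf("  log-likelihood %.3f, %d parameters, converged: %s\n",
              x$log_likelihood, length(x$estimates), x$converged))
  if (any(x$nonidentified)) {
    cat("  non-identified transitions:",
        paste(names(x$nonidentified)[x$nonidentified], collapse = ", "), "\n")
  }
  cat("\nFitted intensities (reference region):\n")
  print(round(intensity_matrix(x), 4))
  invisible(x)
}

#' Tidy method for multi-state model fits
#'
#' One row per free parameter: log baseline intensities (`type =
#' "log_intensity"`) and region coefficients (`type = "coefficient"`, the
#' log hazard ratios). `exponentiate = TRUE` transforms estimates and
#' confidence bounds to the rate / hazard-ratio scale.
#'
#' @param x An [fit_msm()] result.
#' @param conf_level Wald confidence level (default 0.95).
#' @param exponentiate Report `exp(estimate)` and exponentiated bounds?
#' @param ... Unused.
#' @return A tibble: `term`, `type`, `region`, `from`, `to`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @export
tidy.msm_fit <- function(x, conf_level = 0.95, exponentiate = FALSE, ...) {
  k <- nrow(x$transitions)
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
  n_cov <- length(x$covariate_regions)
  out <- tibble::tibble(
    term = names(x$estimates),
    type = rep(c("log_intensity", "coefficient"), c(k, k * n_cov)),
    region = c(rep(x$reference, k),
               rep(x$covariate_regions, each = k)),
    from = rep(x$transitions$from, 1 + n_cov),
    to = rep(x$transitions$to, 1 + n_cov),
    estimate = unname(x$estimates),
    std.error = unname(x$std_errors),
    conf.low = unname(x$estimates - zcrit * x$std_errors),
    conf.high = unname(x$estimates + zcrit * x$std_errors)
  )
  if (exponentiate) {
    out <- dplyr::mutate(out,
                         estimate = exp(.data$estimate),
                         conf.low = exp(.data$conf.low),
                         conf.high = exp(.data$conf.high))
  }
  out
}

#' Glance method for multi-state model fits
#'
#' @param x An [fit_msm()] result.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `df`, `nobs`, `n_pairs`,
#'   `converged`, `iterations`, `degenerate`.
#' @export
glance.msm_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$log_likelihood,
    df = length(x$estimates),
    nobs = x$n_obs,
    n_pairs = x$n_pairs,
    converged = x$converged,
    iterations = x$n_iterations,
    degenerate = x$degenerate
  )
}
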