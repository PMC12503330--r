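test_that("single-region fit recovers a known generator within 3 SEs", {
  Q <- build_Q(log(c(0.15, 0.02, 0.25, 0.08, 0.05, 0.4)))
  cfg <- sim_config(regions = list(Asia = list(n_subjects = 40, Q = Q)),
                    n_weeks = 80)
  panel <- simulate_panel(cfg, seed = 41)
  fit <- fit_msm(panel)
  expect_true(fit$converged)
  truth <- log(c(0.15, 0.02, 0.25, 0.08, 0.05, 0.4))
  expect_true(all(abs(fit$estimates - truth) <= 3 * fit$std_errors))
})

test_that("region effects are recovered and reported as hazard ratios", {
  logq <- log(c(0.12, 0.01, 0.6, 0.1, 0.05, 0.7))
  beta <- matrix(0, 6, 1)
  beta[3, 1] <- log(0.2)   # Asia slows recovery 2->1
  beta[1, 1] <- log(1.5)   # Asia deteriorates 1->2 faster
  cfg <- sim_config(regions = list(
    Asia = list(n_subjects = 30, Q = build_Q(logq, beta, 1)),
    Europe = list(n_subjects = 30, Q = build_Q(logq, beta, 0))
  ), n_weeks = 80)
  panel <- simulate_panel(cfg, seed = 42)
  fit <- fit_msm(panel, reference = "Europe")
  hr <- hazard_ratios(fit)
  h21 <- hr[hr$from == 2 & hr$to == 1, ]
  expect_true(abs(h21$log_hr - log(0.2)) <= 3 * h21$se_log_hr)
  expect_true(h21$ci_low < 0.2 & 0.2 < h21$ci_high)
  # Wald interval algebra: exp(beta -/+ 1.96 se)
  expect_equal(h21$ci_low, exp(h21$log_hr - qnorm(0.975) * h21$se_log_hr))
  # the fitted Asia matrix applies the multiplicative effect
  expect_equal(intensity_matrix(fit, "Asia")[2, 1],
               exp(fit$estimates["logq_21"] + fit$estimates["beta_Asia_21"]),
               ignore_attr = TRUE)
})

test_that("sojourn times equal minus reciprocal diagonal with delta-method SE", {
  cfg <- sim_config(regions = list(Europe = list(n_subjects = 15)),
                    n_weeks = 60)
  panel <- simulate_panel(cfg, seed = 43)
  fit <- fit_msm(panel)
  sj <- sojourn_times(fit)
  Q <- intensity_matrix(fit, "Europe")
  expect_equal(sj$mean, -1 / diag(Q), ignore_attr = TRUE)
  # single-exit state: se(mean) = se(log q) * mean exactly (delta method)
  tr <- tibble::tibble(from = c(1L, 2L), to = c(2L, 1L))
  fit2 <- fit_msm(dplyr::filter(panel, state != 3L) |>
                    dplyr::group_by(country) |>
                    dplyr::mutate(week = dplyr::row_number()) |>
                    dplyr::ungroup(),
                  transitions = tr, allow_gaps = FALSE)
  sj2 <- sojourn_times(fit2)
  se_logq <- fit2$std_errors[1:2]
  expect_equal(sj2$se[1:2], unname(se_logq * sj2$mean[1:2]),
               tolerance = 1e-6)
})

test_that("never-observed transitions hit the boundary and are flagged", {
  # two subjects oscillating 1 <-> 2 only
  panel <- tibble::tibble(
    country = rep(c("a", "b"), each = 20), region = "Asia",
    week = rep(1:20, 2), state = rep(rep(c(1L, 2L), 10), 2)
  )
  fit <- suppressWarnings(fit_msm(panel))
  expect_true(any(fit$nonidentified))
  expect_true(fit$nonidentified[["Very Unhealthy-Good"]])
  # states 3 never appears: all rates out of 3 are unsupported
  expect_true(all(fit$nonidentified[grepl("^Very", names(fit$nonidentified))]))
})

test_that("count-refit self-consistency: refitting data reconstructed from the
           fitted one-week chain reproduces the intensity matrix", {
  cfg <- sim_config(regions = list(Asia = list(n_subjects = 25)), n_weeks = 60)
  panel <- simulate_panel(cfg, seed = 44)
  fit <- fit_msm(panel)
  P1 <- transition_probability(intensity_matrix(fit, "Asia"), 1)
  # build a large pseudo-panel whose 1-week pairs follow P1 closely
  set.seed(45)
  big <- random_panel(list(Asia = intensity_matrix(fit, "Asia")),
                      n_subjects = 60, n_weeks = 120)
  refit <- fit_msm(big)
  expect_equal(intensity_matrix(refit, "Asia"),
               intensity_matrix(fit, "Asia"), tolerance = 0.25)
})

test_that("tidy and glance follow broom conventions", {
  cfg <- sim_config(regions = list(Asia = list(n_subjects = 10),
                                   Europe = list(n_subjects = 10)),
                    n_weeks = 40)
  fit <- fit_msm(simulate_panel(cfg, seed = 46))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "conf.low",
                    "conf.high") %in% names(td)))
  expect_equal(nrow(td), 12L)  # 6 baselines + 6 Asia coefficients
  expect_setequal(unique(td$type), c("log_intensity", "coefficient"))
  tde <- tidy(fit, exponentiate = TRUE)
  expect_equal(tde$estimate, exp(td$estimate))
  gl <- glance(fit)
  expect_equal(gl$nobs, 800L)
  expect_equal(gl$n_pairs, 780L)
  expect_true(gl$converged)
  expect_output(print(fit), "3-state")
})

test_that("time-homogeneity check: duplicated halves agree exactly, and the
           LR statistic is calibrated under the null", {
  cfg <- sim_config(regions = list(Asia = list(n_subjects = 12)), n_weeks = 40)
  half <- simulate_panel(cfg, seed = 47)
  doubled <- dplyr::bind_rows(
    half,
    dplyr::mutate(half, week = week + 40L)
  )
  chk <- time_homogeneity_check(doubled)
  expect_false(chk$underpowered)
  expect_equal(chk$Q_early$Asia, chk$Q_late$Asia)
  expect_gte(chk$statistic, 0)
  expect_equal(chk$df, 6L)
  expect_output(print(chk), "LR statistic")

  # null calibration: homogeneous data should rarely reject at alpha = 0.05
  set.seed(48)
  pvals <- replicate(12, {
    p <- simulate_panel(sim_config(
      regions = list(Asia = list(n_subjects = 15)), n_weeks = 60),
      seed = sample.int(1e6, 1))
    time_homogeneity_check(p)$p_value
  })
  expect_gte(mean(pvals > 0.01), 0.75)
})

test_that("underpowered halves are flagged without a statistic", {
  panel <- tibble::tibble(country = "a", region = "Asia", week = 1:8,
                          state = c(1L, 1L, 2L, 2L, 1L, 1L, 2L, 1L))
  chk <- suppressWarnings(time_homogeneity_check(panel))
  expect_true(chk$underpowered)
  expect_true(is.na(chk$statistic))
  expect_output(print(chk), "underpowered")
})
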