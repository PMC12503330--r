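test_that("default scenario mirrors the study shape", {
  cfg <- sim_config()
  panel <- simulate_panel(cfg, seed = 51)
  expect_equal(nrow(panel), 19 * 40)
  expect_equal(dplyr::n_distinct(panel$country), 19L)
  expect_equal(sort(unique(panel$region)), c("Africa", "Asia", "Europe"))
  expect_equal(max(panel$week), 40L)
  # region generator sojourns match the configured magnitudes
  Qs <- region_intensities()
  expect_equal(-1 / diag(Qs$Asia), c(6.80, 6.64, 3.36), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(-1 / diag(Qs$Europe), c(7.68, 0.90, 0.68), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(-1 / diag(Qs$Africa), c(4.57, 2.66, 0.95), tolerance = 1e-3,
               ignore_attr = TRUE)
  # Asia recovers from Unhealthy at 0.09 times Europe's rate
  expect_equal(Qs$Asia[2, 1] / Qs$Europe[2, 1], 0.09, tolerance = 1e-6)
})

test_that("simulation is reproducible from (config, seed)", {
  cfg <- sim_config(n_weeks = 20)
  expect_identical(simulate_panel(cfg, seed = 52), simulate_panel(cfg, seed = 52))
  expect_false(identical(simulate_panel(cfg, seed = 52),
                         simulate_panel(cfg, seed = 53)))
})

test_that("a zero intensity matrix yields a constant path", {
  Q <- matrix(0, 3, 3)
  path <- simulate_ctmc_path(Q, horizon = 10, initial_state = 2, seed = 54)
  expect_equal(nrow(path), 1L)
  expect_equal(sample_weekly(path, 10), rep(2L, 10))
})

test_that("holding times follow the exponential exit-rate law", {
  # mean holding time in Good over 10,000 completed visits ~ -1/q_11
  Q <- region_intensities()$Europe
  path <- simulate_ctmc_path(Q, horizon = 95000, initial_state = 1,
                             seed = 55)
  completed <- diff(path$time)
  holds <- completed[path$state[-nrow(path)] == 1]
  expect_gte(length(holds), 10000)
  holds <- holds[seq_len(10000)]
  expect_equal(mean(holds), -1 / Q[1, 1], tolerance = 0.02)
})

test_that("symmetric two-state chain spends half its time in each state", {
  Q <- matrix(c(-0.5, 0.5, 0, 0.5, -0.5, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  path <- simulate_ctmc_path(Q, horizon = 5000, initial_state = 1, seed = 56)
  segs <- diff(c(path$time, 5000))
  frac1 <- sum(segs[path$state == 1]) / 5000
  expect_equal(frac1, 0.5, tolerance = 0.05)
})

test_that("weekly sampling matches the one-week transition law", {
  Q <- region_intensities()$Africa
  cfg <- sim_config(regions = list(Africa = list(n_subjects = 120)),
                    n_weeks = 60)
  panel <- simulate_panel(cfg, seed = 57)
  counts <- count_transitions(panel)
  P_hat <- sweep(counts, 1, rowSums(counts), "/")
  P_true <- transition_probability(Q, 1)
  for (r in 1:3) {
    n_r <- rowSums(counts)[r]
    se <- sqrt(P_true[r, ] * (1 - P_true[r, ]) / n_r)
    expect_true(all(abs(P_hat[r, ] - P_true[r, ]) <= 3 * se + 1e-12))
  }
})

test_that("daily expansion round-trips through preprocessing when noiseless", {
  cfg <- sim_config(regions = list(Europe = list(n_subjects = 3)),
                    n_weeks = 8, daily_mode = TRUE, daily_noise_sd = 0,
                    missing_day_rate = 0)
  panel <- simulate_panel(cfg, seed = 58)
  day <- expand_to_daily(panel, cfg, seed = 59)
  weekly <- aggregate_weekly(day$daily)
  merged <- dplyr::inner_join(weekly, day$latent,
                              by = c("country", "region", "week"))
  expect_equal(merged$aqi, merged$latent_aqi, tolerance = 1e-9)
  expect_equal(merged$state,
               dplyr::inner_join(panel, day$latent,
                                 by = c("country", "region", "week"))$state)
  expect_false(any(weekly$imputed))
})

test_that("heavy missingness flags most weeks as imputed downstream", {
  cfg <- sim_config(regions = list(Europe = list(n_subjects = 3)),
                    n_weeks = 30, daily_mode = TRUE, daily_noise_sd = 5,
                    missing_day_rate = 0.6)
  panel <- simulate_panel(cfg, seed = 60)
  day <- expand_to_daily(panel, cfg, seed = 61)
  weekly <- aggregate_weekly(day$daily)
  expect_gt(mean(weekly$imputed), 0.5)
})

test_that("config validation rejects broken inputs", {
  expect_error(sim_config(n_weeks = 1), "n_weeks")
  expect_error(sim_config(missing_day_rate = 1), "missing_day_rate")
  badQ <- matrix(1, 3, 3)
  expect_error(sim_config(regions = list(X = list(n_subjects = 2, Q = badQ))))
  expect_error(sim_config(regions = list(Mars = list(n_subjects = 2))),
               "Mars")
})
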