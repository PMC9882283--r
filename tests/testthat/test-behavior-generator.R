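test_that("with all noise sources off, bids equal base value over budget", {
  cfg <- behavior_config(drift_sd = 0, bid_noise_sd = 0,
                         coef_starting_bid = 0, coef_total_liquid = 0,
                         coef_prev_comp_bid = 0, coef_prev_result = 0,
                         coef_win_streak = 0, coef_lose_streak = 0,
                         fail_rate = 0, n_trials = 50)
  s <- generate_session(cfg, seed = 1)
  expect_equal(s$bid, cfg$base_values_ml[s$magnitude_level] / cfg$budget_ml)
})

test_that("sessions and datasets are reproducible from their seeds", {
  cfg <- behavior_config(n_trials = 60)
  expect_identical(generate_session(cfg, seed = 7), generate_session(cfg, seed = 7))
  expect_identical(generate_dataset(cfg, 2, seed = 9), generate_dataset(cfg, 2, seed = 9))
  expect_false(identical(generate_session(cfg, seed = 7),
                         generate_session(cfg, seed = 8)))
})

test_that("generator refuses degenerate inputs", {
  expect_error(generate_session(behavior_config(n_trials = 5)), "at least 10")
  expect_error(behavior_config(base_values_ml = c(0.5, 0.4, 0.9)), "increasing")
  expect_error(behavior_config(drift_rho = 1), "drift_rho")
  expect_error(generate_dataset(behavior_config(), 0), "at least 1")
})

test_that("bids stay in the bid space and are rank-ordered by magnitude", {
  s <- quick_session(n = 500, seed = 3)
  expect_true(all(s$bid >= 0 & s$bid <= 1))
  means <- tapply(s$bid, s$magnitude_level, mean)
  expect_true(all(diff(means) > 0))
  tt <- trial_table(s)
  ct <- suppressWarnings(cor.test(tt$bid, tt$magnitude_ml,
                                  method = "spearman", exact = FALSE))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})

test_that("streaks, liquid accounting and failed-trial bookkeeping are consistent", {
  s <- quick_session(n = 400, seed = 5, fail_rate = 0.05)
  expect_true(all(diff(s$total_liquid_ml) >= 0))
  expect_true(all(s$win_streak >= 0) && all(s$lose_streak >= 0))
  expect_true(all(s$win_streak == 0 | s$lose_streak == 0))

  # recompute same-magnitude streaks from the outcome sequence
  for (m in 1:3) {
    idx <- which(s$magnitude_level == m & !s$failed)
    ws <- ls_ <- 0L
    for (i in idx) {
      expect_identical(s$win_streak[i], ws)
      expect_identical(s$lose_streak[i], ls_)
      if (s$won[i]) { ws <- ws + 1L; ls_ <- 0L } else { ls_ <- ls_ + 1L; ws <- 0L }
    }
  }

  # failed trials deliver nothing and are dropped from analysis tables
  failed <- s[s$failed, ]
  expect_true(all(is.na(failed$won)))
  expect_true(all(failed$juice_ml == 0 & failed$water_ml == 0))
  expect_false(any(trial_table(s)$failed))
})

test_that("between-session mean-bid variation comes from the latent drift", {
  with_drift <- behavior_config(drift_sd = 0.02, bid_noise_sd = 0.05, n_trials = 200)
  no_drift <- behavior_config(drift_sd = 0, bid_noise_sd = 0.05, n_trials = 200)
  # per-session mean of mid-magnitude bids, so the random magnitude mix does
  # not masquerade as day-to-day value variation
  mean_mid_bids <- function(cfg, seed) {
    vapply(generate_dataset(cfg, 25, seed = seed),
           function(s) mean(s$bid[s$magnitude_level == 2]), numeric(1))
  }
  sd_drift <- sd(mean_mid_bids(with_drift, 31))
  sd_flat <- sd(mean_mid_bids(no_drift, 31))
  expect_gt(sd_drift, 0)
  # without drift, session means differ only by averaged trial noise
  expect_lt(sd_flat, sd_drift / 2)
  expect_lt(sd_flat, 0.02)
})
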