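test_that("baseline spiking is Poisson at the configured rate", {
  s <- quick_session(n = 500, seed = 2)
  cfg <- neuron_config(baseline_hz = 5, attn_amp_hz = 0, value_gain_hz = 0,
                       include_water_cue = FALSE)
  rec <- simulate_neuron(s, cfg, seed = 8)
  # 1-s pre-cue epoch: mean count ~ 5 per trial
  pre <- rowSums(rec$rasters$fractal[, as.integer(colnames(rec$rasters$fractal)) < 0])
  expect_equal(mean(pre), 5, tolerance = 0.15)
  expect_equal(var(pre), 5, tolerance = 0.8)
})

test_that("simulation is reproducible and links only completed trials", {
  s <- quick_session(n = 200, seed = 3, fail_rate = 0.05)
  cfg <- neuron_config()
  expect_identical(simulate_neuron(s, cfg, seed = 4), simulate_neuron(s, cfg, seed = 4))
  rec <- simulate_neuron(s, cfg, seed = 4)
  expect_equal(nrow(rec$rasters$fractal), sum(!s$failed))
  expect_true(all(rec$trials$trial %in% s$trial[!s$failed]))
})

test_that("prediction error is positive for high and negative for low magnitudes", {
  s <- quick_session(n = 400, seed = 5)
  pe <- prediction_error(s)
  expect_gt(mean(pe[s$magnitude_level == 3]), 0)
  expect_lt(mean(pe[s$magnitude_level == 1]), 0)
})

test_that("value component produces magnitude-ordered excitation and depression", {
  s <- quick_session(n = 500, seed = 6)
  rec <- simulate_neuron(s, neuron_config(value_gain_hz = 15), seed = 7)
  w <- analysis_window(180, 360)
  resp <- windowed_response(rec, "fractal", w)
  base <- mean(baseline_response(rec))
  by_mag <- tapply(resp, rec$trials$magnitude_level, mean)
  expect_true(all(diff(by_mag) > 0))
  expect_gt(by_mag[3], base)   # positive prediction error: excitation
  expect_lt(by_mag[1], base)   # negative prediction error: depression
})

test_that("the attentional component alone carries no bid information", {
  s <- quick_session(n = 500, seed = 9)
  rec <- simulate_neuron(s, neuron_config(value_gain_hz = 0, attn_amp_hz = 20),
                         seed = 10)
  # value window excludes the attentional boxcar: regression should be null
  fit <- bid_regression(windowed_response(rec, "fractal", analysis_window(180, 360)),
                        rec$trials$bid)
  expect_gt(fit$p, 0.001)
  expect_lt(fit$r2, 0.05)
  # attention window response is flat across magnitudes
  attn <- windowed_response(rec, "fractal", analysis_window(100, 180))
  p_mag <- summary(lm(attn ~ rec$trials$magnitude_level))$coefficients[2, 4]
  expect_gt(p_mag, 0.01)
})

test_that("population simulation is reproducible and records ground truth", {
  ds <- generate_dataset(behavior_config(n_trials = 120), 2, seed = 11)
  p1 <- simulate_population(ds, n_bid_coders = 3, n_null_dopamine = 2,
                            n_non_dopamine = 2, seed = 12)
  p2 <- simulate_population(ds, n_bid_coders = 3, n_null_dopamine = 2,
                            n_non_dopamine = 2, seed = 12)
  expect_identical(p1, p2)
  expect_equal(nrow(p1$manifest), 7L)
  expect_true(all(p1$manifest$value_gain_hz[p1$manifest$type == "bid_coder"] > 0))
  expect_true(all(p1$manifest$value_gain_hz[p1$manifest$type != "bid_coder"] == 0))
  expect_true(all(p1$manifest$waveform_ms[p1$manifest$type == "non_dopamine"] < 1.8))
  expect_error(simulate_population(ds, 0, 0, 0), "empty")
})
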