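test_that("windowed responses average the expected rates", {
  # constant 10 Hz Poisson neuron
  set.seed(3)
  raster <- matrix(rpois(1000 * 500, 10 / 1000), 1000, 500,
                   dimnames = list(NULL, 0:499))
  rec <- manual_recording(raster)
  w <- analysis_window(180, 360)
  expect_equal(mean(windowed_response(rec, "fractal", w)), 10, tolerance = 0.3)

  # empty raster gives 0 Hz
  empty <- manual_recording(matrix(0, 20, 500, dimnames = list(NULL, 0:499)))
  expect_equal(windowed_response(empty, "fractal", w), rep(0, 20))

  # +20 Hz boxcar spanning exactly the window
  bc <- boxcar_counts(50, baseline_hz = 5, attn_hz = 0, value_hz = 20,
                      value_win = c(180, 360))
  rec_bc <- manual_recording(bc$counts, baseline = bc$baseline)
  expect_equal(mean(windowed_response(rec_bc, "fractal", w)), 25)
})

test_that("z-normalization is the baseline-referenced affine map", {
  set.seed(4)
  base <- rnorm(200, 10, 2)
  expect_equal(mean(znormalize(rnorm(500, 10, 2), base)), 0, tolerance = 0.2)
  expect_equal(znormalize(mean(base) + 2 * sd(base), base), 2)
  expect_error(znormalize(1:5, rep(3, 10)), "baseline SD")
  # invariance under affine rescaling of the rate scale
  resp <- rnorm(50, 12, 3)
  expect_equal(znormalize(2 * resp + 1, 2 * base + 1), znormalize(resp, base))
})

test_that("window detection recovers boxcar edges exactly on noise-free traces", {
  lo <- boxcar_counts(30, 6, attn_hz = 15, value_hz = -3)
  hi <- boxcar_counts(30, 6, attn_hz = 15, value_hz = 8)
  w <- determine_window(lo$counts, hi$counts, lo$baseline, hi$baseline)
  expect_s3_class(w, "analysis_window")
  expect_equal(w$start_ms, 180)
  expect_equal(w$end_ms, 360)  # trailing edge of the last significant bin
})

test_that("window detection flags flat or non-returning traces", {
  flat <- boxcar_counts(30, 6, attn_hz = 0, value_hz = 0)
  expect_warning(w <- determine_window(flat$counts, flat$counts,
                                       flat$baseline, flat$baseline),
                 "undetermined")
  expect_null(w)
  # excitation that never returns to baseline: no start can be set
  stuck <- boxcar_counts(30, 6, attn_hz = 10, value_hz = 10,
                         attn_win = c(100, 180), value_win = c(180, 500))
  expect_warning(w2 <- determine_window(stuck$counts, stuck$counts,
                                        stuck$baseline, stuck$baseline),
                 "undetermined")
  expect_null(w2)
  expect_error(analysis_window(170, 360), "multiples of 20")
})

test_that("bid binning follows the stated partition and quantile rules", {
  expect_equal(bin_bids(0.95, "tenths"), 10L)
  expect_equal(bin_bids(c(0, 0.1, 0.11), "tenths"), c(1L, 1L, 2L))
  expect_equal(bin_bids(0.45, "quintiles"), 3L)

  # uniform bids: tercile counts equal within 1
  set.seed(5)
  b <- runif(300)
  counts <- table(bin_bids(b, "terciles_skew_corrected"))
  expect_lte(diff(range(counts)), 1)

  # heavily tied distribution: rank rule gives sizes 4/3/3
  tied <- c(rep(0.1, 8), 0.5, 0.9)
  expect_equal(as.integer(table(bin_bids(tied, "terciles_skew_corrected"))),
               c(4L, 3L, 3L))
  expect_error(bin_bids(rep(0.4, 10), "terciles_skew_corrected"), "distinct")
})

test_that("bid regression reports exact fits and refuses degenerate input", {
  bids <- seq(0.05, 0.95, length.out = 20)
  fit <- bid_regression(2 * bids, bids)
  expect_equal(fit$beta1, 2)
  expect_equal(fit$r2, 1)
  expect_error(bid_regression(rnorm(20), rep(0.5, 20)), "constant")
  expect_error(bid_regression(rnorm(5), runif(5)), "at least 10")
})

test_that("classification cascade applies the dopamine criteria in order", {
  s <- quick_session(n = 300, seed = 12)
  w <- analysis_window(180, 360)

  # narrow waveform fails the dopamine criterion regardless of response
  narrow <- simulate_neuron(s, neuron_config(waveform_ms = 1.0), seed = 1)
  cl_narrow <- classify_neuron(narrow, w)
  expect_false(cl_narrow$is_dopamine)
  expect_false(cl_narrow$is_bid_encoding)

  # high baseline fails even with a wide waveform
  fast <- simulate_neuron(s, neuron_config(baseline_hz = 25), seed = 2)
  expect_false(classify_neuron(fast, w)$is_dopamine)

  # a strong bid coder passes all three stages
  coder <- simulate_neuron(s, neuron_config(value_gain_hz = 15), seed = 3)
  cl <- classify_neuron(coder, w)
  expect_true(cl$is_dopamine)
  expect_true(cl$is_value_responsive)
  expect_true(cl$is_bid_encoding)
  expect_gt(cl$bid_slope, 0)

  # classification order-independence across input orderings
  pop <- simulate_population(s, n_bid_coders = 3, n_null_dopamine = 2, seed = 4)
  fwd <- classify_population(pop$recordings, w)
  rev_ <- classify_population(rev(pop$recordings), w)
  expect_equal(fwd[order(fwd$neuron_id), ],
               rev_[order(rev_$neuron_id), ], ignore_attr = TRUE)
})

test_that("missing water cue is flagged and classification falls back to the fractal", {
  s <- quick_session(n = 200, seed = 13)
  rec <- simulate_neuron(s, neuron_config(include_water_cue = FALSE,
                                          value_gain_hz = 15), seed = 5)
  cl <- classify_neuron(rec, analysis_window(180, 360))
  expect_true(cl$water_cue_missing)
  expect_true(is.na(cl$value_p_water_cue))
  expect_true(cl$is_value_responsive)
})

test_that("per-magnitude regressions separate bid coding from magnitude coding", {
  ds <- generate_dataset(subject_profile("decoding", n_trials = 400), 4, seed = 31)
  w <- analysis_window(180, 360)

  bid_pop <- simulate_population(ds, n_bid_coders = 8, seed = 32)
  tbl <- response_table(bid_pop$recordings, w)
  per_mag <- magnitude_regression_constant_magnitude(tbl)
  expect_named(per_mag, c("low", "mid", "high"))
  for (fit in per_mag) {
    expect_gt(fit$beta1, 0)
    expect_lt(fit$p, 0.01)
  }

  # pure magnitude coder: no bid slope within a constant magnitude
  mag_cfg <- neuron_config(value_gain_hz = 0)
  mag_pop <- simulate_population(ds, n_bid_coders = 8, config = mag_cfg,
                                 magnitude_gain_hz = 6, seed = 33)
  tbl_mag <- response_table(mag_pop$recordings, w)
  per_mag2 <- magnitude_regression_constant_magnitude(tbl_mag)
  expect_gt(per_mag2$mid$p, 0.01)
  expect_lt(per_mag2$mid$r2, 0.02)
})

test_that("matched-bid comparison handles disjoint ranges and detects injected effects", {
  # disjoint bid ranges across magnitudes: nothing to match
  s <- manual_session(rep(c(1L, 2L), 30), runif(60),
                      bid = ifelse(rep(c(1, 2), 30) == 1,
                                   runif(60, 0, 0.2), runif(60, 0.6, 0.9)))
  raster <- matrix(1, 60, 500, dimnames = list(NULL, 0:499))
  set.seed(6)
  base <- matrix(rpois(60 * 500, 0.006), 60, 500, dimnames = list(NULL, -1000:-501))
  rec <- manual_recording(raster, bids = s$bid, baseline = base,
                          magnitude_level = s$magnitude_level)
  tbl <- response_table(list(rec), analysis_window(180, 360))
  res <- matched_bid_comparison(tbl, c(1, 2))
  expect_true(res$missing)
  expect_true(is.na(res$p))

  # injected magnitude effect is detected as a positive median difference
  ds <- generate_dataset(subject_profile("decoding", n_trials = 300), 4, seed = 41)
  w <- analysis_window(180, 360)
  pop <- simulate_population(ds, n_bid_coders = 8, magnitude_gain_hz = 5.8,
                             seed = 42)
  tblm <- response_table(pop$recordings, w)
  resm <- matched_bid_comparison(tblm, c(1, 3))
  expect_false(resm$missing)
  expect_lt(resm$p, 0.05)
  expect_gt(resm$median_diff, 0)
})

test_that("movement regressions are calibrated on movement-decoupled neurons", {
  ds <- generate_dataset(subject_profile("decoding", n_trials = 300), 4, seed = 51)
  pop <- simulate_population(ds, n_bid_coders = 0, n_null_dopamine = 40, seed = 52)
  tbl <- response_table(pop$recordings, analysis_window(180, 360))
  mv <- movement_control_regressions(tbl)
  expect_equal(nrow(mv), 4L)
  expect_equal(mv$n_neurons, rep(40L, 4))
  # null neurons: significant counts stay near the 5% chance level
  expect_true(all(mv$n_significant / mv$n_neurons <= 0.2))
})
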