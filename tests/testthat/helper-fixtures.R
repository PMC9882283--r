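# Shared fixtures, all generated in code at test time.

# small, fast behavioral session
quick_session <- function(n = 120, seed = 1, subject = "V", ...) {
  generate_session(subject_profile(subject, n_trials = n, ...), seed = seed)
}

# hand-built session carrying only the columns the analyses touch
manual_session <- function(magnitude_level, computer_bid,
                           bid = rep(0.5, length(magnitude_level)),
                           won = rep(TRUE, length(magnitude_level)),
                           failed = rep(FALSE, length(magnitude_level)),
                           budget = 1.2) {
  n <- length(magnitude_level)
  mags <- c(0.3, 1.0, 1.7)
  df <- data.frame(
    trial = seq_len(n), session_id = 1L, subject_id = "manual",
    session_number = 1L, day_of_week = 1L,
    magnitude_level = magnitude_level, magnitude_ml = mags[magnitude_level],
    latent_value_ml = bid * budget, starting_bid = 0.5, bid = bid,
    computer_bid = computer_bid, won = won,
    juice_ml = ifelse(won, mags[magnitude_level], 0),
    water_ml = budget * (1 - ifelse(won, computer_bid, 0)),
    price_paid = ifelse(won, computer_bid, 0),
    total_liquid_ml = 0, win_streak = 0L, lose_streak = 0L,
    prev_same_mag_comp_bid = NA_real_, prev_same_mag_result = NA,
    movement_velocity = 0, movement_absement = 0, failed = failed)
  # same-magnitude history consistent with the outcome sequence
  for (m in unique(magnitude_level)) {
    idx <- which(magnitude_level == m & !failed)
    ws <- ls_ <- 0L
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (k > 1) {
        df$prev_same_mag_comp_bid[i] <- computer_bid[idx[k - 1]]
        df$prev_same_mag_result[i] <- won[idx[k - 1]]
      }
      df$win_streak[i] <- ws
      df$lose_streak[i] <- ls_
      if (won[i]) { ws <- ws + 1L; ls_ <- 0L } else { ls_ <- ls_ + 1L; ws <- 0L }
    }
  }
  attr(df, "config") <- behavior_config(n_trials = max(n, 10L))
  class(df) <- c("bdm_session", "data.frame")
  df
}

# deterministic (noise-free) count matrices with attention and value boxcars
boxcar_counts <- function(n_trials, baseline_hz, attn_hz, value_hz,
                          attn_win = c(100, 180), value_win = c(180, 350),
                          poisson_seed = NULL) {
  rate <- matrix(baseline_hz, n_trials, 500)
  rate[, (attn_win[1] + 1):attn_win[2]] <-
    rate[, (attn_win[1] + 1):attn_win[2]] + attn_hz
  rate[, (value_win[1] + 1):value_win[2]] <-
    rate[, (value_win[1] + 1):value_win[2]] + value_hz
  rate[rate < 0] <- 0
  base <- matrix(baseline_hz, n_trials, 500)
  if (!is.null(poisson_seed)) {
    set.seed(poisson_seed)
    counts <- matrix(rpois(length(rate), rate / 1000), n_trials, 500)
    baseline <- matrix(rpois(length(base), base / 1000), n_trials, 500)
  } else {
    counts <- rate / 1000
    baseline <- base / 1000
  }
  dimnames(counts) <- list(NULL, 0:499)
  dimnames(baseline) <- list(NULL, -1000:-501)
  list(counts = counts, baseline = baseline)
}

# minimal hand-built recording with given fractal raster
manual_recording <- function(raster, bids = NULL, baseline = NULL,
                             waveform_ms = 2.5, magnitude_level = NULL) {
  n <- nrow(raster)
  if (is.null(bids)) bids <- seq(0, 1, length.out = n)
  if (is.null(baseline)) {
    baseline <- matrix(0, n, 500, dimnames = list(NULL, -1000:-501))
  }
  if (is.null(magnitude_level)) magnitude_level <- rep(1:3, length.out = n)
  rasters <- list(fractal = cbind(baseline, raster))
  structure(list(
    neuron_id = "manual", waveform_ms = waveform_ms, config = NULL,
    session_id = 1L,
    trials = data.frame(trial = seq_len(n), bid = bids,
                        magnitude_level = magnitude_level,
                        magnitude_ml = c(0.3, 1.0, 1.7)[magnitude_level],
                        movement_velocity = 0, movement_absement = 0),
    rasters = rasters, baseline_window = c(-1000, -500)),
    class = "neuron_recording")
}

# synthetic per-neuron decoding tables without any spiking machinery
synthetic_decoding_tab <- function(n_per_cat = 30, noise_sd = 0, slope = 1,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bids <- runif(10 * n_per_cat, rep((0:9) / 10, each = n_per_cat) + 1e-6,
                rep((1:10) / 10, each = n_per_cat))
  data.frame(bid = bids,
             response = slope * bids + rnorm(length(bids), 0, noise_sd),
             category = discretize_for_decoding(bids))
}
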