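#' Configuration of the synthetic dopamine-neuron generator
#'
#' Spiking is an inhomogeneous Poisson process in 1-ms bins. The cue response
#' has two boxcar components: an initial "attentional" excitation that is
#' identical across magnitudes and bids, and a later "value" component whose
#' rate change is \code{value_gain_hz} times the trial's reward prediction
#' error plus \code{magnitude_gain_hz} times the centered magnitude level.
#' The prediction error is the bid-implied subjective value (bid times budget)
#' minus the mean of the three base subjective values, i.e. the prediction
#' standing at the trial-start cross before the magnitude cue appears. Rates
#' are floored at 0 Hz after summing components, so negative prediction
#' errors express as bounded suppression.
#'
#' Putative dopamine neurons have wide waveforms (> 1.8 ms) and low baseline
#' rates (< 10 Hz); set \code{waveform_ms} and \code{baseline_hz} accordingly
#' (or violate them to generate non-dopamine neurons).
#'
#' @param baseline_hz Baseline firing rate (Hz).
#' @param waveform_ms Spike waveform width flag (ms).
#' @param attn_amp_hz,attn_onset_ms,attn_dur_ms Attentional boxcar: amplitude
#'   above baseline and window \code{[onset, onset + dur)} after cue onset.
#' @param value_gain_hz Rate change per ml of prediction error (Hz/ml); 0 for
#'   null (non-coding) dopamine neurons.
#' @param neg_scale Relative scaling of the response to negative prediction
#'   errors (default 0.4): dopamine suppression is weaker than excitation
#'   because the low firing rate leaves little room below baseline, so the
#'   value component is \code{value_gain_hz * pe} for positive and
#'   \code{value_gain_hz * neg_scale * pe} for negative prediction errors.
#'   This asymmetry bends the population bid-response curve and keeps the
#'   bin-averaged population regression away from a perfect straight-line
#'   fit, as in recorded populations.
#' @param value_onset_ms,value_offset_ms Value boxcar window after cue onset
#'   (\code{onset < offset}).
#' @param magnitude_gain_hz Direct magnitude coding (Hz per centered magnitude
#'   level); 0 for pure bid coders.
#' @param include_water_cue Also simulate a raster aligned to the computer-bid
#'   onset (the water-payout cue), carrying the same value component.
#' @param seed Default RNG seed used by [simulate_neuron()].
#' @return An object of class \code{neuron_config}.
#' @export
neuron_config <- function(baseline_hz = 6, waveform_ms = 2.5,
                          attn_amp_hz = 15, attn_onset_ms = 100,
                          attn_dur_ms = 80,
                          value_gain_hz = 12, value_onset_ms = 180,
                          value_offset_ms = 360,
                          neg_scale = 0.4,
                          magnitude_gain_hz = 0,
                          include_water_cue = TRUE,
                          seed = NULL) {
  if (baseline_hz < 0) stop_domain("baseline_hz must be non-negative")
  if (value_onset_ms >= value_offset_ms)
    stop_domain("value_onset_ms must precede value_offset_ms")
  if (attn_dur_ms < 0) stop_domain("attn_dur_ms must be non-negative")
  if (neg_scale < 0) stop_domain("neg_scale must be non-negative")
  structure(list(baseline_hz = baseline_hz, waveform_ms = waveform_ms,
                 attn_amp_hz = attn_amp_hz, attn_onset_ms = attn_onset_ms,
                 attn_dur_ms = attn_dur_ms,
                 value_gain_hz = value_gain_hz, neg_scale = neg_scale,
                 value_onset_ms = value_onset_ms,
                 value_offset_ms = value_offset_ms,
                 magnitude_gain_hz = magnitude_gain_hz,
                 include_water_cue = include_water_cue,
                 seed = seed),
            class = "neuron_config")
}

#' @export
print.neuron_config <- function(x, ...) {
  cat("Synthetic neuron: baseline", x$baseline_hz, "Hz, waveform",
      x$waveform_ms, "ms\n  attention +", x$attn_amp_hz, "Hz @ [",
      x$attn_onset_ms, ",", x$attn_onset_ms + x$attn_dur_ms,
      ") ms; value gain", x$value_gain_hz, "Hz/ml @ [",
      x$value_onset_ms, ",", x$value_offset_ms, ") ms; magnitude gain",
      x$magnitude_gain_hz, "Hz\n")
  invisible(x)
}

#' Trial-by-trial reward prediction error implied by the bids
#'
#' The signed prediction error at magnitude-cue onset: the bid-implied
#' subjective value (bid times budget) minus the mean of the three base
#' subjective values, which is the value prediction standing at the preceding
#' trial-start cross. Positive for high magnitudes and negative for low
#' magnitudes under rank-ordered bidding.
#'
#' @param session A \code{bdm_session} (its generator config supplies the base
#'   values and budget).
#' @return Numeric vector, one prediction error (water-equivalent ml) per
#'   trial row of \code{session}.
#' @export
prediction_error <- function(session) {
  cfg <- attr(session, "config")
  if (is.null(cfg)) stop_domain("session carries no generator config")
  session$bid * cfg$budget_ml - mean(cfg$base_values_ml)
}

# raster of 1-ms Poisson counts for a vector of per-trial value-driver rates
poisson_raster <- function(rate_base_hz, times_ms, attn, value_delta_hz,
                           value_win, attn_win) {
  n <- length(value_delta_hz)
  rate <- matrix(rate_base_hz, nrow = n, ncol = length(times_ms))
  in_attn <- times_ms >= attn_win[1] & times_ms < attn_win[2]
  rate[, in_attn] <- rate[, in_attn] + attn
  in_val <- times_ms >= value_win[1] & times_ms < value_win[2]
  rate[, in_val] <- rate[, in_val] + value_delta_hz
  rate[rate < 0] <- 0
  counts <- matrix(stats::rpois(length(rate), rate / 1000),
                   nrow = n, dimnames = list(NULL, times_ms))
  counts
}

#' Simulate a neuron's spike rasters over a behavioral session
#'
#' For every completed trial, 1-ms-binned Poisson spike counts are drawn for
#' a raster aligned to the magnitude-cue (fractal) onset spanning -1000 to
#' +799 ms (the trial-start cross precedes the cue by 500 ms, so the baseline
#' epoch 0-500 ms before the cross occupies raster times -1000 to -501 ms)
#' and, optionally, a raster aligned to the computer-bid onset (water cue)
#' spanning 0 to +799 ms.
#'
#' @param session A \code{bdm_session}.
#' @param config A [neuron_config()].
#' @param neuron_id Identifier.
#' @param seed RNG seed (defaults to \code{config$seed}).
#' @return An object of class \code{neuron_recording}: a list with
#'   \code{neuron_id}, \code{waveform_ms}, \code{config}, \code{trials} (the
#'   completed trials' \code{trial}, \code{bid}, \code{magnitude_level},
#'   \code{magnitude_ml}, movement features), \code{rasters} (named list of
#'   integer count matrices, trials x 1-ms bins, column names = time in ms
#'   relative to the alignment event), and \code{baseline_window} (times, in
#'   fractal-aligned ms, of the pre-cross baseline epoch).
#' @export
simulate_neuron <- function(session, config = neuron_config(),
                            neuron_id = "n1", seed = NULL) {
  stopifnot(inherits(session, "bdm_session"))
  trials <- trial_table(session, completed_only = TRUE)
  if (nrow(trials) == 0L) stop_domain("session has no completed trials")
  seed <- seed %||% config$seed

  pe <- prediction_error(session)[!session$failed]
  pe_scaled <- ifelse(pe >= 0, pe, config$neg_scale * pe)
  mag_z <- trials$magnitude_level - 2
  value_delta <- config$value_gain_hz * pe_scaled +
    config$magnitude_gain_hz * mag_z
  attn_win <- c(config$attn_onset_ms, config$attn_onset_ms + config$attn_dur_ms)
  val_win <- c(config$value_onset_ms, config$value_offset_ms)

  with_seed(seed, {
    rasters <- list(
      fractal = poisson_raster(config$baseline_hz, -1000:799,
                               config$attn_amp_hz, value_delta,
                               val_win, attn_win)
    )
    if (config$include_water_cue) {
      rasters$water_cue <- poisson_raster(config$baseline_hz, 0:799,
                                          config$attn_amp_hz, value_delta,
                                          val_win, attn_win)
    }
    structure(list(
      neuron_id = neuron_id,
      waveform_ms = config$waveform_ms,
      config = config,
      session_id = trials$session_id[1],
      trials = trials[, c("trial", "bid", "magnitude_level", "magnitude_ml",
                          "movement_velocity", "movement_absement")],
      rasters = rasters,
      baseline_window = c(-1000, -500)
    ), class = "neuron_recording")
  })
}

#' @export
print.neuron_recording <- function(x, ...) {
  cat("Neuron", x$neuron_id, "- waveform", x$waveform_ms, "ms,",
      nrow(x$trials), "trials, events:",
      paste(names(x$rasters), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a population of non-simultaneously recorded neurons
#'
#' Neurons are simulated independently, each on one session of
#' \code{dataset} (cycled in order), emulating recordings collected across
#' days. Three cell types are generated: bid coders (positive value gain,
#' jittered around \code{config$value_gain_hz}), null dopamine neurons (zero
#' value gain), and non-dopamine neurons (narrow waveform, high baseline, no
#' value component). Ground-truth gains per neuron are recorded in the
#' manifest.
#'
#' @param dataset A \code{bdm_dataset} (or a single \code{bdm_session}).
#' @param n_bid_coders,n_null_dopamine,n_non_dopamine Cell-type counts.
#' @param config Baseline [neuron_config()] for dopamine-like cells.
#' @param gain_jitter Bid coders' value gains are drawn uniformly in
#'   \code{config$value_gain_hz * (1 +/- gain_jitter)} (heterogeneous
#'   effect sizes); 0 for identical gains.
#' @param magnitude_gain_hz Magnitude gain given to bid coders (default 0 =
#'   pure bid coding).
#' @param seed Population seed; per-neuron seeds are derived from it.
#' @return An object of class \code{neuron_population}: list with
#'   \code{recordings} (list of \code{neuron_recording}) and \code{manifest}
#'   (data frame of ground-truth parameters per neuron).
#' @export
simulate_population <- function(dataset, n_bid_coders = 20L,
                                n_null_dopamine = 0L, n_non_dopamine = 0L,
                                config = neuron_config(),
                                gain_jitter = 0.5,
                                magnitude_gain_hz = 0,
                                seed = 1L) {
  if (inherits(dataset, "bdm_session")) dataset <- structure(list(dataset), class = "bdm_dataset")
  n_total <- n_bid_coders + n_null_dopamine + n_non_dopamine
  if (n_total < 1L) stop_domain("population is empty")
  types <- rep(c("bid_coder", "null_dopamine", "non_dopamine"),
               c(n_bid_coders, n_null_dopamine, n_non_dopamine))
  seeds <- derive_seeds(seed, n_total + 1L)
  gains <- with_seed(seeds[[n_total + 1L]], {
    g <- numeric(n_total)
    bc <- types == "bid_coder"
    g[bc] <- config$value_gain_hz *
      stats::runif(sum(bc), 1 - gain_jitter, 1 + gain_jitter)
    g
  })

  recordings <- vector("list", n_total)
  manifest <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    sess <- dataset[[((i - 1L) %% length(dataset)) + 1L]]
    cfg_i <- config
    cfg_i$value_gain_hz <- gains[i]
    cfg_i$magnitude_gain_hz <- if (types[i] == "bid_coder") magnitude_gain_hz else 0
    if (types[i] == "non_dopamine") {
      cfg_i$waveform_ms <- 0.8
      cfg_i$baseline_hz <- 25
      cfg_i$value_gain_hz <- 0
      cfg_i$magnitude_gain_hz <- 0
    }
    id <- sprintf("%s_%03d", switch(types[i], bid_coder = "bc",
                                    null_dopamine = "nd", non_dopamine = "xx"), i)
    recordings[[i]] <- simulate_neuron(sess, cfg_i, neuron_id = id,
                                       seed = seeds[[i]])
    manifest[[i]] <- data.frame(
      neuron_id = id, type = types[i],
      session_id = sess$session_id[1],
      value_gain_hz = cfg_i$value_gain_hz,
      magnitude_gain_hz = cfg_i$magnitude_gain_hz,
      waveform_ms = cfg_i$waveform_ms,
      baseline_hz = cfg_i$baseline_hz
    )
  }
  structure(list(recordings = recordings,
                 manifest = do.call(rbind, manifest)),
            class = "neuron_population")
}

#' @export
print.neuron_population <- function(x, ...) {
  cat("Neuron population:", nrow(x$manifest), "neurons (",
      paste(names(table(x$manifest$type)), table(x$manifest$type),
            collapse = ", "), ")\n")
  invisible(x)
}
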