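#' Analysis window relative to cue onset
#'
#' Windows are constrained to \code{[0, 500]} ms after the magnitude cue with
#' both edges on the 20-ms grid, matching the resolution of the
#' window-determination algorithm.
#'
#' @param start_ms,end_ms Window edges in ms (multiples of 20,
#'   \code{0 <= start < end <= 500}).
#' @return An object of class \code{analysis_window}.
#' @export
analysis_window <- function(start_ms, end_ms) {
  if (start_ms %% 20 != 0 || end_ms %% 20 != 0)
    stop_domain("window edges must be multiples of 20 ms")
  if (start_ms < 0 || end_ms > 500 || start_ms >= end_ms)
    stop_domain("need 0 <= start < end <= 500")
  structure(list(start_ms = start_ms, end_ms = end_ms),
            class = "analysis_window")
}

#' @export
print.analysis_window <- function(x, ...) {
  cat("Analysis window [", x$start_ms, ",", x$end_ms, ") ms\n")
  invisible(x)
}

# count submatrix of an event raster for times in [from, to)
event_counts <- function(recording, event = "fractal", from = 0, to = 500) {
  raster <- recording$rasters[[event]]
  if (is.null(raster)) stop_domain("recording has no raster for event ", event)
  times <- as.integer(colnames(raster))
  raster[, times >= from & times < to, drop = FALSE]
}

# per-trial baseline counts (1-ms bins over the 500-ms pre-cross epoch)
baseline_counts <- function(recording) {
  event_counts(recording, "fractal",
               recording$baseline_window[1], recording$baseline_window[2])
}

#' Per-trial windowed firing rates
#'
#' Spike count inside the analysis window divided by window duration, per
#' trial (Hz). Never smoothed: smoothing is reserved for displayed traces.
#'
#' @param recording A \code{neuron_recording}.
#' @param event Raster name (\code{"fractal"} or \code{"water_cue"}).
#' @param window An [analysis_window()] (or list with \code{start_ms},
#'   \code{end_ms}).
#' @return Numeric vector of rates, one per trial.
#' @export
windowed_response <- function(recording, event = "fractal",
                              window = analysis_window(180, 360)) {
  cm <- event_counts(recording, event, window$start_ms, window$end_ms)
  rowSums(cm) / ((window$end_ms - window$start_ms) / 1000)
}

#' Per-trial baseline firing rates
#'
#' Rates over the 0-500 ms epoch before the trial-start (fixation) cross.
#'
#' @param recording A \code{neuron_recording}.
#' @return Numeric vector of rates (Hz), one per trial.
#' @export
baseline_response <- function(recording) {
  rowSums(baseline_counts(recording)) / 0.5
}

#' Z-normalize responses against a baseline distribution
#'
#' \code{(response - mean(baseline)) / sd(baseline)}, the normalization used
#' for all group-level analyses so that no neuron dominates by firing rate.
#'
#' @param responses Numeric vector of per-trial responses.
#' @param baseline Numeric vector of per-trial baseline responses for the same
#'   neuron.
#' @return Z-scored responses.
#' @export
znormalize <- function(responses, baseline) {
  s <- stats::sd(baseline)
  if (!is.finite(s) || s == 0)
    stop_domain("baseline SD is zero; neuron must be excluded from group analyses")
  (responses - mean(baseline)) / s
}

#' Trial-averaged peri-stimulus rate trace
#'
#' @param recording A \code{neuron_recording}.
#' @param event Raster name.
#' @param smooth_ms Moving-average width in ms (0 = none). Smoothing is for
#'   display only and is never applied to windowed scalar statistics.
#' @param trials Optional logical/integer subset of trials.
#' @return A data frame with \code{time_ms} and \code{rate_hz}.
#' @export
psth <- function(recording, event = "fractal", smooth_ms = 80, trials = NULL) {
  raster <- recording$rasters[[event]]
  if (is.null(raster)) stop_domain("no raster for event ", event)
  if (!is.null(trials)) raster <- raster[trials, , drop = FALSE]
  rate <- colMeans(raster) * 1000
  if (smooth_ms > 0) {
    k <- rep(1 / smooth_ms, smooth_ms)
    rate <- stats::filter(rate, k, sides = 2)
  }
  data.frame(time_ms = as.integer(colnames(raster)), rate_hz = as.numeric(rate))
}

#' Determine the value-component analysis window from count matrices
#'
#' Implements the two-sided window rule: the window starts where the initial
#' ("attentional") component of the lowest-magnitude averaged response returns
#' to the baseline mean, and ends at the last 20-ms bin in \code{[0, 500]} ms
#' where the highest-magnitude response still differs significantly from
#' baseline (Wilcoxon sign-rank across trials, Bonferroni-Holm correction over
#' the 25 bins); the end edge is the trailing edge of that bin. The start rule
#' operates on the 20-ms-binned averaged trace (first bin at/after the peak
#' bin whose mean falls to or below the baseline mean; the window starts at
#' that bin's leading edge), which is the 20-ms rounding of the crossing. The
#' sign-rank test compares each trial's 20-ms window count against the
#' duration-matched 20-ms bin of that trial's baseline epoch, so the null
#' distribution of differences is symmetric even at low Poisson rates.
#'
#' @param low_counts,high_counts Integer matrices (trials x 1-ms bins) of
#'   post-cue counts for the lowest and highest magnitude, columns named with
#'   times 0..499.
#' @param low_baseline,high_baseline Matching baseline count matrices
#'   (trials x 500 1-ms bins).
#' @param bin_ms Bin width of the grid (default 20 ms).
#' @param alpha Significance level for the end-of-window test.
#' @return An [analysis_window()], or \code{NULL} (with a warning) when no
#'   window can be determined (flat trace, no baseline return, or no
#'   significant response).
#' @export
determine_window <- function(low_counts, high_counts,
                             low_baseline, high_baseline,
                             bin_ms = 20, alpha = 0.05) {
  if (nrow(low_counts) < 20L || nrow(high_counts) < 20L)
    stop_domain("need at least 20 trials per magnitude")
  t_max <- ncol(low_counts)
  n_bins <- t_max %/% bin_ms
  bin_cols <- function(j) ((j - 1) * bin_ms + 1):(j * bin_ms)

  base_mean_hz <- sum(low_baseline) / (nrow(low_baseline) * ncol(low_baseline)) * 1000
  low_bin_hz <- vapply(seq_len(n_bins), function(j)
    mean(low_counts[, bin_cols(j), drop = FALSE]) * 1000, numeric(1))

  peak <- which.max(low_bin_hz)
  if (low_bin_hz[peak] <= base_mean_hz) {
    warning("no initial component above baseline; window undetermined")
    return(NULL)
  }
  cross <- which(low_bin_hz <= base_mean_hz & seq_len(n_bins) >= peak)
  if (length(cross) == 0L) {
    warning("trace never returns to baseline mean; window undetermined")
    return(NULL)
  }
  start_ms <- (min(cross) - 1L) * bin_ms

  p <- vapply(seq_len(n_bins), function(j) {
    d <- rowSums(high_counts[, bin_cols(j), drop = FALSE]) -
      rowSums(high_baseline[, bin_cols(j), drop = FALSE])
    if (all(d == 0)) return(NA_real_)
    suppressWarnings(stats::wilcox.test(d, mu = 0, exact = FALSE)$p.value)
  }, numeric(1))
  sig <- which(stats::p.adjust(p, method = "holm") < alpha)
  if (length(sig) == 0L) {
    warning("no significant response bins; window undetermined")
    return(NULL)
  }
  end_ms <- max(sig) * bin_ms
  if (end_ms <= start_ms) {
    warning("no significant bins after the initial component; window undetermined")
    return(NULL)
  }
  analysis_window(start_ms, end_ms)
}

#' Determine the analysis window from a recorded population
#'
#' Stacks per-trial post-cue and baseline count matrices across neurons for
#' the lowest- and highest-magnitude trials and applies [determine_window()],
#' the per-animal procedure.
#'
#' @param recordings List of \code{neuron_recording} objects.
#' @param ... Passed to [determine_window()].
#' @return An [analysis_window()] or \code{NULL}.
#' @export
population_analysis_window <- function(recordings, ...) {
  pull <- function(level) {
    cnt <- lapply(recordings, function(r) {
      sel <- r$trials$magnitude_level == level
      list(counts = event_counts(r, "fractal", 0, 500)[sel, , drop = FALSE],
           baseline = baseline_counts(r)[sel, , drop = FALSE])
    })
    list(counts = do.call(rbind, lapply(cnt, `[[`, "counts")),
         baseline = do.call(rbind, lapply(cnt, `[[`, "baseline")))
  }
  lo <- pull(1L)
  hi <- pull(max(vapply(recordings, function(r) max(r$trials$magnitude_level),
                        numeric(1))))
  determine_window(lo$counts, hi$counts, lo$baseline, hi$baseline, ...)
}

#' Simple linear regression of responses on bids
#'
#' The single-neuron (and, on z-scores or bin averages, group-level) test of
#' bid encoding: ordinary least squares of the windowed response on the bid,
#' \code{y = b0 + b1 * bid}.
#'
#' @param responses Per-trial scalar responses (raw rates for single neurons,
#'   z-scores for groups, or bin averages).
#' @param bids Normalized bids, same length.
#' @param min_trials Minimum number of observations (default 10).
#' @return An object of class \code{bid_regression}: \code{beta0},
#'   \code{beta1}, \code{r2}, \code{p} (slope test), \code{n}.
#' @export
bid_regression <- function(responses, bids, min_trials = 10L) {
  if (length(responses) != length(bids))
    stop_domain("responses and bids must have equal length")
  keep <- is.finite(responses) & is.finite(bids)
  responses <- responses[keep]; bids <- bids[keep]
  if (length(bids) < min_trials)
    stop_domain("need at least ", min_trials, " trials")
  if (stats::sd(bids) == 0) stop_domain("bids are constant")
  fit <- stats::lm(responses ~ bids)
  sm <- suppressWarnings(summary(fit))  # exact fits trip lm's rounding warning
  structure(list(beta0 = unname(stats::coef(fit)[1]),
                 beta1 = unname(stats::coef(fit)[2]),
                 r2 = sm$r.squared,
                 p = sm$coefficients["bids", "Pr(>|t|)"],
                 n = length(bids)),
            class = "bid_regression")
}

#' @export
print.bid_regression <- function(x, ...) {
  cat(sprintf("Bid regression: slope %.3f, R2 %.3f, p %.3g (n = %d)\n",
              x$beta1, x$r2, x$p, x$n))
  invisible(x)
}

#' Discretize bids into bins
#'
#' \code{"tenths"} and \code{"quintiles"} are fixed equal-width partitions of
#' the \code{[0, 1]} bid space (right-closed: a bid of exactly 0.1 falls in
#' the first tenth). \code{"terciles_skew_corrected"} assigns equal counts by
#' bid rank (ties split in order of occurrence), which corrects for the
#' skewness of each empirical bid distribution.
#'
#' @param bids Normalized bids.
#' @param scheme Binning scheme.
#' @return Integer bin labels (1 = lowest).
#' @export
bin_bids <- function(bids, scheme = c("tenths", "quintiles",
                                      "terciles_skew_corrected")) {
  scheme <- match.arg(scheme)
  check_bid(bids)
  if (scheme %in% c("tenths", "quintiles")) {
    k <- if (scheme == "tenths") 10L else 5L
    b <- ceiling(bids * k)
    b[b < 1L] <- 1L
    return(as.integer(b))
  }
  k <- 3L
  if (length(unique(bids)) < k)
    stop_domain("need at least ", k, " distinct bid values for quantile bins")
  n <- length(bids)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- integer(n)
  labels[order(bids)] <- rep(seq_len(k), sizes)
  labels
}

#' Group-level regression on bin-averaged responses
#'
#' Splits the bid space into \code{n_bins} equal-width bins, averages the
#' (z-normalized) responses within bins, and regresses the bin means on the
#' bin-mean bids; empty bins are dropped. With 25 bins this is the
#' population-level summary fit of normalized dopamine activity against bids.
#'
#' @param responses Z-scored responses pooled over neurons.
#' @param bids Matching bids.
#' @param n_bins Number of equal-width bins (default 25).
#' @return A \code{bid_regression} on the bin averages, with the bin table in
#'   \code{attr(, "bins")}.
#' @export
binned_population_regression <- function(responses, bids, n_bins = 25L) {
  check_bid(bids)
  b <- ceiling(bids * n_bins)
  b[b < 1L] <- 1L
  mean_resp <- tapply(responses, b, mean)
  mean_bid <- tapply(bids, b, mean)
  res <- bid_regression(as.numeric(mean_resp), as.numeric(mean_bid),
                        min_trials = 3L)
  attr(res, "bins") <- data.frame(bin = as.integer(names(mean_resp)),
                                  mean_bid = as.numeric(mean_bid),
                                  mean_response = as.numeric(mean_resp))
  res
}

#' Classify a neuron: dopamine criteria, value responsiveness, bid encoding
#'
#' Applies the classification cascade: (1) putative dopamine = wide waveform
#' (> 1.8 ms), low baseline rate (< 10 Hz), and a significant response to at
#' least one task event in 0-200 ms post-event (Wilcoxon sign-rank of
#' per-trial counts against a duration-matched baseline segment, p < alpha);
#' (2) value-responsive = a graded second-component response, i.e. a
#' significant single regression of the windowed response on magnitude rank
#' for the magnitude cue or for the water-payout cue (two separate
#' regressions); (3) bid-encoding = significant simple regression of the
#' windowed magnitude-cue response on the bids, evaluated only for putative
#' dopamine neurons.
#'
#' @param recording A \code{neuron_recording}.
#' @param window The value-component [analysis_window()].
#' @param alpha Significance level (default 0.05).
#' @return An object of class \code{neuron_classification} with logical fields
#'   \code{is_dopamine}, \code{is_value_responsive}, \code{is_bid_encoding},
#'   the supporting statistics, and \code{water_cue_missing} flag.
#' @export
classify_neuron <- function(recording, window = analysis_window(180, 360),
                            alpha = 0.05) {
  base_rates <- baseline_response(recording)
  base_cnts <- baseline_counts(recording)

  screen_p <- vapply(names(recording$rasters), function(ev) {
    d <- rowSums(event_counts(recording, ev, 0, 200)) -
      rowSums(base_cnts[, 1:200, drop = FALSE])
    if (all(d == 0)) return(NA_real_)
    suppressWarnings(stats::wilcox.test(d, mu = 0, exact = FALSE)$p.value)
  }, numeric(1))
  event_responsive <- any(screen_p < alpha, na.rm = TRUE)

  is_dopamine <- recording$waveform_ms > 1.8 &&
    mean(base_rates) < 10 && event_responsive

  mag_rank <- recording$trials$magnitude_level
  fr <- windowed_response(recording, "fractal", window)
  p_frac <- summary(stats::lm(fr ~ mag_rank))$coefficients["mag_rank", "Pr(>|t|)"]
  water_missing <- is.null(recording$rasters$water_cue)
  p_water <- NA_real_
  if (!water_missing) {
    wc <- windowed_response(recording, "water_cue", window)
    p_water <- summary(stats::lm(wc ~ mag_rank))$coefficients["mag_rank", "Pr(>|t|)"]
  }
  is_value_responsive <- isTRUE(p_frac < alpha) || isTRUE(p_water < alpha)

  eq4 <- bid_regression(fr, recording$trials$bid)
  is_bid_encoding <- is_dopamine && eq4$p < alpha

  structure(list(neuron_id = recording$neuron_id,
                 is_dopamine = is_dopamine,
                 is_value_responsive = is_value_responsive,
                 is_bid_encoding = is_bid_encoding,
                 waveform_ms = recording$waveform_ms,
                 baseline_hz = mean(base_rates),
                 event_screen_p = screen_p,
                 value_p_fractal = p_frac,
                 value_p_water_cue = p_water,
                 water_cue_missing = water_missing,
                 bid_slope = eq4$beta1, bid_r2 = eq4$r2, bid_p = eq4$p),
            class = "neuron_classification")
}

#' @export
print.neuron_classification <- function(x, ...) {
  cat(x$neuron_id, ": dopamine =", x$is_dopamine,
      "| value-responsive =", x$is_value_responsive,
      "| bid-encoding =", x$is_bid_encoding,
      sprintf("(slope %.2f, R2 %.2f, p %.3g)\n", x$bid_slope, x$bid_r2, x$bid_p))
  invisible(x)
}

#' Classification manifest for a population
#'
#' @param recordings List of \code{neuron_recording}.
#' @param window Value-component [analysis_window()].
#' @param alpha Significance level.
#' @return Data frame, one row per neuron, with the classification fields.
#' @export
classify_population <- function(recordings, window = analysis_window(180, 360),
                                alpha = 0.05) {
  rows <- lapply(recordings, function(r) {
    cl <- classify_neuron(r, window, alpha)
    data.frame(neuron_id = cl$neuron_id, is_dopamine = cl$is_dopamine,
               is_value_responsive = cl$is_value_responsive,
               is_bid_encoding = cl$is_bid_encoding,
               waveform_ms = cl$waveform_ms, baseline_hz = cl$baseline_hz,
               bid_slope = cl$bid_slope, bid_r2 = cl$bid_r2, bid_p = cl$bid_p)
  })
  do.call(rbind, rows)
}

#' Per-trial windowed response table for a population
#'
#' Joins each neuron's windowed responses (raw and z-normalized against its
#' baseline epoch) to the trial's bid, magnitude and movement features; the
#' long keyed table underlying all group-level analyses. Neurons with zero
#' baseline SD are excluded and listed in \code{attr(, "excluded")}.
#'
#' @param recordings List of \code{neuron_recording}.
#' @param window [analysis_window()].
#' @param event Raster to window (default \code{"fractal"}).
#' @return Data frame keyed by (\code{neuron_id}, \code{trial}) with columns
#'   \code{bid}, \code{magnitude_level}, \code{magnitude_ml},
#'   \code{movement_velocity}, \code{movement_absement}, \code{response}
#'   (raw Hz) and \code{z}.
#' @export
response_table <- function(recordings, window = analysis_window(180, 360),
                           event = "fractal") {
  excluded <- character()
  rows <- lapply(recordings, function(r) {
    resp <- windowed_response(r, event, window)
    base <- baseline_response(r)
    if (stats::sd(base) == 0) {
      excluded <<- c(excluded, r$neuron_id)
      return(NULL)
    }
    cbind(data.frame(neuron_id = r$neuron_id, session_id = r$session_id),
          r$trials,
          data.frame(response = resp, z = znormalize(resp, base)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Bid regressions restricted to a constant reward magnitude
#'
#' Regresses the pooled z-normalized responses on bids separately within each
#' magnitude level: significant slopes despite constant magnitude demonstrate
#' coding of the bid (instantaneous subjective value) rather than of the
#' externally cued reward amount.
#'
#' @param tbl A [response_table()].
#' @param response_col Column to regress (default \code{"z"}).
#' @param min_trials Minimum trials per magnitude.
#' @return Named list of \code{bid_regression} objects, one per magnitude
#'   level present.
#' @export
magnitude_regression_constant_magnitude <- function(tbl, response_col = "z",
                                                    min_trials = 10L) {
  levels_present <- sort(unique(tbl$magnitude_level))
  res <- lapply(levels_present, function(m) {
    sub <- tbl[tbl$magnitude_level == m, ]
    bid_regression(sub[[response_col]], sub$bid, min_trials = min_trials)
  })
  names(res) <- c("low", "mid", "high")[levels_present]
  res
}

# greedy nearest-neighbour pairing of two bid vectors within a tolerance;
# processed in ascending order of the first group's bids, each trial used once
greedy_match <- function(bids_a, bids_b, tolerance) {
  used <- logical(length(bids_b))
  pairs <- list()
  for (i in order(bids_a)) {
    free <- which(!used)
    if (length(free) == 0L) break
    j <- free[which.min(abs(bids_b[free] - bids_a[i]))]
    if (abs(bids_b[j] - bids_a[i]) <= tolerance) {
      used[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  if (length(pairs) == 0L) return(NULL)
  do.call(rbind, pairs)
}

#' Matched-bid comparison of responses across reward magnitudes
#'
#' Tests whether reward magnitude is encoded independently of the bid: within
#' each neuron's session, trials of two magnitude levels are greedily paired
#' so their bids differ by at most \code{tolerance} (5% of the bid space by
#' default, each trial used at most once); units whose matched bid
#' distributions still differ (rank-sum p < 0.05) are eliminated; response
#' differences (higher minus lower magnitude) are pooled across neurons and
#' tested for zero median with a paired Wilcoxon sign-rank test. A
#' significant positive difference indicates magnitude coding beyond the bid;
#' no difference indicates pure bid (subjective value) coding.
#'
#' @param tbl A [response_table()].
#' @param pair Two magnitude levels to compare, e.g. \code{c(1, 2)}.
#' @param tolerance Maximal bid difference within a pair (fraction of the
#'   full bid space).
#' @param response_col Response column (default \code{"z"}).
#' @param screen_alpha Level of the matched-bid distribution screen.
#' @return An object of class \code{matched_bid_result}: \code{pair},
#'   \code{n_pairs}, \code{n_units}, \code{n_units_screened_out},
#'   \code{median_diff}, \code{p}, \code{missing} (TRUE when no matchable
#'   pairs exist).
#' @export
matched_bid_comparison <- function(tbl, pair = c(1L, 2L), tolerance = 0.05,
                                   response_col = "z", screen_alpha = 0.05) {
  lo <- min(pair); hi <- max(pair)
  units <- split(tbl, interaction(tbl$neuron_id, tbl$session_id, drop = TRUE))
  diffs <- list()
  n_units <- 0L
  n_screened <- 0L
  for (u in units) {
    a <- u[u$magnitude_level == lo, ]
    b <- u[u$magnitude_level == hi, ]
    if (nrow(a) == 0L || nrow(b) == 0L) next
    m <- greedy_match(a$bid, b$bid, tolerance)
    if (is.null(m)) next
    if (nrow(m) >= 2L) {
      scr <- suppressWarnings(stats::wilcox.test(a$bid[m[, 1]], b$bid[m[, 2]],
                                                 exact = FALSE))
      if (is.finite(scr$p.value) && scr$p.value < screen_alpha) {
        n_screened <- n_screened + 1L
        next
      }
    }
    n_units <- n_units + 1L
    diffs[[length(diffs) + 1L]] <-
      b[[response_col]][m[, 2]] - a[[response_col]][m[, 1]]
  }
  if (length(diffs) == 0L) {
    return(structure(list(pair = c(lo, hi), n_pairs = 0L, n_units = 0L,
                          n_units_screened_out = n_screened,
                          median_diff = NA_real_, p = NA_real_,
                          missing = TRUE),
                     class = "matched_bid_result"))
  }
  d <- unlist(diffs)
  wt <- suppressWarnings(stats::wilcox.test(d, mu = 0, exact = FALSE))
  structure(list(pair = c(lo, hi), n_pairs = length(d), n_units = n_units,
                 n_units_screened_out = n_screened,
                 median_diff = stats::median(d), p = wt$p.value,
                 missing = FALSE),
            class = "matched_bid_result")
}

#' @export
print.matched_bid_result <- function(x, ...) {
  if (x$missing) {
    cat("Matched-bid comparison", paste(x$pair, collapse = " vs "),
        ": no matchable pairs\n")
  } else {
    cat(sprintf(
      "Matched-bid %d vs %d: %d pairs from %d units (%d screened out), median diff %.3f, p = %.3g\n",
      x$pair[1], x$pair[2], x$n_pairs, x$n_units, x$n_units_screened_out,
      x$median_diff, x$p))
  }
  invisible(x)
}

#' Movement-parameter control regressions
#'
#' Per neuron, regresses the windowed response on each movement feature
#' (signed and unsigned velocity and absement) in separate simple
#' regressions, counts neurons with significant slopes, and compares each
#' count against the 5% chance level with a binomial test. Bid encoding that
#' survives this control cannot be explained by arm movement.
#'
#' @param tbl A [response_table()].
#' @param alpha Per-regression significance level.
#' @return Data frame with one row per feature: \code{feature},
#'   \code{n_significant}, \code{n_neurons}, \code{binom_p} (two-sided
#'   against 5%).
#' @export
movement_control_regressions <- function(tbl, alpha = 0.05) {
  feats <- list(velocity = tbl$movement_velocity,
                unsigned_velocity = abs(tbl$movement_velocity),
                absement = tbl$movement_absement,
                unsigned_absement = abs(tbl$movement_absement))
  rows <- lapply(names(feats), function(fn) {
    f <- feats[[fn]]
    if (stats::sd(f) == 0) {
      message("feature ", fn, " is constant; skipped")
      return(NULL)
    }
    by_neuron <- split(data.frame(r = tbl$response, f = f), tbl$neuron_id)
    sig <- vapply(by_neuron, function(d) {
      if (stats::sd(d$f) == 0) return(NA)
      summary(stats::lm(r ~ f, data = d))$coefficients["f", "Pr(>|t|)"] < alpha
    }, logical(1))
    n <- sum(!is.na(sig))
    k <- sum(sig, na.rm = TRUE)
    data.frame(feature = fn, n_significant = k, n_neurons = n,
               binom_p = stats::binom.test(k, n, p = alpha)$p.value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
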