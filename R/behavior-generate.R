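#' Generate one synthetic BDM bidding session
#'
#' Simulates an ordered sequence of auction trials under the model described
#' in [behavior_config()]: pseudo-random magnitude order (all three magnitudes
#' represented), a shared AR(1) latent value drift, linear trial-history
#' effects, uniform starting cursor positions and computer bids, second-price
#' auction resolution, and per-trial bookkeeping of cumulative liquid and
#' same-magnitude win/lose streaks. Movement features are derived
#' deterministically from the cursor path: \code{velocity = (bid -
#' starting_bid) / bid_epoch_s} and \code{absement = (bid - starting_bid) / 2
#' * bid_epoch_s} (mean displacement times duration).
#'
#' @param config A [behavior_config()].
#' @param session_id Identifier stored with the session.
#' @param session_number Integer session index (used for day-of-week and
#'   between-session bookkeeping); defaults to \code{session_id} when numeric.
#' @param seed RNG seed; defaults to \code{config$seed}. The session is fully
#'   reproducible from the seed.
#' @param subject_id Subject label stored with the session.
#' @return A data frame of class \code{bdm_session}, one row per trial, with
#'   columns \code{trial}, \code{session_id}, \code{subject_id},
#'   \code{session_number}, \code{day_of_week}, \code{magnitude_level} (1 =
#'   low, 2 = mid, 3 = high), \code{magnitude_ml}, \code{latent_value_ml},
#'   \code{starting_bid}, \code{bid}, \code{computer_bid}, \code{won},
#'   \code{juice_ml}, \code{water_ml}, \code{price_paid},
#'   \code{total_liquid_ml} (before the trial), \code{win_streak},
#'   \code{lose_streak} (same-magnitude counts before the trial),
#'   \code{prev_same_mag_comp_bid}, \code{prev_same_mag_result},
#'   \code{movement_velocity}, \code{movement_absement}, \code{failed}.
#'   The generating config is attached as \code{attr(, "config")}.
#' @export
generate_session <- function(config = behavior_config(), session_id = 1L,
                             session_number = NULL, seed = NULL,
                             subject_id = "synthetic") {
  stopifnot(inherits(config, "behavior_config"))
  n <- config$n_trials
  if (n < 10L) stop_domain("n_trials must be at least 10")
  session_number <- session_number %||%
    (if (is.numeric(session_id)) as.integer(session_id) else 1L)
  seed <- seed %||% config$seed
  B <- config$budget_ml
  nmag <- length(config$magnitudes_ml)
  aucfg <- as_auction_config(config)

  with_seed(seed, {
    mag <- sample.int(nmag, n, replace = TRUE)
    while (length(unique(mag)) < nmag) mag <- sample.int(nmag, n, replace = TRUE)

    # shared latent value drift, stationary initialization
    innov <- stats::rnorm(n, 0, config$drift_sd)
    d <- numeric(n)
    d[1] <- if (config$drift_sd > 0)
      stats::rnorm(1, 0, config$drift_sd / sqrt(1 - config$drift_rho^2)) else 0
    for (t in seq_len(n)[-1]) d[t] <- config$drift_rho * d[t - 1] + innov[t]

    starting_bid <- stats::runif(n)
    computer_bid <- stats::runif(n)
    noise <- stats::rnorm(n, 0, config$bid_noise_sd)
    failed <- stats::runif(n) < config$fail_rate

    latent <- config$base_values_ml[mag] + d

    bid <- numeric(n)
    won <- rep(NA, n)
    juice <- water <- price <- numeric(n)
    total_liquid <- numeric(n)        # before each trial
    win_streak <- lose_streak <- integer(n)
    prev_cb <- rep(NA_real_, n)       # previous same-magnitude computer bid
    prev_res <- rep(NA, n)            # previous same-magnitude result

    # per-magnitude running state
    ws <- ls_ <- integer(nmag)
    last_cb <- rep(NA_real_, nmag)
    last_res <- rep(NA, nmag)
    liquid <- 0

    for (t in seq_len(n)) {
      m <- mag[t]
      total_liquid[t] <- liquid
      win_streak[t] <- ws[m]
      lose_streak[t] <- ls_[m]
      prev_cb[t] <- last_cb[m]
      prev_res[t] <- last_res[m]

      liq_norm <- liquid / (B * n)
      hist_eff <- config$coef_starting_bid * (starting_bid[t] - 0.5) +
        config$coef_total_liquid * (liq_norm - 0.5) +
        (if (!is.na(last_cb[m])) config$coef_prev_comp_bid * (last_cb[m] - 0.5) else 0) +
        (if (!is.na(last_res[m])) config$coef_prev_result * (last_res[m] - 0.5) else 0) +
        config$coef_win_streak * min(ws[m], config$streak_cap) +
        config$coef_lose_streak * min(ls_[m], config$streak_cap)

      bid[t] <- clip01(latent[t] / B + hist_eff + noise[t])

      if (failed[t]) next  # no auction, no payout, history state unchanged

      out <- resolve_auction(bid[t], computer_bid[t], config$magnitudes_ml[m], aucfg)
      won[t] <- out$won
      juice[t] <- out$juice_ml
      water[t] <- out$water_ml
      price[t] <- out$price_paid
      liquid <- liquid + out$juice_ml + out$water_ml
      last_cb[m] <- computer_bid[t]
      last_res[m] <- out$won
      if (out$won) { ws[m] <- ws[m] + 1L; ls_[m] <- 0L }
      else { ls_[m] <- ls_[m] + 1L; ws[m] <- 0L }
    }

    dur <- config$bid_epoch_s
    session <- data.frame(
      trial = seq_len(n),
      session_id = session_id,
      subject_id = subject_id,
      session_number = session_number,
      day_of_week = ((session_number - 1L) %% 5L) + 1L,
      magnitude_level = mag,
      magnitude_ml = config$magnitudes_ml[mag],
      latent_value_ml = latent,
      starting_bid = starting_bid,
      bid = bid,
      computer_bid = computer_bid,
      won = won,
      juice_ml = juice,
      water_ml = water,
      price_paid = price,
      total_liquid_ml = total_liquid,
      win_streak = win_streak,
      lose_streak = lose_streak,
      prev_same_mag_comp_bid = prev_cb,
      prev_same_mag_result = prev_res,
      movement_velocity = (bid - starting_bid) / dur,
      movement_absement = (bid - starting_bid) / 2 * dur,
      failed = failed
    )
    attr(session, "config") <- config
    class(session) <- c("bdm_session", "data.frame")
    session
  })
}

#' Generate a multi-session synthetic dataset
#'
#' Sessions share one generator configuration but receive independent drift
#' realizations (and seeds derived from the dataset seed), so day-to-day
#' variation in mean bids emerges from the stationary initialization of the
#' latent drift.
#'
#' @param config A [behavior_config()].
#' @param n_sessions Number of sessions (at least 1).
#' @param seed Dataset seed; per-session seeds are derived from it.
#' @param subject_id Subject label.
#' @return A list of \code{bdm_session} objects of class \code{bdm_dataset}.
#' @export
generate_dataset <- function(config = behavior_config(), n_sessions = 5L,
                             seed = config$seed, subject_id = "synthetic") {
  if (n_sessions < 1L) stop_domain("n_sessions must be at least 1")
  seeds <- derive_seeds(seed, n_sessions)
  sessions <- lapply(seq_len(n_sessions), function(i)
    generate_session(config, session_id = i, session_number = i,
                     seed = seeds[[i]], subject_id = subject_id))
  structure(sessions, class = "bdm_dataset", config = config)
}

#' Stack a dataset (or session) into one trial table
#'
#' @param x A \code{bdm_session} or \code{bdm_dataset}.
#' @param completed_only Drop failed (aborted) trials, the default for all
#'   analyses.
#' @return A plain data frame of trials.
#' @export
trial_table <- function(x, completed_only = TRUE) {
  if (inherits(x, "bdm_session")) x <- list(x)
  df <- do.call(rbind, lapply(x, as.data.frame))
  rownames(df) <- NULL
  if (completed_only) df <- df[!df$failed, , drop = FALSE]
  df
}

#' @export
print.bdm_session <- function(x, ...) {
  cat("BDM session", format(x$session_id[1]), "-", nrow(x), "trials,",
      sum(x$failed), "failed\n")
  NextMethod()
}
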