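#' Configuration of the synthetic bidding-session generator
#'
#' The generator emulates the statistical structure of BDM bidding in highly
#' trained subjects: mean bids rank-ordered by juice magnitude, a shared
#' latent subjective-value drift that moves bids for all three magnitudes
#' coherently (an AR(1) process added to every magnitude's base value), and
#' linear trial-history effects (starting cursor position, cumulative liquid
#' consumed, previous same-magnitude computer bid and result, win/lose
#' streaks).
#'
#' On trial t with magnitude m the bid is
#' \deqn{bid_t = clip( (base_m + d_t)/B + \sum_k c_k x_{kt} + \epsilon_t, 0, 1)}
#' with \eqn{d_t = \rho d_{t-1} + N(0, \sigma_d)} shared across magnitudes,
#' \eqn{d_1 \sim N(0, \sigma_d/\sqrt{1-\rho^2})} (so day-to-day mean-bid
#' variation emerges from session initialization), and centered history
#' regressors: starting bid minus 0.5, normalized cumulative liquid minus 0.5,
#' previous same-magnitude computer bid minus 0.5, previous same-magnitude
#' result coded +0.5 win / -0.5 loss, and raw win/lose streak counts.
#'
#' @param magnitudes_ml Three strictly increasing juice volumes (ml).
#' @param base_values_ml Mean subjective value of each magnitude in
#'   water-equivalent ml; strictly increasing, within \code{[0, budget_ml]}.
#' @param budget_ml Water budget per trial (ml).
#' @param drift_rho AR(1) coefficient of the shared latent value drift,
#'   in \code{[0, 1)}.
#' @param drift_sd Innovation SD of the drift (ml).
#' @param bid_noise_sd Per-trial bid noise SD (bid units).
#' @param coef_starting_bid,coef_total_liquid,coef_prev_comp_bid,coef_prev_result,coef_win_streak,coef_lose_streak
#'   Linear history-effect coefficients, in bid units per (centered) regressor
#'   unit.
#' @param streak_cap Streak effects saturate: the win/lose streak regressors
#'   enter the bid as \code{min(streak, streak_cap)}. Without saturation a
#'   positive win-streak coefficient is self-reinforcing (higher bids win
#'   more often, lengthening the streak) and bids pin to the edge of the bid
#'   space. Raw streak counts are still recorded per trial.
#' @param fail_rate Probability that a trial is aborted (joystick error /
#'   timeout); failed trials are flagged and excluded from all analyses.
#' @param bid_epoch_s Duration of the bidding epoch used to derive the
#'   deterministic movement features (velocity and absement).
#' @param n_trials Trials per session (at least 10).
#' @param seed Default RNG seed used by [generate_session()].
#' @return An object of class \code{behavior_config}.
#' @seealso [subject_profile()] for per-subject presets.
#' @export
behavior_config <- function(magnitudes_ml = c(0.3, 1.0, 1.7),
                            base_values_ml = c(0.25, 0.60, 0.95),
                            budget_ml = 1.2,
                            drift_rho = 0.97,
                            drift_sd = 0.02,
                            bid_noise_sd = 0.05,
                            coef_starting_bid = -0.1,
                            coef_total_liquid = 0.18,
                            coef_prev_comp_bid = 0.02,
                            coef_prev_result = 0.01,
                            coef_win_streak = 0.016,
                            coef_lose_streak = -0.007,
                            streak_cap = 5L,
                            fail_rate = 0.02,
                            bid_epoch_s = 2,
                            n_trials = 500L,
                            seed = 1L) {
  if (length(base_values_ml) != length(magnitudes_ml))
    stop_domain("base_values_ml must match magnitudes_ml in length")
  if (any(diff(base_values_ml) <= 0))
    stop_domain("base_values_ml must be strictly increasing")
  if (any(base_values_ml < 0) || any(base_values_ml > budget_ml))
    stop_domain("base_values_ml must lie within [0, budget_ml]")
  if (drift_rho < 0 || drift_rho >= 1)
    stop_domain("drift_rho must lie in [0, 1)")
  if (drift_sd < 0 || bid_noise_sd < 0)
    stop_domain("SDs must be non-negative")
  if (fail_rate < 0 || fail_rate >= 1)
    stop_domain("fail_rate must lie in [0, 1)")
  structure(list(
    magnitudes_ml = magnitudes_ml, base_values_ml = base_values_ml,
    budget_ml = budget_ml, drift_rho = drift_rho, drift_sd = drift_sd,
    bid_noise_sd = bid_noise_sd,
    coef_starting_bid = coef_starting_bid,
    coef_total_liquid = coef_total_liquid,
    coef_prev_comp_bid = coef_prev_comp_bid,
    coef_prev_result = coef_prev_result,
    coef_win_streak = coef_win_streak,
    coef_lose_streak = coef_lose_streak,
    streak_cap = as.integer(streak_cap),
    fail_rate = fail_rate, bid_epoch_s = bid_epoch_s,
    n_trials = as.integer(n_trials), seed = seed
  ), class = "behavior_config")
}

#' Per-subject generator presets
#'
#' Presets for the two subjects' reward ranges (juice magnitudes U:
#' 0.2/0.45/0.7 ml, V: 0.3/1.0/1.7 ml, budget 1.2 ml) with history
#' coefficients set to the reported per-subject mixed-model estimates
#' (V: starting bid -0.1, total liquid 0.18, win streak 0.016, lose streak
#' -0.007; U: -0.04, 0.47, 0.05, -0.03). The \code{"decoding"} profile spreads
#' the base subjective values over the bid space and raises the bid noise so
#' that 600-trial sessions populate all ten bid deciles, as the
#' pseudo-population decoding protocol requires.
#'
#' @param subject One of \code{"U"}, \code{"V"}, \code{"decoding"}.
#' @param ... Overrides forwarded to [behavior_config()].
#' @return A \code{behavior_config}.
#' @export
subject_profile <- function(subject = c("V", "U", "decoding"), ...) {
  subject <- match.arg(subject)
  base <- switch(subject,
    V = list(magnitudes_ml = c(0.3, 1.0, 1.7),
             base_values_ml = c(0.25, 0.60, 0.95),
             coef_starting_bid = -0.1, coef_total_liquid = 0.18,
             coef_win_streak = 0.016, coef_lose_streak = -0.007),
    U = list(magnitudes_ml = c(0.2, 0.45, 0.7),
             base_values_ml = c(0.30, 0.55, 0.80),
             coef_starting_bid = -0.04, coef_total_liquid = 0.47,
             coef_win_streak = 0.05, coef_lose_streak = -0.03),
    decoding = list(magnitudes_ml = c(0.3, 1.0, 1.7),
                    base_values_ml = c(0.20, 0.60, 1.00),
                    bid_noise_sd = 0.11, drift_sd = 0.025,
                    coef_starting_bid = -0.1, coef_total_liquid = 0.18,
                    coef_win_streak = 0.016, coef_lose_streak = -0.007,
                    n_trials = 600L)
  )
  args <- utils::modifyList(base, list(...))
  do.call(behavior_config, args)
}

#' @export
print.behavior_config <- function(x, ...) {
  cat("Synthetic BDM behavior generator\n")
  cat("  magnitudes:", paste(x$magnitudes_ml, collapse = "/"), "ml;",
      "base values:", paste(x$base_values_ml, collapse = "/"), "ml\n")
  cat("  drift AR(1) rho", x$drift_rho, "sd", x$drift_sd,
      "; bid noise sd", x$bid_noise_sd, "\n")
  cat("  n_trials", x$n_trials, "; fail rate", x$fail_rate, "\n")
  invisible(x)
}

# auction_config matching a behavior_config
as_auction_config <- function(config) {
  auction_config(budget_ml = config$budget_ml,
                 magnitudes_ml = config$magnitudes_ml)
}
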