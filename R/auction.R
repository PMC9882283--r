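#' Auction configuration for the BDM bidding task
#'
#' The Becker-DeGroot-Marschak (BDM) mechanism used here is a second-price
#' sealed-bid auction against a computer opponent whose bid is drawn uniformly
#' over the bid space. The subject bids a fraction of a fixed water endowment
#' (the budget) for one of three juice magnitudes. Winning (bid greater than or
#' equal to the computer bid) delivers the juice plus the remainder of the
#' water budget after paying the *computer's* bid (the second price); losing
#' delivers the full water budget and no juice.
#'
#' Bids are represented throughout on the normalized closed interval
#' \code{[0, 1]} (fractions of the bid space); multiply by \code{budget_ml} to
#' obtain milliliters.
#'
#' @param budget_ml Water endowment per trial in ml (default 1.2).
#' @param magnitudes_ml Strictly increasing vector of the three juice volumes
#'   on offer, in ml.
#' @param tie_rule Only \code{"bidder_wins"} is implemented: a bid equal to the
#'   computer bid wins the auction.
#' @return An object of class \code{auction_config}.
#' @examples
#' cfg <- auction_config()
#' resolve_auction(0.5, 0.5, 0.45, cfg)
#' @export
auction_config <- function(budget_ml = 1.2,
                           magnitudes_ml = c(0.3, 1.0, 1.7),
                           tie_rule = "bidder_wins") {
  if (!is.numeric(budget_ml) || length(budget_ml) != 1L || budget_ml <= 0)
    stop_domain("budget_ml must be a single positive number")
  if (length(magnitudes_ml) < 2L || any(diff(magnitudes_ml) <= 0))
    stop_domain("magnitudes_ml must be strictly increasing")
  tie_rule <- match.arg(tie_rule)
  structure(list(budget_ml = budget_ml,
                 magnitudes_ml = magnitudes_ml,
                 tie_rule = tie_rule),
            class = "auction_config")
}

#' @export
print.auction_config <- function(x, ...) {
  cat("BDM auction: budget", x$budget_ml, "ml; magnitudes",
      paste(x$magnitudes_ml, collapse = "/"), "ml; ties win\n")
  invisible(x)
}

check_bid <- function(bid, what = "bid") {
  if (!is.numeric(bid) || anyNA(bid) || any(bid < 0 | bid > 1))
    stop_domain(what, " must lie in [0, 1]")
  invisible(bid)
}

#' Resolve one (or several) BDM auctions
#'
#' Applies the second-price rule: the subject wins when its bid equals or
#' exceeds the computer bid, receives the juice, and pays the computer bid out
#' of the water budget. On a loss the full water budget is paid out and no
#' juice is delivered.
#'
#' @param bid,computer_bid Normalized bids in \code{[0, 1]}; vectors recycle.
#' @param magnitude_ml Juice volume at stake, in ml.
#' @param config An [auction_config()].
#' @return A data frame with columns \code{won}, \code{juice_ml},
#'   \code{water_ml}, \code{price_paid} (the normalized second price; 0 on a
#'   loss).
#' @export
resolve_auction <- function(bid, computer_bid, magnitude_ml,
                            config = auction_config()) {
  check_bid(bid)
  check_bid(computer_bid, "computer_bid")
  n <- max(length(bid), length(computer_bid), length(magnitude_ml))
  bid <- rep_len(bid, n)
  computer_bid <- rep_len(computer_bid, n)
  magnitude_ml <- rep_len(magnitude_ml, n)
  won <- bid >= computer_bid
  price <- ifelse(won, computer_bid, 0)
  data.frame(
    won = won,
    juice_ml = ifelse(won, magnitude_ml, 0),
    water_ml = config$budget_ml * (1 - price),
    price_paid = price
  )
}

#' Expected total payout of a BDM bid
#'
#' For a subjective juice value of \code{value_ml} water-equivalent ml, a
#' normalized bid \code{b}, budget \code{B} and a uniform computer bid on
#' \code{[0, 1]}, the expected payout (juice value plus water, in
#' water-equivalent ml) is \code{b * v + B - B * b^2 / 2}: winning probability
#' \code{b}, and the expected second price conditional on winning is
#' \code{b / 2}. The function is strictly concave in \code{b} with its maximum
#' at \code{b = v / B}, which is the incentive-compatibility property of the
#' mechanism.
#'
#' @param value_ml Subjective value of the juice in water-equivalent ml
#'   (non-negative).
#' @param bid Normalized bid(s) in \code{[0, 1]}.
#' @param config An [auction_config()].
#' @return Expected payout(s) in water-equivalent ml.
#' @export
expected_payoff <- function(value_ml, bid, config = auction_config()) {
  if (!is.numeric(value_ml) || anyNA(value_ml) || any(value_ml < 0))
    stop_domain("value_ml must be non-negative")
  check_bid(bid)
  B <- config$budget_ml
  bid * value_ml + B - B * bid^2 / 2
}

#' Optimal BDM bid for a given subjective value
#'
#' The payoff-maximizing bid is the subjective value expressed as a fraction
#' of the budget, \code{v / B} (truthful bidding). Values exceeding the budget
#' are clamped to a bid of 1 with a warning, since the bid space cannot
#' express them.
#'
#' @inheritParams expected_payoff
#' @return Normalized optimal bid(s).
#' @export
optimal_bid <- function(value_ml, config = auction_config()) {
  if (!is.numeric(value_ml) || anyNA(value_ml) || any(value_ml < 0))
    stop_domain("value_ml must be non-negative")
  B <- config$budget_ml
  b <- value_ml / B
  if (any(b > 1)) {
    warning("value_ml exceeds budget_ml; bid clamped to 1")
    b <- pmin(b, 1)
  }
  b
}
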