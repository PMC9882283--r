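#' Rank-order check of bids against reward magnitude
#'
#' Spearman rank correlation of bids with juice magnitude, per session and
#' pooled over the dataset, plus the fraction of sessions reaching p < 0.05.
#' Sessions with constant bids are flagged and excluded from the fraction.
#'
#' @param dataset A \code{bdm_dataset} or single \code{bdm_session}.
#' @param alpha Significance level for the per-session fraction.
#' @return A list with \code{per_session} (data frame: session_id, rho, rho2,
#'   p, constant_bids), \code{pooled_rho}, \code{pooled_rho2},
#'   \code{pooled_p}, and \code{frac_sessions_significant}.
#' @export
rank_order_check <- function(dataset, alpha = 0.05) {
  if (inherits(dataset, "bdm_session"))
    dataset <- structure(list(dataset), class = "bdm_dataset")
  per <- lapply(dataset, function(s) {
    tt <- trial_table(s)
    if (length(unique(tt$magnitude_level)) < 2L)
      stop_domain("need at least 2 magnitude levels per session")
    if (stats::sd(tt$bid) == 0)
      return(data.frame(session_id = tt$session_id[1], rho = NA_real_,
                        rho2 = NA_real_, p = NA_real_, constant_bids = TRUE))
    ct <- suppressWarnings(
      stats::cor.test(tt$bid, tt$magnitude_ml, method = "spearman",
                      exact = FALSE))
    data.frame(session_id = tt$session_id[1],
               rho = unname(ct$estimate), rho2 = unname(ct$estimate)^2,
               p = ct$p.value, constant_bids = FALSE)
  })
  per <- do.call(rbind, per)
  all_tt <- trial_table(dataset)
  pooled <- suppressWarnings(
    stats::cor.test(all_tt$bid, all_tt$magnitude_ml, method = "spearman",
                    exact = FALSE))
  ok <- !per$constant_bids
  list(per_session = per,
       pooled_rho = unname(pooled$estimate),
       pooled_rho2 = unname(pooled$estimate)^2,
       pooled_p = pooled$p.value,
       frac_sessions_significant = if (any(ok)) mean(per$p[ok] < alpha) else NA_real_)
}

# same-magnitude lagged computer bids for one session's completed trials
same_mag_lags <- function(mag, comp_bid, max_lag) {
  n <- length(mag)
  out <- matrix(NA_real_, n, max_lag)
  for (m in unique(mag)) {
    idx <- which(mag == m)
    for (l in seq_len(max_lag)) {
      if (length(idx) > l)
        out[idx[-seq_len(l)], l] <- comp_bid[idx[seq_len(length(idx) - l)]]
    }
  }
  out
}

#' Build the candidate design matrix for bid-variance analysis
#'
#' Assembles, per session and within session order, the 31 candidate
#' regressors used for lasso variable selection and the mixed-effects models:
#' reward value, starting bid, previous total liquid, day of week, session
#' number, previous-trial failure, previous-trial result, previous
#' same-magnitude result, trial number, lagged competing (computer) bids at
#' t-1, t-2, t-3, t-5 and t-7, same-magnitude competing-bid lags t-1 through
#' t-10 (skipping intervening other-magnitude trials), rolling means of the
#' same-magnitude competing bid over the last 2 to 6 same-magnitude trials,
#' and the same-magnitude win and lose streaks. The response column \code{y}
#' is the bid.
#'
#' Rows with any undefined lag (session-initial trials) are dropped; the
#' number dropped is recorded in \code{attr(, "n_dropped")}. Failed trials
#' never enter; "previous trial failure" refers to the immediately preceding
#' trial in raw session order.
#'
#' @param dataset A \code{bdm_dataset} or \code{bdm_session}.
#' @return A data frame of class \code{bdm_design_matrix} with the response
#'   \code{y} and the candidate columns listed in
#'   \code{attr(, "candidates")}.
#' @export
build_design_matrix <- function(dataset) {
  if (inherits(dataset, "bdm_session"))
    dataset <- structure(list(dataset), class = "bdm_dataset")
  per_session <- lapply(dataset, function(s) {
    raw <- as.data.frame(s)
    prev_failed_raw <- c(NA, raw$failed[-nrow(raw)])
    keep <- !raw$failed
    d <- raw[keep, , drop = FALSE]
    n <- nrow(d)
    if (n == 0L) return(NULL)
    lag1 <- function(x) c(NA, x[-length(x)])
    sm <- same_mag_lags(d$magnitude_level, d$computer_bid, 10L)
    roll <- sapply(2:6, function(k) rowMeans(sm[, seq_len(k), drop = FALSE]))
    out <- data.frame(
      y = d$bid,
      reward_value = d$magnitude_ml,
      starting_bid = d$starting_bid,
      prev_total_liquid = d$total_liquid_ml,
      day_of_week = d$day_of_week,
      session_number = d$session_number,
      prev_trial_failure = as.numeric(prev_failed_raw[keep]),
      prev_trial_result = as.numeric(lag1(d$won)),
      prev_same_mag_result = as.numeric(d$prev_same_mag_result),
      trial_number = d$trial,
      comp_bid_t1 = lag1(d$computer_bid),
      comp_bid_t2 = c(rep(NA, 2), d$computer_bid[seq_len(max(0, n - 2))]),
      comp_bid_t3 = c(rep(NA, 3), d$computer_bid[seq_len(max(0, n - 3))]),
      comp_bid_t5 = c(rep(NA, 5), d$computer_bid[seq_len(max(0, n - 5))]),
      comp_bid_t7 = c(rep(NA, 7), d$computer_bid[seq_len(max(0, n - 7))])
    )
    colnames(sm) <- paste0("same_mag_comp_bid_t", 1:10)
    colnames(roll) <- paste0("same_mag_comp_bid_mean", 2:6)
    out <- cbind(out, sm, roll)
    out$win_streak <- d$win_streak
    out$lose_streak <- d$lose_streak
    out$session_id <- d$session_id
    out$magnitude_level <- d$magnitude_level
    out
  })
  dm <- do.call(rbind, per_session)
  candidates <- setdiff(colnames(dm), c("y", "session_id", "magnitude_level"))
  complete <- stats::complete.cases(dm[, c("y", candidates)])
  n_dropped <- sum(!complete)
  dm <- dm[complete, , drop = FALSE]
  rownames(dm) <- NULL
  if (nrow(dm) == 0L)
    warning("fewer trials than the maximum lag; design matrix is empty")
  attr(dm, "candidates") <- candidates
  attr(dm, "n_dropped") <- n_dropped
  class(dm) <- c("bdm_design_matrix", "data.frame")
  dm
}

#' Lasso variable selection with the one-standard-error rule
#'
#' Cross-validated L1-penalized least squares (via \pkg{glmnet}) over the
#' standardized candidate regressors; the chosen penalty is the largest
#' lambda whose cross-validated MSE lies within one standard error of the
#' minimum. Constant columns are dropped with a warning before fitting.
#'
#' @param dm A [build_design_matrix()] result.
#' @param n_folds Number of cross-validation folds (>= 2; default 10).
#' @param seed Seed controlling the fold assignment.
#' @return An object of class \code{lasso_selection}: \code{selected}
#'   (regressor names surviving at the 1-SE lambda), \code{selected_min}
#'   (at the CV-minimum lambda), \code{chosen_lambda}, \code{lambda_min},
#'   \code{lambda_path}, \code{cv_fold_count}, \code{dropped_constant}.
#' @export
lasso_select <- function(dm, n_folds = 10L, seed = 1L) {
  if (n_folds < 2L) stop_domain("n_folds must be at least 2")
  candidates <- attr(dm, "candidates") %||%
    setdiff(colnames(dm), c("y", "session_id", "magnitude_level"))
  x <- as.matrix(dm[, candidates, drop = FALSE])
  keep <- apply(x, 2L, function(col) stats::sd(col) > 0)
  if (!all(keep))
    warning("dropping constant candidate columns: ",
            paste(candidates[!keep], collapse = ", "))
  x <- x[, keep, drop = FALSE]
  y <- dm$y
  cv <- with_seed(seed, {
    foldid <- sample(rep_len(seq_len(n_folds), nrow(x)))
    glmnet::cv.glmnet(x, y, foldid = foldid, standardize = TRUE)
  })
  nonzero <- function(lambda) {
    cf <- as.matrix(stats::coef(cv, s = lambda))
    rownames(cf)[cf[, 1] != 0 & rownames(cf) != "(Intercept)"]
  }
  structure(list(
    selected = nonzero(cv$lambda.1se),
    selected_min = nonzero(cv$lambda.min),
    chosen_lambda = cv$lambda.1se,
    lambda_min = cv$lambda.min,
    lambda_path = cv$lambda,
    cv_fold_count = as.integer(n_folds),
    dropped_constant = candidates[!keep],
    cv_fit = cv
  ), class = "lasso_selection")
}

#' @export
print.lasso_selection <- function(x, ...) {
  cat("Lasso (1-SE rule): lambda =", signif(x$chosen_lambda, 4), "-",
      length(x$selected), "regressors survive\n")
  if (length(x$selected)) cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

mixed_model_spec <- function(tag) {
  switch(tag,
    Eq1 = list(fixed = c("reward_value", "starting_bid", "prev_total_liquid",
                         "same_mag_comp_bid_t1", "prev_same_mag_result"),
               random = c("trial_number", "session_number")),
    Eq2 = list(fixed = c("starting_bid", "prev_total_liquid",
                         "same_mag_comp_bid_t1", "prev_same_mag_result"),
               random = c("reward_value", "trial_number", "session_number")),
    Eq3 = list(fixed = c("starting_bid", "prev_total_liquid",
                         "same_mag_comp_bid_t1", "win_streak", "lose_streak"),
               random = c("reward_value", "trial_number", "session_number",
                          "prev_same_mag_result")),
    stop_domain("unknown model tag: ", tag))
}

#' Mixed-effects models of bidding behavior
#'
#' Fits one of three random-intercept mixed models of the bid by maximum
#' likelihood (\pkg{lme4}):
#' \describe{
#'   \item{Eq1}{fixed effects reward magnitude, starting bid, total liquid,
#'     previous same-magnitude computer bid and result; random intercepts by
#'     trial number and session number (removing trial-progression and
#'     between-day variability).}
#'   \item{Eq2}{as Eq1 without the reward-magnitude fixed effect, which moves
#'     to a random-intercept grouping variable (isolating value-irrelevant
#'     predictors from the magnitude-bid correlation).}
#'   \item{Eq3}{replaces the previous-result fixed effect by win-streak and
#'     lose-streak counts, with previous result as an additional
#'     random-intercept grouping (the two are collinear).}
#' }
#' Fixed-effect p-values use the large-sample Wald normal approximation.
#' Grouping variables with fewer than 2 levels are dropped with a flag; a
#' singular fit is refit without its zero-variance components and flagged.
#'
#' @param dm A [build_design_matrix()] result.
#' @param model_tag \code{"Eq1"}, \code{"Eq2"} or \code{"Eq3"}.
#' @return An object of class \code{mixed_model_result} with
#'   \code{coefficients} (term, estimate, se, z, p), \code{varcor} (variance
#'   components), \code{adj_r2}, \code{singular}, \code{dropped_groups},
#'   \code{formula} and the underlying \code{fit}.
#' @export
fit_mixed_model <- function(dm, model_tag = c("Eq1", "Eq2", "Eq3")) {
  model_tag <- match.arg(model_tag)
  spec <- mixed_model_spec(model_tag)
  dat <- as.data.frame(dm)
  for (g in spec$random) dat[[paste0(".g_", g)]] <- factor(dat[[g]])

  usable <- spec$random[vapply(spec$random, function(g) {
    nl <- nlevels(dat[[paste0(".g_", g)]])
    nl >= 2L && nl < nrow(dat)  # a saturated grouping cannot be estimated
  }, logical(1))]
  dropped <- setdiff(spec$random, usable)
  if (length(dropped))
    warning("unusable grouping variables dropped (fewer than 2 levels, or one ",
            "level per observation): ", paste(dropped, collapse = ", "))

  fit_with <- function(groups) {
    if (length(groups) == 0L) {
      f <- stats::reformulate(spec$fixed, response = "y")
      return(list(fit = stats::lm(f, data = dat), formula = f, is_lm = TRUE))
    }
    f <- stats::as.formula(paste(
      "y ~", paste(spec$fixed, collapse = " + "), "+",
      paste(sprintf("(1 | .g_%s)", groups), collapse = " + ")))
    ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
    list(fit = lme4::lmer(f, data = dat, REML = FALSE, control = ctrl),
         formula = f, is_lm = FALSE)
  }

  res <- fit_with(usable)
  singular <- FALSE
  if (!res$is_lm && lme4::isSingular(res$fit, tol = 1e-5)) {
    singular <- TRUE
    vc <- as.data.frame(lme4::VarCorr(res$fit))
    zero <- vc$grp[vc$grp != "Residual" & vc$vcov < 1e-10]
    keep <- usable[!paste0(".g_", usable) %in% zero]
    if (length(keep) < length(usable)) {
      dropped <- c(dropped, setdiff(usable, keep))
      res <- fit_with(keep)
      usable <- keep
    }
  }
  fit <- res$fit

  if (res$is_lm) {
    sm <- summary(fit)
    co <- sm$coefficients
    coefs <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                        z = co[, 3], p = co[, 4], row.names = NULL)
    varcor <- data.frame(group = "Residual", variance = sm$sigma^2)
  } else {
    co <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                        se = co[, "Std. Error"], z = co[, "t value"],
                        p = 2 * stats::pnorm(-abs(co[, "t value"])),
                        row.names = NULL)
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcor <- data.frame(group = sub("^\\.g_", "", vc$grp), variance = vc$vcov)
  }
  y <- dat$y
  r2 <- stats::cor(stats::fitted(fit), y)^2
  n <- length(y)
  p_fix <- length(spec$fixed)
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p_fix - 1)

  structure(list(tag = model_tag, formula = res$formula,
                 coefficients = coefs, varcor = varcor,
                 adj_r2 = adj_r2, singular = singular,
                 dropped_groups = dropped, fit = fit),
            class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat("Mixed model", x$tag, if (x$singular) "(singular fit, refit)" else "",
      "- adjusted R2 =", round(x$adj_r2, 3), "\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Within-session coherence of bids across reward magnitudes
#'
#' For each magnitude, bids are placed at their trial positions and linearly
#' interpolated onto the full (completed-)trial axis, producing three equally
#' populated bid vectors; pairwise Spearman correlations between them measure
#' whether bids for the three magnitudes move together over the session.
#' Because interpolation fills trials where a magnitude was absent, the
#' estimates are lower bounds on the latent coherence.
#'
#' @param session A \code{bdm_session}.
#' @param min_per_magnitude Minimum completed trials required per magnitude.
#' @return An object of class \code{coherence_result}: \code{rho_LM},
#'   \code{rho_MH}, \code{rho_LH} (NA when a magnitude is absent) and
#'   \code{n_interpolated}.
#' @export
bid_coherence <- function(session, min_per_magnitude = 5L) {
  tt <- trial_table(session)
  n <- nrow(tt)
  series <- lapply(1:3, function(m) {
    idx <- which(tt$magnitude_level == m)
    if (length(idx) == 0L) return(NULL)
    if (length(idx) < min_per_magnitude)
      stop_domain("fewer than ", min_per_magnitude,
                  " completed trials for magnitude level ", m)
    stats::approx(idx, tt$bid[idx], xout = seq_len(n), rule = 2)$y
  })
  rho <- function(a, b) {
    if (is.null(a) || is.null(b)) return(NA_real_)
    suppressWarnings(stats::cor(a, b, method = "spearman"))
  }
  structure(list(rho_LM = rho(series[[1]], series[[2]]),
                 rho_MH = rho(series[[2]], series[[3]]),
                 rho_LH = rho(series[[1]], series[[3]]),
                 n_interpolated = n),
            class = "coherence_result")
}

#' @export
print.coherence_result <- function(x, ...) {
  cat("Bid coherence (Spearman, interpolated, lower bound): L:M =",
      round(x$rho_LM, 3), " M:H =", round(x$rho_MH, 3),
      " L:H =", round(x$rho_LH, 3), "\n")
  invisible(x)
}
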