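test_that("rank-order check recovers perfect ordering and degrades under shuffling", {
  # perfectly ordered bids, no overlap between magnitudes
  s <- manual_session(magnitude_level = rep(1:3, each = 20),
                      computer_bid = runif(60),
                      bid = rep(c(0.2, 0.5, 0.8), each = 20) +
                        rep(seq(0, 0.019, length.out = 20), 3))
  ro <- rank_order_check(s)
  # with three tied magnitude ranks the maximal attainable Spearman rho is the
  # rank correlation of a perfectly ordered arrangement; compute it directly
  rho_max <- cor(rank(s$bid), rank(s$magnitude_ml))
  expect_lt(rho_max, 1)
  expect_equal(ro$per_session$rho, rho_max, tolerance = 1e-8)
  expect_lt(ro$per_session$p, 1e-10)

  # shuffling the magnitude labels destroys the pooled correlation
  set.seed(21)
  ds <- generate_dataset(behavior_config(n_trials = 300), 5, seed = 13)
  shuffled <- structure(lapply(ds, function(sess) {
    perm <- sample(nrow(sess))
    sess$magnitude_level <- sess$magnitude_level[perm]
    sess$magnitude_ml <- sess$magnitude_ml[perm]
    sess
  }), class = "bdm_dataset")
  ro_shuf <- rank_order_check(shuffled)
  expect_lt(abs(ro_shuf$pooled_rho), 0.1)

  # generated data: pooled rho2 strictly inside (0, 1), all sessions positive
  ro_gen <- rank_order_check(ds)
  expect_gt(ro_gen$pooled_rho2, 0)
  expect_lt(ro_gen$pooled_rho2, 1)
  expect_true(all(ro_gen$per_session$rho > 0))
})

test_that("design matrix lag arithmetic matches hand-computed cases", {
  # 11-trial single-magnitude session: lag-10 defined only for the last trial
  s <- manual_session(magnitude_level = rep(2L, 11),
                      computer_bid = (1:11) / 12)
  dm_all <- build_design_matrix(s)
  expect_equal(nrow(dm_all), 1L)
  expect_equal(dm_all$trial_number, 11)
  expect_equal(dm_all$same_mag_comp_bid_t10, 1 / 12)
  expect_equal(dm_all$same_mag_comp_bid_t1, 10 / 12)
  # rolling mean over the last 2 same-magnitude competing bids
  expect_equal(dm_all$same_mag_comp_bid_mean2, mean(c(10, 9) / 12))

  # alternating magnitudes force same-magnitude t-1 == global t-2
  s2 <- manual_session(magnitude_level = rep(c(1L, 2L), 15),
                       computer_bid = (1:30) / 31)
  raw <- same_lag <- build_design_matrix(s2)
  expect_equal(raw$same_mag_comp_bid_t1, raw$comp_bid_t2)

  # the candidate list is the 31 enumerated regressors
  dm <- build_design_matrix(generate_dataset(behavior_config(n_trials = 120), 2, seed = 2))
  expect_length(attr(dm, "candidates"), 31L)
  expect_false(anyNA(dm[, attr(dm, "candidates")]))
})

test_that("lasso recovers strong true regressors and rejects pure noise", {
  make_dm <- function(y, x) {
    dm <- data.frame(y = y, x)
    attr(dm, "candidates") <- colnames(x)
    class(dm) <- c("bdm_design_matrix", "data.frame")
    dm
  }
  hits <- 0L; empties <- 0L
  n_seeds <- 10L
  for (i in seq_len(n_seeds)) {
    set.seed(i)
    x <- matrix(rnorm(300 * 31), 300, 31,
                dimnames = list(NULL, paste0("v", 1:31)))
    y <- 0.8 * x[, 1] - 0.7 * x[, 2] + 0.6 * x[, 3] + rnorm(300, 0, 0.5)
    sel <- lasso_select(make_dm(y, x), seed = i)
    hits <- hits + all(paste0("v", 1:3) %in% sel$selected)
    sel_null <- lasso_select(make_dm(rnorm(300), x), seed = i)
    empties <- empties + (length(sel_null$selected) == 0L)
    # the 1-SE selection never exceeds the CV-minimum selection
    expect_lte(length(sel$selected), length(sel$selected_min))
    expect_gte(sel$chosen_lambda, sel$lambda_min)
  }
  expect_gte(hits, n_seeds - 1L)
  expect_gte(empties, n_seeds %/% 2 + 1L)
})

test_that("lasso drops constant columns with a warning", {
  x <- cbind(v1 = rnorm(100), v2 = rep(1, 100), v3 = rnorm(100))
  dm <- data.frame(y = x[, "v1"] + rnorm(100, 0, 0.1), x)
  attr(dm, "candidates") <- c("v1", "v2", "v3")
  expect_warning(sel <- lasso_select(dm, n_folds = 5, seed = 1), "constant")
  expect_equal(sel$dropped_constant, "v2")
})

test_that("mixed models recover injected coefficient signs and agree across forms", {
  ds <- generate_dataset(subject_profile("V", n_trials = 150), 3, seed = 101)
  dm <- build_design_matrix(ds)
  eq2 <- fit_mixed_model(dm, "Eq2")
  co2 <- eq2$coefficients
  expect_lt(co2$estimate[co2$term == "starting_bid"], 0)
  expect_gt(co2$estimate[co2$term == "prev_total_liquid"], 0)
  expect_true(all(c("estimate", "se", "z", "p") %in% colnames(co2)))
  expect_gt(eq2$adj_r2, 0)

  # shared regressors keep their signs between Eq2 and Eq3
  eq3 <- fit_mixed_model(dm, "Eq3")
  co3 <- eq3$coefficients
  for (term in c("starting_bid", "prev_total_liquid", "same_mag_comp_bid_t1")) {
    expect_equal(sign(co2$estimate[co2$term == term]),
                 sign(co3$estimate[co3$term == term]))
  }
  # streak terms appear only in Eq3, previous result only in Eq2's fixed part
  expect_true(all(c("win_streak", "lose_streak") %in% co3$term))
  expect_false("prev_same_mag_result" %in% co3$term)
})

test_that("single-session fits drop the session grouping with a flag", {
  dm <- build_design_matrix(quick_session(n = 150, seed = 4))
  expect_warning(fit <- fit_mixed_model(dm, "Eq1"), "session_number")
  expect_true("session_number" %in% fit$dropped_groups)
})

test_that("coherence is 1 for identical series, near 0 for independent noise, high for shared drift", {
  # three identical (monotone) interleaved bid sequences: interpolation
  # preserves the ordering, so all pairwise rank correlations are exactly 1
  n <- 90
  lv <- rep(1:3, n / 3)
  shared <- rep(seq(0.2, 0.8, length.out = n / 3), each = 3)
  s_ident <- manual_session(lv, runif(n), bid = shared)
  co <- bid_coherence(s_ident)
  # flat extrapolation at the session edges introduces a few rank ties
  expect_equal(co$rho_LM, 1, tolerance = 1e-3)
  expect_equal(co$rho_LH, 1, tolerance = 1e-3)

  indep_cfg <- behavior_config(drift_sd = 0, bid_noise_sd = 0.05, n_trials = 300,
                               coef_starting_bid = 0, coef_total_liquid = 0,
                               coef_prev_comp_bid = 0, coef_prev_result = 0,
                               coef_win_streak = 0, coef_lose_streak = 0)
  co_ind <- bid_coherence(generate_session(indep_cfg, seed = 6))
  expect_lt(max(abs(unlist(co_ind[1:3]))), 0.35)

  drift_cfg <- behavior_config(drift_rho = 0.98, drift_sd = 0.03,
                               bid_noise_sd = 0.02, n_trials = 300)
  co_dr <- bid_coherence(generate_session(drift_cfg, seed = 6))
  expect_true(all(unlist(co_dr[1:3]) > 0.5))
})

test_that("coherence reports a missing magnitude as NA", {
  s <- manual_session(rep(c(1L, 3L), 20), runif(40), bid = runif(40))
  co <- bid_coherence(s)
  expect_true(is.na(co$rho_LM))
  expect_true(is.na(co$rho_MH))
  expect_false(is.na(co$rho_LH))
})
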