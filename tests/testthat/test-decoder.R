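test_that("decoding categories are right-closed deciles of the bid space", {
  expect_equal(discretize_for_decoding(c(0.05, 0.95)), c(1L, 10L))
  expect_equal(discretize_for_decoding(0.10), 1L)
  expect_equal(discretize_for_decoding(0), 1L)
  expect_equal(discretize_for_decoding(1), 10L)
  expect_equal(discretize_for_decoding(0.1000001), 2L)
  # uniform bids at 500 trials populate all categories comfortably
  set.seed(7)
  expect_true(all(tabulate(discretize_for_decoding(runif(500)), 10) >= 10))
})

test_that("pseudo-population assembly enforces eligibility and reproducibility", {
  tabs <- list(a = synthetic_decoding_tab(seed = 1),
               b = synthetic_decoding_tab(seed = 2),
               c = synthetic_decoding_tab(seed = 3))
  pp <- assemble_pseudopopulation(tabs, seed = 5)
  expect_equal(dim(pp$X), c(100L, 3L))
  expect_length(pp$y, 100L)
  expect_equal(pp$category, rep(1:10, each = 10))
  expect_identical(pp, assemble_pseudopopulation(tabs, seed = 5))

  # a neuron with only 9 trials in one category is dropped
  short <- synthetic_decoding_tab(seed = 4)
  short <- short[-(which(short$category == 3)[1:21]), ]
  tabs$short <- short
  expect_message(pp2 <- assemble_pseudopopulation(tabs, seed = 5), "excluded")
  expect_equal(ncol(pp2$X), 3L)
  expect_equal(pp2$excluded, "short")
  expect_error(assemble_pseudopopulation(list(x = short), seed = 1), "eligible")
})

test_that("five-fold split holds out 2 of 10 trials per category", {
  pp <- assemble_pseudopopulation(list(a = synthetic_decoding_tab(seed = 1)),
                                  seed = 2)
  folds <- cv_folds(pp)
  expect_equal(sort(unique(folds)), 1:5)
  for (f in 1:5) {
    per_cat_test <- table(pp$category[folds == f])
    per_cat_train <- table(pp$category[folds != f])
    expect_true(all(per_cat_test == 2))
    expect_true(all(per_cat_train == 8))
  }
})

test_that("a noise-free linear code decodes perfectly and shuffling destroys it", {
  tabs <- lapply(1:5, function(i) synthetic_decoding_tab(noise_sd = 0, seed = i))
  names(tabs) <- paste0("n", 1:5)
  pp <- assemble_pseudopopulation(tabs, seed = 9)
  res <- run_svr_cv(pp)
  expect_gt(res$mean_r2, 0.95)  # epsilon-insensitive tube leaves a small bias
  expect_length(res$fold_r2, 5L)

  set.seed(10)
  pp$y <- sample(pp$y)
  expect_lt(run_svr_cv(pp)$mean_r2, 0.1)
})

test_that("held-out trials never influence training predictions", {
  tabs <- lapply(1:3, function(i) synthetic_decoding_tab(noise_sd = 0.3, seed = i))
  names(tabs) <- paste0("n", 1:3)
  pp <- assemble_pseudopopulation(tabs, seed = 4)
  folds <- cv_folds(pp)
  test_idx <- which(folds == 1)
  # permuting the held-out rows (jointly in X and y) leaves the fold R2 unchanged
  perm <- sample(test_idx)
  pp_perm <- pp
  pp_perm$X[test_idx, ] <- pp$X[perm, ]
  pp_perm$y[test_idx] <- pp$y[perm]
  expect_equal(run_svr_cv(pp)$fold_r2[1], run_svr_cv(pp_perm)$fold_r2[1])
})

test_that("both accuracy definitions are available and ranked sensibly", {
  tabs <- lapply(1:4, function(i) synthetic_decoding_tab(noise_sd = 0.15, seed = i))
  names(tabs) <- paste0("n", 1:4)
  pp <- assemble_pseudopopulation(tabs, seed = 11)
  sse <- run_svr_cv(pp, r2_method = "sse")$mean_r2
  corr <- run_svr_cv(pp, r2_method = "cor")$mean_r2
  expect_true(sse >= 0 && sse <= 1)
  expect_gte(corr, sse - 1e-9)  # floored explained variance cannot exceed cor^2
})

test_that("decoding curves are reproducible and separate real from shuffled data", {
  tabs <- lapply(1:6, function(i) synthetic_decoding_tab(noise_sd = 0.25, seed = i))
  names(tabs) <- paste0("n", 1:6)
  cv1 <- decoding_curve(tabs, "random", sizes = c(2, 6), n_iterations = 15,
                        seed = 21)
  cv2 <- decoding_curve(tabs, "random", sizes = c(2, 6), n_iterations = 15,
                        seed = 21)
  expect_identical(cv1, cv2)
  expect_true(all(cv1$significant))
  expect_true(all(cv1$shuffle_mean_r2 < 0.1))
  expect_gt(cv1$mean_r2[cv1$n_neurons == 6], cv1$mean_r2[cv1$n_neurons == 2] - 0.05)
})

test_that("ordering policies rank by per-neuron encoding quality", {
  # neurons with graded noise: n1 best ... n6 worst
  tabs <- lapply(1:6, function(i)
    synthetic_decoding_tab(noise_sd = 0.05 * i^1.5, seed = 30 + i))
  names(tabs) <- paste0("n", 1:6)
  best <- decoding_curve(tabs, "best_first", sizes = 2, n_iterations = 15, seed = 3)
  worst <- decoding_curve(tabs, "worst_first", sizes = 2, n_iterations = 15, seed = 3)
  expect_gt(best$mean_r2, worst$mean_r2)
})
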