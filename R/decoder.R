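#' Discretize bids into the ten decoding categories
#'
#' Equal-width decile partition of the bid space: category k covers
#' \code{((k-1)/10, k/10]}, with category 1 also including a bid of exactly 0.
#'
#' @param bids Normalized bids in \code{[0, 1]}.
#' @return Integer category labels 1..10.
#' @export
discretize_for_decoding <- function(bids) {
  check_bid(bids)
  k <- ceiling(bids * 10)
  k[k < 1L] <- 1L
  as.integer(k)
}

#' Per-neuron decoding tables
#'
#' Extracts, per neuron, the trial bids, windowed responses and decoding
#' categories used for pseudo-population assembly.
#'
#' @param recordings List of \code{neuron_recording}.
#' @param window [analysis_window()] for the value component.
#' @param event Raster to window.
#' @return Named list of data frames (\code{bid}, \code{response},
#'   \code{category}), one per neuron.
#' @export
decoding_tables <- function(recordings, window = analysis_window(180, 360),
                            event = "fractal") {
  tabs <- lapply(recordings, function(r) {
    data.frame(bid = r$trials$bid,
               response = windowed_response(r, event, window),
               category = discretize_for_decoding(r$trials$bid))
  })
  names(tabs) <- vapply(recordings, `[[`, character(1), "neuron_id")
  tabs
}

neuron_eligible <- function(tab, n_per_category = 10L) {
  counts <- tabulate(tab$category, nbins = 10L)
  all(counts >= n_per_category)
}

#' Assemble a pseudo-population response matrix
#'
#' For every eligible neuron (at least \code{n_per_category} trials in each
#' of the ten bid categories) and every category, \code{n_per_category}
#' trials are sampled uniformly without replacement; the i-th sampled trial
#' of each neuron within a category forms pseudo-trial i of that category
#' (non-simultaneously recorded neurons joined on the shared bid category).
#' The regression target of each pseudo-trial is the actual bid of the trial
#' contributed by a randomly designated anchor neuron for that category,
#' preserving the continuous character of the bids.
#'
#' @param tabs Per-neuron tables from [decoding_tables()] (or a compatible
#'   list of data frames with \code{bid}, \code{response}, \code{category}).
#' @param seed RNG seed for the trial selection.
#' @param n_per_category Trials sampled per category per neuron (default 10,
#'   giving 100 pseudo-trials).
#' @return An object of class \code{pseudo_population}: response matrix
#'   \code{X} (pseudo-trials x neurons), target \code{y}, \code{category}
#'   labels, and \code{excluded} neuron names.
#' @export
assemble_pseudopopulation <- function(tabs, seed = NULL,
                                      n_per_category = 10L) {
  eligible <- vapply(tabs, neuron_eligible, logical(1),
                     n_per_category = n_per_category)
  excluded <- names(tabs)[!eligible]
  if (length(excluded))
    message("neurons excluded (fewer than ", n_per_category,
            " trials in some bid category): ", paste(excluded, collapse = ", "))
  tabs <- tabs[eligible]
  if (length(tabs) == 0L) stop_domain("no eligible neurons")
  n_cat <- 10L
  n_pt <- n_cat * n_per_category

  with_seed(seed, {
    X <- matrix(NA_real_, n_pt, length(tabs),
                dimnames = list(NULL, names(tabs)))
    bid_draws <- array(NA_real_, dim = c(n_pt, length(tabs)))
    for (j in seq_along(tabs)) {
      tab <- tabs[[j]]
      for (k in seq_len(n_cat)) {
        rows <- which(tab$category == k)
        pick <- rows[sample.int(length(rows), n_per_category)]
        slot <- (k - 1L) * n_per_category + seq_len(n_per_category)
        X[slot, j] <- tab$response[pick]
        bid_draws[slot, j] <- tab$bid[pick]
      }
    }
    anchor <- sample.int(length(tabs), n_cat, replace = TRUE)
    y <- numeric(n_pt)
    for (k in seq_len(n_cat)) {
      slot <- (k - 1L) * n_per_category + seq_len(n_per_category)
      y[slot] <- bid_draws[slot, anchor[k]]
    }
    structure(list(X = X, y = y,
                   category = rep(seq_len(n_cat), each = n_per_category),
                   n_per_category = n_per_category,
                   excluded = excluded),
              class = "pseudo_population")
  })
}

#' @export
print.pseudo_population <- function(x, ...) {
  cat("Pseudo-population:", nrow(x$X), "pseudo-trials x", ncol(x$X),
      "neurons (", x$n_per_category, "trials per bid category )\n")
  invisible(x)
}

#' Cross-validation fold assignment for a pseudo-population
#'
#' Five folds partition the sampled trials within each bid category: fold f
#' holds out sampled positions 2f-1 and 2f of every category, so each fold
#' trains on 8 and tests on 2 trials per category (80%/20%). Sampled
#' positions are already in random order from the assembly.
#'
#' @param pp A \code{pseudo_population}.
#' @param n_folds Number of folds (default 5).
#' @return Integer vector of fold labels per pseudo-trial.
#' @export
cv_folds <- function(pp, n_folds = 5L) {
  per_fold <- pp$n_per_category %/% n_folds
  pos <- rep(seq_len(pp$n_per_category), times = max(pp$category))
  ((pos - 1L) %/% per_fold) + 1L
}

svr_fold_r2 <- function(X, y, train, test, r2_method, cost, epsilon) {
  mu <- colMeans(X[train, , drop = FALSE])
  sdev <- apply(X[train, , drop = FALSE], 2L, stats::sd)
  sdev[sdev == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdev, "/")
  if (stats::sd(y[train]) == 0 || all(apply(X[train, , drop = FALSE], 2L,
                                            stats::sd) == 0))
    return(NA_real_)
  fit <- e1071::svm(Xs[train, , drop = FALSE], y[train], type = "eps-regression",
                    kernel = "linear", cost = cost, epsilon = epsilon,
                    scale = FALSE)
  pred <- stats::predict(fit, Xs[test, , drop = FALSE])
  actual <- y[test]
  if (r2_method == "cor") {
    if (stats::sd(pred) == 0 || stats::sd(actual) == 0) return(NA_real_)
    return(stats::cor(pred, actual)^2)
  }
  sst <- sum((actual - mean(actual))^2)
  if (sst == 0) return(NA_real_)
  max(0, 1 - sum((actual - pred)^2) / sst)
}

#' Cross-validated SVR decoding of bids from a pseudo-population
#'
#' Linear support-vector regression of the bid on the neuron response vector,
#' five-fold cross-validated (8 training and 2 test trials per bid category
#' per fold). Responses are standardized by training-fold statistics. The
#' reported per-fold accuracy is the held-out explained variance
#' \code{max(0, 1 - SSE/SST)} by default (so chance-level decoding reports
#' 0); \code{r2_method = "cor"} gives the squared Pearson correlation
#' instead.
#'
#' @param pp A \code{pseudo_population}.
#' @param r2_method \code{"sse"} (floored 1 - SSE/SST, default) or
#'   \code{"cor"}.
#' @param cost,epsilon SVR hyperparameters (library defaults).
#' @return List with \code{fold_r2} (five values) and \code{mean_r2}.
#'   Degenerate folds (constant targets or responses) yield \code{NA} and are
#'   excluded from the mean with a warning.
#' @export
run_svr_cv <- function(pp, r2_method = c("sse", "cor"), cost = 1,
                       epsilon = 0.1) {
  r2_method <- match.arg(r2_method)
  folds <- cv_folds(pp)
  r2 <- vapply(sort(unique(folds)), function(f) {
    svr_fold_r2(pp$X, pp$y, which(folds != f), which(folds == f),
                r2_method, cost, epsilon)
  }, numeric(1))
  if (anyNA(r2)) warning("degenerate fold(s) excluded from the mean")
  list(fold_r2 = r2, mean_r2 = mean(r2, na.rm = TRUE))
}

#' Neuron-dropping decoding curve with shuffle null
#'
#' Mean cross-validated decoding accuracy as a function of the number of
#' neurons in the pseudo-population, under an ordering policy: neurons added
#' in random order (fresh order per iteration), or from best to worst /
#' worst to best bid encoding (ordered by their simple-regression R2 with the
#' bids). For every population size, \code{n_iterations} fresh random trial
#' selections are assembled, decoded, and decoded again with bid labels
#' permuted across pseudo-trials (the shuffle null); real and shuffled
#' iteration-level accuracies are compared with a Wilcoxon rank-sum test.
#'
#' @param tabs Per-neuron tables from [decoding_tables()].
#' @param ordering \code{"random"}, \code{"best_first"} or
#'   \code{"worst_first"}.
#' @param sizes Population sizes to evaluate (default: 1 to the number of
#'   eligible neurons).
#' @param n_iterations Trial-selection iterations per size (default 300; use
#'   fewer at desk scale).
#' @param seed Seed; the full curve is reproducible from it.
#' @param alpha Level of the real-vs-shuffle comparison (default 0.01).
#' @param r2_method,cost,epsilon Passed to [run_svr_cv()].
#' @return A data frame of class \code{decoding_curve}: one row per size with
#'   \code{ordering}, \code{n_neurons}, \code{mean_r2}, \code{sd_r2},
#'   \code{shuffle_mean_r2}, \code{p_vs_shuffle}, \code{significant}.
#'   Iteration-level values are kept in \code{attr(, "iterations")}.
#' @export
decoding_curve <- function(tabs, ordering = c("random", "best_first",
                                              "worst_first"),
                           sizes = NULL, n_iterations = 300L, seed = 1L,
                           alpha = 0.01, r2_method = c("sse", "cor"),
                           cost = 1, epsilon = 0.1) {
  ordering <- match.arg(ordering)
  r2_method <- match.arg(r2_method)
  eligible <- vapply(tabs, neuron_eligible, logical(1))
  tabs <- tabs[eligible]
  if (length(tabs) == 0L) stop_domain("no eligible neurons")
  N <- length(tabs)
  sizes <- sizes %||% seq_len(N)
  if (any(sizes > N)) stop_domain("requested size exceeds eligible neurons")

  if (ordering != "random") {
    r2_neuron <- vapply(tabs, function(tab)
      bid_regression(tab$response, tab$bid)$r2, numeric(1))
    ord <- order(r2_neuron, decreasing = (ordering == "best_first"))
    tabs <- tabs[ord]
  }

  iter_seeds <- derive_seeds(seed, n_iterations)
  rows <- list()
  iter_store <- list()
  for (n in sizes) {
    real <- shuf <- numeric(n_iterations)
    for (it in seq_len(n_iterations)) {
      res <- with_seed(iter_seeds[[it]], {
        subset_tabs <- if (ordering == "random")
          tabs[sample.int(N, n)] else tabs[seq_len(n)]
        pp <- assemble_pseudopopulation(subset_tabs, seed = NULL)
        r_real <- run_svr_cv(pp, r2_method, cost, epsilon)$mean_r2
        pp$y <- sample(pp$y)
        r_shuf <- run_svr_cv(pp, r2_method, cost, epsilon)$mean_r2
        c(r_real, r_shuf)
      })
      real[it] <- res[1]; shuf[it] <- res[2]
    }
    p <- suppressWarnings(stats::wilcox.test(real, shuf, exact = FALSE)$p.value)
    rows[[length(rows) + 1L]] <- data.frame(
      ordering = ordering, n_neurons = n,
      mean_r2 = mean(real), sd_r2 = stats::sd(real),
      shuffle_mean_r2 = mean(shuf), p_vs_shuffle = p,
      significant = is.finite(p) && p < alpha)
    iter_store[[as.character(n)]] <- data.frame(n_neurons = n,
                                                iteration = seq_len(n_iterations),
                                                real_r2 = real, shuffle_r2 = shuf)
  }
  out <- do.call(rbind, rows)
  attr(out, "iterations") <- do.call(rbind, iter_store)
  attr(out, "r2_method") <- r2_method
  class(out) <- c("decoding_curve", "data.frame")
  out
}

#' @export
print.decoding_curve <- function(x, ...) {
  cat("Decoding curve (", x$ordering[1], " ordering, accuracy = ",
      if (attr(x, "r2_method") %||% "sse" == "sse")
        "floored 1-SSE/SST" else "squared correlation", ")\n", sep = "")
  print(as.data.frame(x)[, c("n_neurons", "mean_r2", "shuffle_mean_r2",
                             "p_vs_shuffle")], digits = 3)
  invisible(x)
}

#' Calibrate the neuronal value gain against a population regression target
#'
#' Constrains the value gain of the synthetic bid-coding neurons so that the
#' pooled z-normalized population response, averaged within 25 bid bins and
#' regressed on the bids, attains an R2 inside \code{target} (the
#' population-level effect-size band of the recorded populations). The
#' calibration is constraint satisfaction, not optimization: the gain starts
#' at its configured default (chosen for physiological realism of the phasic
#' modulation) and is verified against the band; only when the population R2
#' falls outside the band is the gain stepped along the grid in the
#' direction that restores it (the R2 is monotone in the gain up to its
#' asymmetry-limited plateau).
#'
#' @param dataset A \code{bdm_dataset} (or single \code{bdm_session}) used
#'   for the calibration population; with several sessions the neurons are
#'   distributed over them as in non-simultaneous recording.
#' @param gain_grid Candidate gains (Hz/ml), increasing, used when the
#'   default is out of band.
#' @param target R2 band, default \code{c(0.85, 0.95)}.
#' @param n_neurons Neurons per candidate population.
#' @param window [analysis_window()] used for the responses.
#' @param config Base [neuron_config()]; its \code{value_gain_hz} is the
#'   starting point.
#' @param seed RNG seed.
#' @return List with \code{gain} (the calibrated gain, or NA when no
#'   candidate lands in the band) and \code{table} (gain, population R2, in
#'   evaluation order).
#' @export
calibrate_value_gain <- function(dataset, gain_grid = seq(2, 30, by = 2),
                                 target = c(0.85, 0.95), n_neurons = 20L,
                                 window = analysis_window(180, 360),
                                 config = neuron_config(), seed = 1L) {
  pop_r2 <- function(gain, seed_offset) {
    cfg <- config
    cfg$value_gain_hz <- gain
    pop <- simulate_population(dataset, n_bid_coders = n_neurons,
                               config = cfg, gain_jitter = 0.5,
                               seed = seed + seed_offset)
    tbl <- response_table(pop$recordings, window)
    binned_population_regression(tbl$z, tbl$bid)$r2
  }
  tried <- data.frame(gain = numeric(), population_r2 = numeric())
  evaluate <- function(gain) {
    r2 <- pop_r2(gain, nrow(tried))
    tried[nrow(tried) + 1L, ] <<- c(gain, r2)
    r2
  }
  gain <- config$value_gain_hz
  r2 <- evaluate(gain)
  if (r2 < target[1] || r2 > target[2]) {
    candidates <- if (r2 < target[1])
      sort(gain_grid[gain_grid > gain]) else
      sort(gain_grid[gain_grid < gain], decreasing = TRUE)
    gain <- NA_real_
    for (g in candidates) {
      r2 <- evaluate(g)
      if (r2 >= target[1] && r2 <= target[2]) { gain <- g; break }
    }
  }
  list(gain = gain, table = tried)
}
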