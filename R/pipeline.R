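#' Pipeline configuration
#'
#' Bundles generator, analysis and decoder parameters for an end-to-end run:
#' synthetic behavior, behavioral statistics, neuronal simulation and
#' analysis, and pseudo-population decoding. Every random stage consumes a
#' seed derived from the single pipeline seed.
#'
#' @param subject Subject profile passed to [subject_profile()].
#' @param n_sessions,n_trials Behavioral scale.
#' @param n_bid_coders,n_null_dopamine,n_non_dopamine Population composition.
#' @param value_gain_hz Value gain of the bid coders (Hz/ml).
#' @param alpha Significance level for classification and behavioral tests.
#' @param matched_bid_tolerance Bid tolerance of the matched-bid test.
#' @param decode_sizes Population sizes of the decoding curve.
#' @param decode_iterations Trial-selection iterations per size.
#' @param seed Master seed.
#' @param ... Extra overrides forwarded to [subject_profile()].
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(subject = "decoding", n_sessions = 2L,
                            n_trials = 400L, n_bid_coders = 12L,
                            n_null_dopamine = 4L, n_non_dopamine = 4L,
                            value_gain_hz = 12, alpha = 0.05,
                            matched_bid_tolerance = 0.05,
                            decode_sizes = c(1L, 5L, 10L),
                            decode_iterations = 20L, seed = 1L, ...) {
  structure(list(subject = subject, n_sessions = as.integer(n_sessions),
                 n_trials = as.integer(n_trials),
                 n_bid_coders = as.integer(n_bid_coders),
                 n_null_dopamine = as.integer(n_null_dopamine),
                 n_non_dopamine = as.integer(n_non_dopamine),
                 value_gain_hz = value_gain_hz, alpha = alpha,
                 matched_bid_tolerance = matched_bid_tolerance,
                 decode_sizes = as.integer(decode_sizes),
                 decode_iterations = as.integer(decode_iterations),
                 seed = seed, profile_args = list(...)),
            class = "pipeline_config")
}

write_stage <- function(df, outdir, name) {
  if (!is.null(outdir))
    utils::write.csv(df, file.path(outdir, paste0(name, ".csv")),
                     row.names = FALSE)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes generate -> behavioral analysis -> neuronal analysis -> decoding
#' and returns (and optionally writes) the result bundle: rank-order and
#' coherence statistics, lasso selection, mixed-model fits, the analysis
#' window, the classification manifest, per-magnitude bid regressions, the
#' matched-bid comparisons, movement controls, and the decoding curve with
#' its shuffle null. Any stage failure aborts with a stage-tagged error;
#' artifacts written before the failure are retained.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory for tabular artifacts and the run
#'   log.
#' @return A list of class \code{pipeline_result}.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 4L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log_lines <- c(paste("bdmvalue", as.character(utils::packageVersion("bdmvalue"))),
                 paste("seed", config$seed), paste("run", format(Sys.time())))

  ## 1. behavior generation
  result <- list(config = config)
  dataset <- stage("generate", {
    prof <- do.call(subject_profile,
                    c(list(subject = config$subject,
                           n_trials = config$n_trials),
                      config$profile_args))
    generate_dataset(prof, n_sessions = config$n_sessions, seed = seeds[[1]],
                     subject_id = config$subject)
  })
  result$dataset <- dataset
  if (!is.null(outdir))
    write_session_table(dataset, file.path(outdir, "sessions.csv"))

  ## 2. behavioral statistics
  result$behavior <- stage("behavior_analysis", {
    dm <- build_design_matrix(dataset)
    list(rank_order = rank_order_check(dataset, alpha = config$alpha),
         lasso = lasso_select(dm, seed = seeds[[2]]),
         mixed_models = lapply(stats::setNames(nm = c("Eq1", "Eq2", "Eq3")),
                               function(tag) fit_mixed_model(dm, tag)),
         coherence = lapply(dataset, bid_coherence),
         design_matrix = dm)
  })
  write_stage(result$behavior$rank_order$per_session, outdir, "rank_order")

  ## 3. neuronal simulation and analysis
  result$neurons <- stage("neural_analysis", {
    ncfg <- neuron_config(value_gain_hz = config$value_gain_hz)
    pop <- simulate_population(dataset,
                               n_bid_coders = config$n_bid_coders,
                               n_null_dopamine = config$n_null_dopamine,
                               n_non_dopamine = config$n_non_dopamine,
                               config = ncfg, seed = seeds[[3]])
    coders <- pop$recordings[pop$manifest$type == "bid_coder"]
    if (length(coders) == 0L)
      coders <- pop$recordings[pop$manifest$type == "null_dopamine"]
    window <- if (length(coders) == 0L) NULL else
      suppressWarnings(population_analysis_window(coders))
    window <- window %||% analysis_window(180, 360)
    classification <- classify_population(pop$recordings, window,
                                          alpha = config$alpha)
    da <- pop$recordings[classification$is_dopamine]
    tbl <- response_table(da, window)
    list(population = pop, window = window, classification = classification,
         response_table = tbl,
         per_magnitude = magnitude_regression_constant_magnitude(tbl),
         population_fit = binned_population_regression(tbl$z, tbl$bid),
         matched_bid = lapply(list(c(1, 2), c(2, 3), c(1, 3)), function(p)
           matched_bid_comparison(tbl, p,
                                  tolerance = config$matched_bid_tolerance)),
         movement = movement_control_regressions(tbl, alpha = config$alpha))
  })
  write_stage(result$neurons$classification, outdir, "classification")
  write_stage(result$neurons$response_table, outdir, "response_table")

  ## 4. decoding
  result$decoding <- stage("population_decoder", {
    cls <- result$neurons$classification
    coders <- result$neurons$population$recordings[cls$is_bid_encoding]
    if (length(coders) == 0L) coders <- result$neurons$population$recordings
    tabs <- decoding_tables(coders, result$neurons$window)
    eligible <- vapply(tabs, neuron_eligible, logical(1))
    if (!any(eligible)) {
      list(curve = NULL, note = "no neurons eligible for decoding")
    } else {
      sizes <- config$decode_sizes[config$decode_sizes <= sum(eligible)]
      list(curve = decoding_curve(tabs[eligible], "random", sizes = sizes,
                                  n_iterations = config$decode_iterations,
                                  seed = seeds[[4]]),
           note = NULL)
    }
  })
  if (!is.null(result$decoding$curve))
    write_stage(as.data.frame(result$decoding$curve), outdir, "decoding_curve")

  if (!is.null(outdir)) {
    log_lines <- c(log_lines,
                   paste("window",
                         result$neurons$window$start_ms,
                         result$neurons$window$end_ms),
                   paste("n_bid_encoding",
                         sum(result$neurons$classification$is_bid_encoding)))
    writeLines(log_lines, file.path(outdir, "run_log.txt"))
  }
  class(result) <- "pipeline_result"
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("BDM pipeline result\n")
  ro <- x$behavior$rank_order
  cat(sprintf("  behavior: pooled rho2 = %.2f, %d%% sessions significant\n",
              ro$pooled_rho2, round(100 * ro$frac_sessions_significant)))
  cl <- x$neurons$classification
  cat(sprintf("  neurons: %d recorded, %d dopamine, %d bid-encoding; window [%d, %d) ms\n",
              nrow(cl), sum(cl$is_dopamine), sum(cl$is_bid_encoding),
              x$neurons$window$start_ms, x$neurons$window$end_ms))
  if (!is.null(x$decoding$curve)) {
    top <- x$decoding$curve[which.max(x$decoding$curve$n_neurons), ]
    cat(sprintf("  decoding: %.0f%% accuracy at n = %d (shuffle %.0f%%)\n",
                100 * top$mean_r2, top$n_neurons, 100 * top$shuffle_mean_r2))
  } else cat("  decoding:", x$decoding$note, "\n")
  invisible(x)
}
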