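#' Write / read configuration as plain-text key: value files
#'
#' Flat serialization of the generator and analysis configurations; numeric
#' vectors are comma-separated. Round-trips losslessly for the flat configs
#' used in this package.
#'
#' @param config A \code{behavior_config}, \code{neuron_config},
#'   \code{auction_config} or plain named list.
#' @param path Output file.
#' @export
write_config <- function(config, path) {
  cls <- class(config)[1]
  lines <- c(paste0(".class: ", cls),
             vapply(names(config), function(nm) {
               v <- config[[nm]]
               if (is.null(v)) v <- "NULL"
               paste0(nm, ": ", paste(v, collapse = ","))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @return \code{read_config} returns the configuration list with its class
#'   restored.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  kv <- regmatches(lines, regexpr(": ", lines), invert = TRUE)
  out <- list()
  cls <- "list"
  for (p in kv) {
    key <- p[1]; val <- p[2]
    if (key == ".class") { cls <- val; next }
    if (identical(val, "NULL")) { out[key] <- list(NULL); next }
    parts <- strsplit(val, ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) parts <- num
    else if (all(parts %in% c("TRUE", "FALSE"))) parts <- as.logical(parts)
    out[[key]] <- parts
  }
  if (cls != "list") class(out) <- cls
  out
}

session_required_cols <- c(
  "trial", "session_id", "subject_id", "session_number", "day_of_week",
  "magnitude_level", "magnitude_ml", "latent_value_ml", "starting_bid",
  "bid", "computer_bid", "won", "juice_ml", "water_ml", "price_paid",
  "total_liquid_ml", "win_streak", "lose_streak", "prev_same_mag_comp_bid",
  "prev_same_mag_result", "movement_velocity", "movement_absement", "failed")

#' Write / read session trial tables
#'
#' Sessions (or whole datasets) are interchanged as comma-separated text with
#' a header, one row per trial, using the documented column dictionary of
#' [generate_session()]. \code{write_session_table} optionally writes the
#' generator config next to the table so the round trip preserves it.
#'
#' @param x A \code{bdm_session} or \code{bdm_dataset}.
#' @param path CSV output path.
#' @param config_path Optional path for the generator config
#'   (default: \code{path} with a \code{.config} suffix; \code{NULL} skips).
#' @export
write_session_table <- function(x, path,
                                config_path = paste0(path, ".config")) {
  cfg <- attr(x, "config")
  df <- trial_table(x, completed_only = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(config_path) && !is.null(cfg)) write_config(cfg, config_path)
  invisible(path)
}

#' @rdname write_session_table
#' @return \code{read_session_table} returns a \code{bdm_dataset} (list of
#'   \code{bdm_session}); missing required columns raise a schema error
#'   naming the column.
#' @export
read_session_table <- function(path, config_path = paste0(path, ".config")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(session_required_cols, colnames(df))
  if (length(missing))
    stop_domain("session table schema error; missing column(s): ",
                paste(missing, collapse = ", "))
  cfg <- if (!is.null(config_path) && file.exists(config_path))
    read_config(config_path) else NULL
  sessions <- lapply(split(df, df$session_id), function(s) {
    s <- s[order(s$trial), , drop = FALSE]
    rownames(s) <- NULL
    attr(s, "config") <- cfg
    class(s) <- c("bdm_session", "data.frame")
    s
  })
  sessions <- sessions[order(vapply(sessions, function(s)
    s$session_number[1], numeric(1)))]
  structure(unname(sessions), class = "bdm_dataset", config = cfg)
}

#' Write / read spike data as plain tabular text
#'
#' Spike data are interchanged as two CSV files: an event-time table
#' (\code{neuron_id}, \code{trial_id}, \code{event}, \code{time_ms}; integer
#' milliseconds relative to the named alignment event, one row per spike)
#' and a neuron manifest (\code{neuron_id}, \code{waveform_ms},
#' \code{session_id}, raster extents). Reading reconstructs the 1-ms count
#' rasters and checks that every spike references an existing completed trial
#' of the accompanying session.
#'
#' @param recordings List of \code{neuron_recording} (or a
#'   \code{neuron_population}).
#' @param events_path,manifest_path CSV paths.
#' @export
write_spike_table <- function(recordings, events_path, manifest_path) {
  if (inherits(recordings, "neuron_population")) recordings <- recordings$recordings
  ev_rows <- list()
  mf_rows <- list()
  for (r in recordings) {
    for (ev in names(r$rasters)) {
      raster <- r$rasters[[ev]]
      times <- as.integer(colnames(raster))
      idx <- which(raster > 0, arr.ind = TRUE)
      if (nrow(idx)) {
        reps <- raster[idx]
        ev_rows[[length(ev_rows) + 1L]] <- data.frame(
          neuron_id = r$neuron_id,
          trial_id = rep(r$trials$trial[idx[, 1]], reps),
          event = ev,
          time_ms = rep(times[idx[, 2]], reps))
      }
      mf_rows[[length(mf_rows) + 1L]] <- data.frame(
        neuron_id = r$neuron_id, event = ev,
        waveform_ms = r$waveform_ms, session_id = r$session_id,
        t_min = times[1], t_max = times[length(times)])
    }
  }
  utils::write.csv(do.call(rbind, ev_rows), events_path, row.names = FALSE)
  utils::write.csv(do.call(rbind, mf_rows), manifest_path, row.names = FALSE)
  invisible(events_path)
}

#' @rdname write_spike_table
#' @param dataset The \code{bdm_dataset} (or single session) the spikes refer
#'   to; trial references are validated against it.
#' @return \code{read_spike_table} returns a list of
#'   \code{neuron_recording} objects.
#' @export
read_spike_table <- function(events_path, manifest_path, dataset) {
  if (inherits(dataset, "bdm_session"))
    dataset <- structure(list(dataset), class = "bdm_dataset")
  ev <- utils::read.csv(events_path, stringsAsFactors = FALSE)
  mf <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  for (col in c("neuron_id", "trial_id", "event", "time_ms"))
    if (!col %in% colnames(ev))
      stop_domain("spike table schema error; missing column: ", col)
  sessions <- stats::setNames(dataset, vapply(dataset, function(s)
    as.character(s$session_id[1]), character(1)))
  recs <- lapply(split(mf, mf$neuron_id), function(m) {
    sess <- sessions[[as.character(m$session_id[1])]]
    if (is.null(sess))
      stop_domain("spike manifest references unknown session ",
                  m$session_id[1])
    trials <- trial_table(sess)[, c("trial", "bid", "magnitude_level",
                                    "magnitude_ml", "movement_velocity",
                                    "movement_absement")]
    spikes <- ev[ev$neuron_id == m$neuron_id[1], , drop = FALSE]
    bad <- setdiff(unique(spikes$trial_id), trials$trial)
    if (length(bad))
      stop_domain("spike table references unknown trial_id(s): ",
                  paste(utils::head(bad, 5), collapse = ", "))
    rasters <- list()
    for (i in seq_len(nrow(m))) {
      times <- m$t_min[i]:m$t_max[i]
      raster <- matrix(0L, nrow(trials), length(times),
                       dimnames = list(NULL, times))
      sp <- spikes[spikes$event == m$event[i], , drop = FALSE]
      if (nrow(sp)) {
        ti <- match(sp$trial_id, trials$trial)
        ci <- sp$time_ms - m$t_min[i] + 1L
        for (s in seq_len(nrow(sp))) raster[ti[s], ci[s]] <- raster[ti[s], ci[s]] + 1L
      }
      rasters[[m$event[i]]] <- raster
    }
    structure(list(neuron_id = m$neuron_id[1], waveform_ms = m$waveform_ms[1],
                   config = NULL, session_id = m$session_id[1],
                   trials = trials, rasters = rasters,
                   baseline_window = c(-1000, -500)),
              class = "neuron_recording")
  })
  unname(recs)
}
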