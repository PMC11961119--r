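# One CSV per acquisition stream plus a JSON config; all times are absolute
# seconds from session start.

validate_photometry <- function(df) {
  need <- c("t", "f405", "f475")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stopf("pa_schema_error", "photometry is missing column(s): %s",
          paste(miss, collapse = ", "))
  }
  bad <- which(!complete.cases(df[need]) | !is.finite(df$t) |
               !is.finite(df$f405) | !is.finite(df$f475))
  if (length(bad) > 0) {
    stopf("pa_validation_error", "photometry has missing/non-finite sample(s) at row(s): %s",
          paste(head(bad, 10), collapse = ", "))
  }
  if (any(diff(df$t) <= 0)) {
    abort("photometry time is not strictly increasing", class = "pa_validation_error")
  }
  invisible(df)
}

validate_speed <- function(df) {
  need <- c("t", "speed")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stopf("pa_schema_error", "tracking is missing column(s): %s",
          paste(miss, collapse = ", "))
  }
  if (any(!is.finite(df$t)) || any(diff(df$t) <= 0)) {
    abort("tracking time is not strictly increasing", class = "pa_validation_error")
  }
  if (any(df$speed < 0, na.rm = TRUE)) {
    abort("speed must be non-negative", class = "pa_validation_error")
  }
  invisible(df)
}

validate_events <- function(df) {
  need <- c("event_type", "time")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stopf("pa_schema_error", "events are missing column(s): %s",
          paste(miss, collapse = ", "))
  }
  if (sum(df$event_type == "first_shock") > 1) {
    abort("at most one first_shock event per session", class = "pa_validation_error")
  }
  on <- df[df$event_type == "tone_on", ]
  off <- df[df$event_type == "tone_off", ]
  shared <- intersect(on$trial_id, off$trial_id)
  shared <- shared[!is.na(shared)]
  for (id in shared) {
    if (off$time[match(id, off$trial_id)] < on$time[match(id, on$trial_id)]) {
      stopf("pa_validation_error", "tone_off precedes tone_on in trial %s", id)
    }
  }
  invisible(df)
}

#' Write a session to a directory
#'
#' One RFC-4180 CSV per stream (`photometry.csv`, `tracking.csv`,
#' `events.csv`, `trials.csv`) plus `config.json` and, when present,
#' `ground_truth.json` and `video.tif`. Numbers are written at full precision
#' so a read/write round trip is lossless.
#'
#' @param session a `pa_session` (from [simulate_session()] or
#'   [read_session()]).
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_session <- function(session, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("pa_io_error", "cannot create directory '%s'", dir)
  }
  if (!is.null(session$photometry)) {
    readr::write_csv(session$photometry, file.path(dir, "photometry.csv"))
  }
  readr::write_csv(session$speed, file.path(dir, "tracking.csv"))
  readr::write_csv(session$events, file.path(dir, "events.csv"))
  if (!is.null(session$trials)) {
    readr::write_csv(session$trials, file.path(dir, "trials.csv"))
  }
  cfg <- unclass(session$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(session$ground_truth)) {
    gt <- session$ground_truth
    ser <- list(
      params = unclass(gt$params),
      bleach_475 = as.list(gt$bleach_475),
      bleach_405 = as.list(gt$bleach_405),
      post_shock_gain = gt$post_shock_gain,
      first_shock = gt$first_shock,
      movement_epochs = gt$movement_epochs,
      iti_cross_times = gt$iti_cross_times,
      freezing_bouts = gt$freezing_bouts,
      session_end = gt$session_end
    )
    jsonlite::write_json(ser, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (!is.null(session$video) && requireNamespace("tiff", quietly = TRUE)) {
    fr <- purrr::map(seq_len(dim(session$video)[3]),
                     function(i) session$video[, , i])
    tiff::writeTIFF(fr, file.path(dir, "video.tif"))
  }
  invisible(dir)
}

#' Read a session from a directory
#'
#' Reads the file set written by [write_session()] (or equivalent exports:
#' per-stream CSVs with documented columns and a JSON config), validates every
#' stream (schema, monotone time, no missing samples, event ordering) and
#' returns an in-memory session with times in seconds and speeds in cm/s.
#'
#' @param dir session directory.
#' @return a `pa_session`.
#' @export
read_session <- function(dir) {
  need <- file.path(dir, c("tracking.csv", "events.csv", "config.json"))
  missing_files <- need[!file.exists(need)]
  if (length(missing_files) > 0) {
    stopf("pa_io_error", "missing session file(s): %s",
          paste(basename(missing_files), collapse = ", "))
  }
  cfg_raw <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg <- do.call(session_config, c(
    cfg_raw[intersect(names(cfg_raw), names(formals(session_config)))],
    cfg_raw[setdiff(names(cfg_raw), c(names(formals(session_config)), "task"))]
  ))
  phot <- NULL
  pf <- file.path(dir, "photometry.csv")
  if (file.exists(pf)) {
    phot <- readr::read_csv(pf, show_col_types = FALSE)
    validate_photometry(phot)
  }
  speed <- readr::read_csv(file.path(dir, "tracking.csv"), show_col_types = FALSE)
  validate_speed(speed)
  # base read.csv parses doubles with strtod, which is exact to the last ulp;
  # the event table round trip is required to be bitwise
  events <- as_tibble(utils::read.csv(
    file.path(dir, "events.csv"),
    colClasses = c(event_type = "character", time = "numeric",
                   trial_id = "integer")
  ))
  validate_events(events)
  trials <- NULL
  tf <- file.path(dir, "trials.csv")
  if (file.exists(tf)) trials <- readr::read_csv(tf, show_col_types = FALSE)
  video <- NULL
  vf <- file.path(dir, "video.tif")
  if (file.exists(vf) && requireNamespace("tiff", quietly = TRUE)) {
    fr <- tiff::readTIFF(vf, all = TRUE)
    video <- array(unlist(fr), dim = c(dim(fr[[1]]), length(fr)))
  }
  structure(list(photometry = phot, speed = speed, events = events,
                 trials = trials, config = cfg, ground_truth = NULL,
                 video = video), class = "pa_session")
}

#' Run the analysis pipeline
#'
#' Chains the requested stages on a seeded synthetic session (or a session
#' directory produced elsewhere), writing per-stage outputs plus a manifest
#' with MD5 checksums and a log. Stages: `simulate`, `preprocess`, `behavior`,
#' `encode`, `xcov`, `groupstats`.
#'
#' @param config a [session_config()].
#' @param stages character vector of stage names, in order.
#' @param seed integer seed for the simulate stage.
#' @param out_dir output directory.
#' @param session optional existing `pa_session` (required when `simulate` is
#'   not among the stages).
#' @param params generator parameters for `simulate`.
#' @return list with the final `session`, per-stage `results`, and the
#'   `manifest` tibble.
#' @export
run_pipeline <- function(config, stages = c("simulate", "preprocess", "behavior",
                                            "encode", "xcov", "groupstats"),
                         seed = 1, out_dir = tempfile("pa_run_"),
                         session = NULL, params = ground_truth_params()) {
  known <- c("simulate", "preprocess", "behavior", "encode", "xcov", "groupstats")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    stopf("pa_usage_error", "unknown stage name(s): %s (known: %s)",
          paste(bad, collapse = ", "), paste(known, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                       sprintf(fmt, ...)))
  }
  results <- list()
  dff15 <- NULL

  for (st in stages) {
    if (st == "simulate") {
      session <- simulate_session(config, seed, params)
      write_session(session, file.path(out_dir, "session"))
      note("simulate: %d trials, seed %d", nrow(session$trials), seed)
    }
    if (is.null(session)) {
      abort("no session: include 'simulate' or pass `session`", class = "pa_usage_error")
    }
    if (st == "preprocess") {
      d <- compute_dff(session$photometry)
      dff15 <- lowpass_resample(d$trace, session$speed$t, config$lowpass_hz)
      readr::write_csv(dff15, file.path(out_dir, "dff.csv"))
      jsonlite::write_json(unclass(d$fit), file.path(out_dir, "reference_fit.json"),
                           auto_unbox = TRUE, digits = NA)
      results$preprocess <- d
      note("preprocess: %d samples -> %d at video rate", nrow(d$trace), nrow(dff15))
    }
    if (st == "behavior") {
      trials <- score_trials(session$events, session$speed, config)
      readr::write_csv(trials, file.path(out_dir, "trials.csv"))
      wins <- iti_windows(trials, config$iti_margin_s)
      movements <- detect_movements_iti(session$speed, wins, config)
      readr::write_csv(movements, file.path(out_dir, "movements.csv"))
      results$behavior <- list(trials = trials, movements = movements)
      if (!is.null(session$video)) {
        fz <- detect_freezing(session$video, config)
        readr::write_csv(fz$trace, file.path(out_dir, "freezing.csv"))
        results$behavior$freezing <- fz
      }
      note("behavior: %d trials scored, %d ITI movements", nrow(trials), nrow(movements))
    }
    if (st == "encode") {
      if (is.null(dff15)) {
        d <- compute_dff(session$photometry)
        dff15 <- lowpass_resample(d$trace, session$speed$t, config$lowpass_hz)
      }
      enc <- encode_session(session, seed = seed)
      readr::write_csv(enc$fit$kernels, file.path(out_dir, "kernels.csv"))
      jsonlite::write_json(list(r2 = enc$fit$r2, n_samples = enc$fit$n_samples,
                                n_params = enc$fit$n_params),
                           file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
      results$encode <- enc
      note("encode: R2 = %.4f", enc$fit$r2)
    }
    if (st == "xcov") {
      if (is.null(dff15)) {
        d <- compute_dff(session$photometry)
        dff15 <- lowpass_resample(d$trace, session$speed$t, config$lowpass_hz)
      }
      trials <- results$behavior$trials %||% session$trials
      xc <- xcov_evolution(dff15, session$speed, trials, session$events, config)
      readr::write_csv(xc, file.path(out_dir, "xcov.csv"))
      results$xcov <- xc
      note("xcov: %d segments", nrow(xc))
    }
    if (st == "groupstats") {
      trials <- results$behavior$trials %||% session$trials
      hist <- crossing_probability_hist(trials, config)
      readr::write_csv(hist$hist, file.path(out_dir, "hist.csv"))
      summ <- list(stim_window_ratio = hist$stim_window_ratio)
      if (!is.null(dff15)) {
        cr <- trials$crossing_time[!is.na(trials$crossing_time) &
                                   trials$outcome %in% c("avoid", "approach", "omission")]
        if (length(cr) > 0) {
          peri <- align_to_event(dff15, cr, window = c(-4, 4), rate = config$video_rate_hz)
          pp <- pre_peri_contrast(peri)
          readr::write_csv(pp, file.path(out_dir, "peri_event.csv"))
          summ$pre_mean <- mean(pp$pre)
          summ$peri_mean <- mean(pp$peri)
        }
      }
      jsonlite::write_json(summ, file.path(out_dir, "group_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      results$groupstats <- summ
      note("groupstats: written")
    }
  }
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  files <- setdiff(list.files(out_dir, recursive = TRUE, full.names = TRUE),
                   file.path(out_dir, c("manifest.csv", "pipeline.log")))
  manifest <- tibble(file = sub(paste0("^", out_dir, "/?"), "", files),
                     md5 = unname(tools::md5sum(files)))
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  list(session = session, results = results, manifest = manifest)
}
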