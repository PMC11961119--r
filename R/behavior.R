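#' Movement threshold from k-means clustering of speed
#'
#' Speeds are grouped into three clusters (nonmovement, low movement, high
#' movement) by k-means on the scalar speed values; the movement threshold is
#' the lowest speed among samples assigned to the middle (low-movement)
#' cluster. Clusters are ordered by centroid so the result is invariant to
#' k-means label permutation. The k-means seed and restart count live in the
#' config so the threshold is reproducible.
#'
#' @param speed numeric vector of speeds (cm/s) or a tibble with a `speed`
#'   column.
#' @param kmeans_seed seed for the k-means initialization.
#' @param nstart number of random restarts.
#' @return threshold in cm/s.
#' @export
movement_threshold_oft <- function(speed, kmeans_seed = 1, nstart = 10) {
  if (is.data.frame(speed)) speed <- speed$speed
  if (length(unique(speed)) < 3) {
    abort("need at least 3 distinct speed values for 3 clusters",
          class = "pa_degenerate_error")
  }
  km <- run_seeded(kmeans_seed, kmeans(speed, centers = 3, nstart = nstart))
  ord <- order(km$centers[, 1])
  middle <- ord[2]
  min(speed[km$cluster == middle])
}

#' Movement initiation time before a speed peak
#'
#' Working back from the peak within `window_s` (default 2 s), the initiation
#' is the first sample at which speed rises above `frac` (default 10%) of the
#' peak speed and does not drop back below it before the peak. If the speed
#' never drops to or below that level within the window, the movement started
#' earlier than the window and `NA` is returned.
#'
#' @param speed tibble with `t`, `speed`.
#' @param peak_time,peak_speed the peak to work back from.
#' @param frac initiation fraction of peak speed.
#' @param window_s look-back window (s).
#' @return initiation time (s) or `NA`.
#' @export
find_movement_initiation <- function(speed, peak_time, peak_speed,
                                     frac = 0.1, window_s = 2) {
  idx <- which(speed$t >= peak_time - window_s & speed$t <= peak_time)
  if (length(idx) == 0) return(NA_real_)
  v <- speed$speed[idx]
  level <- frac * peak_speed
  below <- which(v <= level)
  if (length(below) == 0) return(NA_real_)
  first_above <- max(below) + 1L
  if (first_above > length(idx)) return(NA_real_)
  speed$t[idx[first_above]]
}

#' Detect movement epochs in the open field
#'
#' Finds speed peaks that exceed the k-means movement threshold in absolute
#' height and rise at least `min_prominence` (default 5 cm/s) above the
#' surrounding baseline, then works back to the movement initiation (first
#' sample above 10% of the peak speed within 2 s). Epochs are kept only when
#' at least `quiescence_s` (default 1 s) of sub-threshold speed immediately
#' precedes the initiation.
#'
#' @param speed tibble with `t`, `speed`.
#' @param threshold movement threshold (cm/s); computed by
#'   [movement_threshold_oft()] when `NULL`.
#' @param config a [session_config()] supplying the detector constants.
#' @return tibble of epochs: `init_time`, `peak_time`, `peak_speed`, `context`.
#' @export
detect_movements_oft <- function(speed, threshold = NULL,
                                 config = session_config("oft")) {
  if (is.null(threshold)) {
    threshold <- movement_threshold_oft(speed$speed, config$kmeans_seed)
  }
  peaks <- find_peaks(speed$speed, min_height = threshold,
                      min_prominence = config$oft_min_prominence)
  epochs <- purrr::map(peaks, function(i) {
    pt <- speed$t[i]
    ps <- speed$speed[i]
    init <- find_movement_initiation(speed, pt, ps,
                                     frac = config$init_frac,
                                     window_s = config$init_window_s)
    if (is.na(init)) return(NULL)
    # quiescence: >= 1 s of sub-threshold speed immediately before initiation
    qi <- which(speed$t >= init - config$quiescence_s & speed$t < init)
    if (length(qi) > 0 && any(speed$speed[qi] >= threshold)) return(NULL)
    tibble(init_time = init, peak_time = pt, peak_speed = ps, context = "oft")
  })
  out <- bind_rows(epochs)
  if (nrow(out) == 0) {
    return(tibble(init_time = numeric(0), peak_time = numeric(0),
                  peak_speed = numeric(0), context = character(0)))
  }
  arrange(out, .data$peak_time)
}

#' Detect movement epochs in inter-trial intervals
#'
#' The speed trace is smoothed with a Gaussian-weighted moving average
#' (7 frames at 15 frames/s), then local maxima with absolute height above
#' 10 cm/s and prominence of at least 3 cm/s are detected within the supplied
#' ITI windows. A movement is excluded if it occurs within 5 s after another
#' (kept) movement, applied greedily in time order. Initiation uses the
#' 10%-of-peak rule on the smoothed trace.
#'
#' @param speed tibble with `t`, `speed`.
#' @param windows tibble with `start`, `end` (s); typically
#'   [iti_windows()] output. Must not overlap.
#' @param config a [session_config()].
#' @param context label stored on the epochs.
#' @return tibble of epochs as in [detect_movements_oft()].
#' @export
detect_movements_iti <- function(speed, windows, config = session_config(),
                                 context = "iti") {
  if (nrow(windows) > 1) {
    w <- arrange(windows, .data$start)
    if (any(w$start[-1] < w$end[-nrow(w)])) {
      abort("ITI windows overlap", class = "pa_validation_error")
    }
  }
  sm <- speed
  sm$speed <- gaussian_smooth(speed$speed, config$smooth_window)
  peaks <- find_peaks(sm$speed, min_height = config$iti_min_height,
                      min_prominence = config$iti_min_prominence)
  if (length(peaks) > 0) {
    pt <- sm$t[peaks]
    in_win <- purrr::map_lgl(pt, function(x) {
      any(x >= windows$start & x <= windows$end)
    })
    peaks <- peaks[in_win]
  }
  kept <- integer(0)
  last_time <- -Inf
  for (i in peaks) {
    if (sm$t[i] - last_time > config$iti_exclusion_s) {
      kept <- c(kept, i)
      last_time <- sm$t[i]
    }
  }
  epochs <- purrr::map(kept, function(i) {
    init <- find_movement_initiation(sm, sm$t[i], sm$speed[i],
                                     frac = config$init_frac,
                                     window_s = config$init_window_s)
    tibble(init_time = init, peak_time = sm$t[i], peak_speed = sm$speed[i],
           context = context)
  })
  out <- bind_rows(epochs)
  if (nrow(out) == 0) {
    return(tibble(init_time = numeric(0), peak_time = numeric(0),
                  peak_speed = numeric(0), context = character(0)))
  }
  out
}

#' Inter-trial-interval analysis windows
#'
#' One window per consecutive trial pair, from `margin_s` (default 5 s) after
#' the end of a trial to `margin_s` before the next tone onset. The trial end
#' is the later of tone offset and crossing.
#'
#' @param trials a trial table.
#' @param margin_s margin on both sides (s).
#' @return tibble `start`, `end`, `trial_index` (index of the preceding
#'   trial); degenerate windows are dropped.
#' @export
iti_windows <- function(trials, margin_s = 5) {
  tr <- arrange(trials, .data$tone_on)
  if (nrow(tr) < 2) return(tibble(start = numeric(0), end = numeric(0),
                                  trial_index = integer(0)))
  trial_end <- pmax(tr$tone_off,
                    ifelse(is.na(tr$crossing_time), -Inf, tr$crossing_time))
  out <- tibble(
    start = trial_end[-nrow(tr)] + margin_s,
    end = tr$tone_on[-1] - margin_s,
    trial_index = tr$trial_id[-nrow(tr)]
  )
  filter(out, .data$end > .data$start)
}

#' Detect freezing from a grayscale frame stack
#'
#' The animal silhouette is segmented by thresholding pixel values below
#' `pixel_threshold` (27/255). The number of silhouette pixels that change
#' between consecutive frames is the raw movement signal; it is filtered with
#' a zero-phase bandpass (`freeze_bandpass_hz`, corners in Hz, with the
#' signal mean restored after filtering so the absolute pixel threshold keeps
#' its meaning), and frames where fewer than `changed_pixel_threshold` (190)
#' silhouette pixels changed are marked freezing. The first frame inherits the
#' second frame's label.
#'
#' @param frames numeric array `height x width x n_frames`, values in `[0, 1]`
#'   (or `[0, 255]`, detected and rescaled).
#' @param config a [session_config()].
#' @param rate frame rate (frames/s).
#' @return object of class `pa_freezing`: list with `trace` (tibble `t`,
#'   `frame`, `changed_pixels`, `freezing`) and `bouts` (tibble `start`,
#'   `end`), where bouts are maximal runs of freezing frames.
#' @export
detect_freezing <- function(frames, config = session_config(), rate = NULL) {
  if (is.null(dim(frames)) || length(dim(frames)) != 3 || dim(frames)[3] < 1) {
    abort("frames must be a height x width x n_frames array", class = "pa_input_error")
  }
  rate <- rate %||% config$video_rate_hz
  if (max(frames) > 1.5) frames <- frames / 255
  n <- dim(frames)[3]
  mask <- frames < config$pixel_threshold
  changed <- numeric(n)
  if (n >= 2) {
    for (i in 2:n) {
      changed[i] <- sum(mask[, , i] != mask[, , i - 1])
    }
    changed[1] <- changed[2]
  }
  filtered <- changed
  if (n > 12) {
    w <- pmin(0.99, pmax(1e-5, config$freeze_bandpass_hz / (rate / 2)))
    bp <- signal::butter(2, w, "pass")
    m <- mean(changed)
    filtered <- as.numeric(signal::filtfilt(bp, changed - m)) + m
  }
  freezing <- filtered < config$changed_pixel_threshold
  if (n >= 2) freezing[1] <- freezing[2]
  t <- (seq_len(n) - 1) / rate
  bouts <- runs_to_bouts(freezing, rate)
  structure(list(
    trace = tibble(t = t, frame = seq_len(n), changed_pixels = filtered,
                   freezing = freezing),
    bouts = bouts, rate = rate
  ), class = "pa_freezing")
}

runs_to_bouts <- function(flag, rate) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = (starts[keep] - 1) / rate, end = ends[keep] / rate)
}

#' @export
print.pa_freezing <- function(x, ...) {
  cat("<pa_freezing>", nrow(x$trace), "frames |", nrow(x$bouts), "bouts |",
      sprintf("%.1f%% frozen\n", 100 * mean(x$trace$freezing)))
  invisible(x)
}

#' Detect chamber midline crossings from x position
#'
#' A crossing is registered when the position moves from beyond the hysteresis
#' band on one side of the chamber midline to beyond it on the other side;
#' the crossing time is the first sample past the far edge of the band. The
#' 1 cm hysteresis suppresses tracking jitter around the midline.
#'
#' @param speed tibble with `t` and `x` (cm).
#' @param mid chamber midline (cm).
#' @param hysteresis_cm width of the dead band (cm).
#' @return numeric vector of crossing times.
#' @export
detect_crossings <- function(speed, mid = 0, hysteresis_cm = 1) {
  h <- hysteresis_cm / 2
  x <- speed$x - mid
  state <- 0L
  times <- numeric(0)
  for (i in seq_along(x)) {
    s <- if (x[i] > h) 1L else if (x[i] < -h) -1L else 0L
    if (s != 0L) {
      if (state != 0L && s != state) times <- c(times, speed$t[i])
      state <- s
    }
  }
  times
}

#' Score trials from events and tracking
#'
#' Applies the task rules to each tone: a crossing within the response window
#' (5 s) after tone onset is an avoid (approach); in the avoidance task a
#' crossing between the end of the window and the end of the shock period is
#' an escape; otherwise the trial is a fail. Latency is the crossing time
#' minus tone onset. Crossings are taken from the event table when present,
#' otherwise detected from the chamber x-position via [detect_crossings()].
#' In the approach task a crossing followed by a lick is a rewarded approach;
#' a crossing with no lick is an omission.
#'
#' @param events event table (tibble `time`, `event_type`, `trial_id`).
#' @param speed tibble with `t`, `speed`, `x`; only needed when crossing
#'   events are absent.
#' @param config a [session_config()].
#' @return trial table: `trial_id`, `tone_on`, `tone_off`, `crossing_time`,
#'   `outcome`, `latency`, `stim`, `block_id`.
#' @export
score_trials <- function(events, speed = NULL, config = session_config()) {
  tones_on <- filter(events, .data$event_type == "tone_on") %>% arrange(.data$time)
  if (nrow(tones_on) == 0) {
    abort("no tone_on events; cannot score trials", class = "pa_validation_error")
  }
  tones_off <- filter(events, .data$event_type == "tone_off") %>% arrange(.data$time)
  cross_t <- events$time[events$event_type == "crossing"]
  cross_id <- events$trial_id[events$event_type == "crossing"]
  if (length(cross_t) == 0) {
    if (is.null(speed) || !"x" %in% names(speed)) {
      abort("no crossing events and no position trace to derive them from",
            class = "pa_validation_error")
    }
    cross_t <- detect_crossings(speed, config$chamber_mid_cm, config$hysteresis_cm)
    cross_id <- rep(NA_integer_, length(cross_t))
  }
  laser_on <- events$time[events$event_type == "laser_on"]
  lick_t <- events$time[events$event_type == "lick"]

  rw <- config$response_window_s
  out <- purrr::map(seq_len(nrow(tones_on)), function(k) {
    t_on <- tones_on$time[k]
    trial_id <- tones_on$trial_id[k] %||% NA_integer_
    if (is.na(trial_id)) trial_id <- k
    # crossings attributed to this trial must not precede its tone
    own <- which(!is.na(cross_id) & cross_id == trial_id)
    if (length(own) > 0 && any(cross_t[own] < t_on - 1e-9)) {
      stopf("pa_data_ordering_error",
            "crossing before tone onset in trial %d", trial_id)
    }
    t_off <- tones_off$time[tones_off$trial_id %in% trial_id]
    if (length(t_off) == 0) {
      nxt <- tones_off$time[tones_off$time > t_on]
      t_off <- if (length(nxt) > 0) nxt[1] else t_on + config$tone_max_s
    }
    limit <- t_on + rw + if (config$task == "avoidance") config$shock_dur_s else 0
    cand <- cross_t[cross_t > t_on & cross_t <= limit + 1e-9]
    crossing <- if (length(cand) > 0) min(cand) else NA_real_
    latency <- if (!is.na(crossing)) crossing - t_on else NA_real_
    outcome <- if (config$task == "avoidance") {
      if (is.na(crossing)) "fail"
      else if (latency <= rw + 1e-9) "avoid"
      else "escape"
    } else if (config$task == "approach") {
      if (is.na(crossing) || latency > rw + 1e-9) {
        crossing <- NA_real_; latency <- NA_real_; "fail"
      } else if (any(lick_t > crossing & lick_t <= crossing + 2)) "approach"
      else "omission"
    } else "none"
    stim <- any(laser_on >= t_on & laser_on <= t_on + rw)
    tibble(trial_id = trial_id, tone_on = t_on, tone_off = t_off[1],
           crossing_time = crossing, outcome = outcome, latency = latency,
           stim = stim)
  })
  out <- bind_rows(out)
  out$block_id <- (seq_len(nrow(out)) - 1L) %/% config$stim_block_len + 1L
  out
}

#' Ratio of freezing duration to avoidance latency
#'
#' For each trial with a crossing, counts the fraction of video frames in
#' `[tone_on, crossing)` labelled freezing. Trials with zero or missing
#' latency are skipped with a message.
#'
#' @param trials trial table with `tone_on`, `crossing_time`, `latency`.
#' @param freezing a `pa_freezing` from [detect_freezing()].
#' @return tibble `trial_id`, `latency`, `frozen_frames`, `total_frames`,
#'   `ratio` (in `[0, 1]`).
#' @export
freezing_latency_ratio <- function(trials, freezing) {
  tr <- filter(trials, !is.na(.data$latency))
  skipped <- sum(is.na(trials$latency) | trials$latency <= 0) -
    sum(is.na(trials$latency))
  tr <- filter(tr, .data$latency > 0)
  if (skipped > 0) inform(sprintf("skipped %d trial(s) with zero latency", skipped))
  ft <- freezing$trace
  purrr::map(seq_len(nrow(tr)), function(k) {
    idx <- ft$t >= tr$tone_on[k] & ft$t < tr$crossing_time[k]
    tibble(trial_id = tr$trial_id[k], latency = tr$latency[k],
           frozen_frames = sum(ft$freezing[idx]), total_frames = sum(idx),
           ratio = if (sum(idx) > 0) sum(ft$freezing[idx]) / sum(idx) else NA_real_)
  }) %>% bind_rows()
}
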