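#' Paired dF/F-speed segments for cross-covariance
#'
#' One segment per inter-trial interval: photometry and speed from
#' `margin_s` (5 s) after tone offset to `margin_s` before the next tone
#' onset, plus (optionally) habituation segments cut from the task-free period
#' before the first tone. The dF/F trace must already be on the video time
#' base (see [lowpass_resample()]); both traces are subset to the identical
#' samples. Segments shorter than `min_samples` are dropped with a message.
#'
#' @param dff15 tibble `t`, `dff` at the video rate.
#' @param speed tibble `t`, `speed` on the same time base.
#' @param trials trial table.
#' @param config a [session_config()].
#' @param habituation include segments from the pre-task period?
#' @param hab_segment_s length of each habituation segment (s).
#' @return tibble with `segment_id`, `trial_index` (preceding trial id, NA for
#'   habituation), `phase`, `t_start`, `t_end`, and a `data` list-column of
#'   paired traces.
#' @export
extract_segments <- function(dff15, speed, trials, config = session_config(),
                             habituation = TRUE, hab_segment_s = 30) {
  if (nrow(dff15) != nrow(speed) || max(abs(dff15$t - speed$t)) > 1e-6) {
    abort("dff and speed are not on the same time base", class = "pa_alignment_error")
  }
  margin <- config$xcov_margin_s
  min_n <- config$xcov_min_samples
  segs <- list()
  if (habituation) {
    first_tone <- min(trials$tone_on)
    hab_end <- first_tone - margin
    n_hab <- max(0, floor(hab_end / hab_segment_s))
    for (k in seq_len(n_hab)) {
      segs[[length(segs) + 1]] <- tibble(
        trial_index = NA_integer_, phase = "habituation",
        t_start = (k - 1) * hab_segment_s, t_end = k * hab_segment_s
      )
    }
  }
  wins <- iti_windows(trials, margin_s = margin)
  for (k in seq_len(nrow(wins))) {
    segs[[length(segs) + 1]] <- tibble(
      trial_index = wins$trial_index[k], phase = "iti",
      t_start = wins$start[k], t_end = wins$end[k]
    )
  }
  segs <- bind_rows(segs)
  if (nrow(segs) == 0) {
    return(tibble(segment_id = integer(0), trial_index = integer(0),
                  phase = character(0), t_start = numeric(0),
                  t_end = numeric(0), data = list()))
  }
  dropped <- 0
  out <- purrr::map(seq_len(nrow(segs)), function(k) {
    idx <- which(dff15$t >= segs$t_start[k] & dff15$t <= segs$t_end[k])
    if (length(idx) < min_n) return(NULL)
    tibble(trial_index = segs$trial_index[k], phase = segs$phase[k],
           t_start = segs$t_start[k], t_end = segs$t_end[k],
           data = list(tibble(t = dff15$t[idx], dff = dff15$dff[idx],
                              speed = speed$speed[idx])))
  })
  n_dropped <- sum(purrr::map_lgl(out, is.null))
  if (n_dropped > 0) {
    inform(sprintf("dropped %d segment(s) shorter than %d samples", n_dropped, min_n))
  }
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(segment_id = integer(0), trial_index = integer(0),
                  phase = character(0), t_start = numeric(0),
                  t_end = numeric(0), data = list()))
  }
  out$segment_id <- seq_len(nrow(out))
  select(out, "segment_id", "trial_index", "phase", "t_start", "t_end", "data")
}

#' Cross-covariance of two equal-length traces over a lag range
#'
#' Mean-removed cross-covariance at every integer lag on the sampling grid up
#' to `max_lag_s` (default 2 s): at lag `l`,
#' `value(l) = sum_i (x[i] - mean(x)) * (y[i - l] - mean(y))` over the valid
#' overlap, so a positive extremal lag means `x` lags `y`. The value with the
#' largest absolute magnitude over the lag range is the segment's
#' cross-covariance; on ties the earlier (more negative) lag is kept.
#' Constant inputs give all-zero values and an extremal value of 0.
#'
#' @param x,y numeric vectors of equal length (>= `2 * max_lag + 1` samples).
#' @param max_lag_s lag range (s).
#' @param rate sampling rate (Hz).
#' @param normalize if `TRUE` scale to a cross-correlation (divide by
#'   `sqrt(sum(xd^2) * sum(yd^2))`); default raw covariance sums.
#' @return object of class `pa_xcov`: tibble `lag` (s), `value`, with
#'   attributes `extremal_value`, `extremal_lag`.
#' @export
segment_xcov <- function(x, y, max_lag_s = 2, rate = 15, normalize = FALSE) {
  n <- length(x)
  L <- round(max_lag_s * rate)
  if (length(y) != n) abort("x and y must have equal length", class = "pa_validation_error")
  if (n < 2 * L + 1) abort("segment shorter than 2*max_lag + 1 samples",
                           class = "pa_validation_error")
  xd <- x - mean(x)
  yd <- y - mean(y)
  lags <- (-L):L
  values <- vapply(lags, function(l) {
    if (l >= 0) sum(xd[(1 + l):n] * yd[1:(n - l)])
    else sum(xd[1:(n + l)] * yd[(1 - l):n])
  }, 0)
  if (normalize) {
    den <- sqrt(sum(xd^2) * sum(yd^2))
    values <- if (den > 0) values / den else values * 0
  }
  i_ext <- which.max(abs(values))  # first index wins ties: earlier lag
  out <- tibble(lag = lags / rate, value = values)
  attr(out, "extremal_value") <- values[i_ext]
  attr(out, "extremal_lag") <- lags[i_ext] / rate
  class(out) <- c("pa_xcov", class(out))
  out
}

#' Trial-by-trial evolution of the dF/F-speed cross-covariance
#'
#' Computes the extremal cross-covariance of every inter-trial (and
#' habituation) segment in trial order, annotated with whether the segment
#' follows the first shock and with the running avoidance success rate. This
#' is the session-level summary used to ask whether the coupling between
#' neural signal and locomotion changes when shocks begin.
#'
#' @param dff15 tibble `t`, `dff` on the video time base.
#' @param speed tibble `t`, `speed`.
#' @param trials trial table.
#' @param events event table (for the `first_shock` marker).
#' @param config a [session_config()].
#' @param success_window trials averaged for the running success rate.
#' @param ... passed to [extract_segments()].
#' @return tibble with one row per segment: `segment_id`, `trial_index`,
#'   `phase`, `extremal_value`, `extremal_lag`, `post_first_shock`,
#'   `success_rate`.
#' @export
xcov_evolution <- function(dff15, speed, trials, events,
                           config = session_config(), success_window = 5, ...) {
  segs <- extract_segments(dff15, speed, trials, config, ...)
  if (nrow(segs) == 0) return(tibble())
  first_shock <- suppressWarnings(
    min(events$time[events$event_type %in% c("first_shock", "shock_on")]))
  rate <- config$video_rate_hz
  res <- purrr::map(seq_len(nrow(segs)), function(k) {
    d <- segs$data[[k]]
    xc <- segment_xcov(d$dff, d$speed, config$xcov_max_lag_s, rate)
    tibble(segment_id = segs$segment_id[k], trial_index = segs$trial_index[k],
           phase = segs$phase[k],
           extremal_value = attr(xc, "extremal_value"),
           extremal_lag = attr(xc, "extremal_lag"),
           post_first_shock = is.finite(first_shock) && segs$t_start[k] > first_shock)
  }) %>% bind_rows()
  # running success rate at the preceding trial of each segment
  tr <- arrange(trials, .data$tone_on)
  succ <- as.numeric(tr$outcome %in% c("avoid", "approach", "omission"))
  run_rate <- vapply(seq_along(succ), function(i) {
    mean(succ[max(1, i - success_window + 1):i])
  }, 0)
  res$success_rate <- run_rate[match(res$trial_index, tr$trial_id)]
  res
}
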