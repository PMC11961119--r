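#' Session configuration
#'
#' Builds the configuration object shared by the synthetic generator, the
#' readers and every detector. All task constants default to the values of the
#' behavioral paradigms this package models: a 5 s response window after tone
#' onset, a 2 s foot shock, inter-trial intervals pseudo-randomized around a
#' 40 s mean, 10% special (shortened/extended tone) trials, and optogenetic
#' stimulation delivered 0.5--2.5 s after tone onset in alternating blocks of
#' six trials. Detector constants (pixel thresholds, peak prominences, filter
#' bands) are stored here rather than hard-coded because several are
#' resolution-dependent.
#'
#' @param task one of `"avoidance"`, `"approach"`, `"oft"`.
#' @param n_trials number of cued trials in the session.
#' @param response_window_s response window after tone onset (s).
#' @param shock_dur_s maximum foot-shock duration (s).
#' @param tone_max_s maximum tone duration (s).
#' @param iti_mean_s mean inter-trial interval (s); ITIs are drawn uniformly on
#'   `[0.5, 1.5] * iti_mean_s`.
#' @param special_trial_fraction per-trial probability of a shortened tone and,
#'   independently, of an extended tone (avoidance) or a reward omission
#'   (approach).
#' @param stim_enabled are optogenetic stimulation blocks present?
#' @param stim_block_len trials per stimulation block; blocks alternate
#'   OFF-ON-OFF-... starting with OFF.
#' @param stim_window laser window relative to tone onset (s).
#' @param habituation_s task-free period at the start of the session (s).
#' @param pavlovian_trials number of Pavlovian (tone + unavoidable shock)
#'   conditioning trials preceding the first avoidance trial.
#' @param photometry_rate_hz sampling rate of the photometry traces.
#' @param video_rate_hz tracking/video frame rate (frames/s).
#' @param lowpass_hz half-power frequency of the zero-phase lowpass applied to
#'   dF/F before interpolation onto the video time base.
#' @param response_window_margin unused placeholder for forward compatibility.
#' @param ... detector constants overriding the defaults listed in Details.
#'
#' @details Overridable detector constants (defaults in parentheses):
#' `oft_min_prominence` (5 cm/s), `iti_min_prominence` (3 cm/s),
#' `iti_min_height` (10 cm/s), `smooth_window` (7 frames),
#' `iti_exclusion_s` (5 s), `init_frac` (0.1), `init_window_s` (2 s),
#' `quiescence_s` (1 s), `iti_margin_s` (5 s), `pixel_threshold` (27/255),
#' `changed_pixel_threshold` (190 pixels), `freeze_bandpass_hz` (c(0.01, 0.9) Hz), `hysteresis_cm` (1), `chamber_mid_cm` (0),
#' `xcov_max_lag_s` (2), `xcov_margin_s` (5), `xcov_min_samples` (61),
#' `hist_bin_s` (0.25), `hist_range_s` (c(0, 7)), `n_shuffles` (20),
#' `kmeans_seed` (1).
#'
#' @return an object of class `pa_config` (a validated named list).
#' @examples
#' cfg <- session_config("avoidance", n_trials = 12)
#' cfg$response_window_s
#' @export
session_config <- function(task = c("avoidance", "approach", "oft"),
                           n_trials = 30,
                           response_window_s = 5,
                           shock_dur_s = 2,
                           tone_max_s = 7,
                           iti_mean_s = 40,
                           special_trial_fraction = 0.10,
                           stim_enabled = FALSE,
                           stim_block_len = 6,
                           stim_window = c(0.5, 2.5),
                           habituation_s = 120,
                           pavlovian_trials = 2,
                           photometry_rate_hz = 60,
                           video_rate_hz = 15,
                           lowpass_hz = 7,
                           response_window_margin = NULL,
                           ...) {
  task <- match.arg(task)
  defaults <- list(
    oft_min_prominence = 5,
    iti_min_prominence = 3,
    iti_min_height = 10,
    smooth_window = 7,
    iti_exclusion_s = 5,
    init_frac = 0.1,
    init_window_s = 2,
    quiescence_s = 1,
    iti_margin_s = 5,
    pixel_threshold = 27 / 255,
    changed_pixel_threshold = 190,
    freeze_bandpass_hz = c(0.01, 0.9),
    hysteresis_cm = 1,
    chamber_mid_cm = 0,
    xcov_max_lag_s = 2,
    xcov_margin_s = 5,
    xcov_min_samples = 61,
    hist_bin_s = 0.25,
    hist_range_s = c(0, 7),
    n_shuffles = 20,
    kmeans_seed = 1
  )
  extra <- list(...)
  unknown <- setdiff(names(extra), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")),
          class = "pa_config_error")
  }
  thresholds <- modifyList(defaults, extra)

  if (task == "oft") pavlovian_trials <- 0
  cfg <- c(
    list(
      task = task,
      n_trials = as.integer(n_trials),
      response_window_s = response_window_s,
      shock_dur_s = shock_dur_s,
      tone_max_s = tone_max_s,
      iti_mean_s = iti_mean_s,
      special_trial_fraction = special_trial_fraction,
      stim_enabled = isTRUE(stim_enabled),
      stim_block_len = as.integer(stim_block_len),
      stim_window = stim_window,
      habituation_s = habituation_s,
      pavlovian_trials = as.integer(pavlovian_trials),
      photometry_rate_hz = photometry_rate_hz,
      video_rate_hz = video_rate_hz,
      lowpass_hz = lowpass_hz
    ),
    thresholds
  )
  class(cfg) <- "pa_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  durs <- c(cfg$response_window_s, cfg$shock_dur_s, cfg$tone_max_s,
            cfg$iti_mean_s, cfg$photometry_rate_hz, cfg$video_rate_hz)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    abort("all durations and rates must be > 0", class = "pa_config_error")
  }
  if (cfg$special_trial_fraction < 0 || cfg$special_trial_fraction > 1) {
    abort("special_trial_fraction must lie in [0, 1]", class = "pa_config_error")
  }
  if (cfg$n_trials < 0) {
    abort("n_trials must be >= 0", class = "pa_config_error")
  }
  if (length(cfg$stim_window) != 2 || diff(cfg$stim_window) <= 0) {
    abort("stim_window must be an increasing pair of times", class = "pa_config_error")
  }
  invisible(cfg)
}

#' @export
print.pa_config <- function(x, ...) {
  cat("<pa_config> task:", x$task,
      "| trials:", x$n_trials,
      "| window:", x$response_window_s, "s",
      "| ITI mean:", x$iti_mean_s, "s",
      if (x$stim_enabled) "| stim blocks ON" else "",
      "\n")
  invisible(x)
}
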