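#' Ground-truth parameters for the synthetic session generator
#'
#' Collects every hidden parameter of the generator: true event-kernel
#' amplitudes and shape, photobleaching constants per channel, shared motion
#' artifact level, per-channel noise, behavioral rates, the latency model, and
#' the post-first-shock gain applied to movement-locked kernels. Defaults are
#' chosen to emulate GCaMP6f population recordings during avoidance sessions:
#' transients of a few percent dF/F with ~0.1 s rise and ~0.6 s decay, slow
#' exponential photobleaching over the session, a slow shared motion wobble,
#' and per-sample noise well below transient amplitude.
#'
#' @param amplitudes named numeric vector of kernel peak amplitudes in percent
#'   dF/F, one per model event type (`tone_on`, `tone_off`, `shock`,
#'   `avoid_cross`, `escape_cross`, `iti_cross`, `movement`, `lick`).
#' @param rise,decay kernel rise/decay time constants (s).
#' @param action_onset time before an action event at which its kernel begins
#'   to rise (s, negative).
#' @param bleach_475,bleach_405 named vectors `c(a, b, c)` of the
#'   `a * exp(-b * t) + c` bleaching curve per channel (arbitrary units).
#' @param noise_frac per-sample white-noise SD as a fraction of the channel
#'   asymptote `c`.
#' @param artifact_frac SD of the shared motion artifact as a fraction of the
#'   475 nm asymptote; the identical trace is added to both channels.
#' @param artifact_bw_hz bandwidth of the artifact (lowpass corner, Hz).
#' @param post_shock_gain multiplier applied to movement-locked kernels
#'   (`movement`, `iti_cross`) for events after the first shock.
#' @param latency_shift,latency_meanlog,latency_sdlog shifted log-normal
#'   crossing-latency model: `latency = shift + rlnorm(meanlog, sdlog)`.
#' @param p_no_cross probability a trial has no crossing at all.
#' @param stim_latency_shift added to latency on stimulation trials (s).
#' @param stim_speed_factor multiplier on speed during the laser window of
#'   stimulation trials.
#' @param iti_cross_rate,movement_rate mean counts per inter-trial interval of
#'   spontaneous crossings and movement epochs.
#' @param hab_movement_every mean spacing of habituation movement epochs (s).
#' @param freeze_rate probability an eligible post-shock ITI contains a
#'   freezing bout.
#' @param crossing_peak_speed,movement_peak_meanlog,movement_peak_sdlog speed
#'   bump amplitudes (cm/s); movement peaks are log-normal, clipped to
#'   `[12, 30]`.
#' @param bump_sd_s Gaussian speed-bump width (s).
#' @param speed_noise_sd baseline speed jitter SD (cm/s).
#'
#' @return an object of class `pa_gt_params`.
#' @export
ground_truth_params <- function(
    amplitudes = c(tone_on = 1, tone_off = 3, shock = 4, avoid_cross = 5,
                   escape_cross = 3, iti_cross = 3, movement = 3, lick = 2),
    rise = 0.1, decay = 0.6, action_onset = -0.5,
    bleach_475 = c(a = 30, b = 1 / 600, c = 100),
    bleach_405 = c(a = 20, b = 1 / 500, c = 80),
    noise_frac = 0.005,
    artifact_frac = 0.02,
    artifact_bw_hz = 0.5,
    post_shock_gain = 1,
    latency_shift = 0.3,
    latency_meanlog = 1.144,
    latency_sdlog = 0.6,
    p_no_cross = 0.05,
    stim_latency_shift = 0,
    stim_speed_factor = 1,
    iti_cross_rate = 1,
    movement_rate = 1.5,
    hab_movement_every = 20,
    freeze_rate = 0.15,
    crossing_peak_speed = 18,
    movement_peak_meanlog = log(16),
    movement_peak_sdlog = 0.2,
    bump_sd_s = 0.4,
    speed_noise_sd = 0.4) {
  p <- as.list(environment())
  if (any(p$bleach_475[["b"]] < 0, p$bleach_405[["b"]] < 0)) {
    abort("bleach decay constants must be >= 0", class = "pa_config_error")
  }
  if (p$noise_frac < 0) abort("noise_frac must be >= 0", class = "pa_config_error")
  class(p) <- "pa_gt_params"
  p
}

# event type -> kernel class
MODEL_EVENT_TYPES <- c("tone_on", "tone_off", "shock", "avoid_cross",
                       "escape_cross", "iti_cross", "movement", "lick")
ACTION_TYPES <- c("avoid_cross", "escape_cross", "iti_cross", "movement")
MOVEMENT_LOCKED_TYPES <- c("movement", "iti_cross")

event_class <- function(type) {
  ifelse(type %in% ACTION_TYPES, "action", "sensory")
}

# normalized difference-of-exponentials transient, unit peak
kernel_shape <- function(tau, rise, decay, onset = 0) {
  u <- tau - onset
  v <- ifelse(u > 0, exp(-u / decay) - exp(-u / rise), 0)
  ustar <- rise * decay / (decay - rise) * log(decay / rise)
  vmax <- exp(-ustar / decay) - exp(-ustar / rise)
  v / vmax
}

#' Ground-truth kernel sampled on its model window
#'
#' Evaluates the generator's true event kernel (difference-of-exponentials,
#' unit-peak shape scaled by the configured amplitude) on the encoding-model
#' tap grid, for comparison with fitted kernels in recovery tests.
#'
#' @param type model event type.
#' @param params a [ground_truth_params()].
#' @param dt tap spacing (s).
#' @return tibble `event_type`, `klass`, `tau`, `value`.
#' @export
true_kernel_vector <- function(type, params, dt = 1 / 15) {
  if (!type %in% names(params$amplitudes)) {
    stopf("pa_generation_error", "no ground-truth kernel for event type '%s'", type)
  }
  klass <- event_class(type)
  tau <- if (klass == "action") seq(-1, 2, by = dt) else seq(0, 2, by = dt)
  onset <- if (klass == "action") params$action_onset else 0
  tibble(
    event_type = type, klass = klass, tau = tau,
    value = params$amplitudes[[type]] *
      kernel_shape(tau, params$rise, params$decay, onset)
  )
}

#' Generate the trial and event structure of a synthetic session
#'
#' Draws a complete trial sequence for the configured task: an initial
#' habituation period, optional Pavlovian conditioning trials (tone with
#' unavoidable shock), then cued trials whose crossing latencies follow a
#' shifted log-normal distribution. Trials crossing within the response window
#' are avoids (approaches); in the avoidance task a shock is delivered at the
#' end of the window on the remaining trials and a crossing during the shock is
#' an escape. Inter-trial intervals are pseudo-random, uniform on
#' `[0.5, 1.5]` times the configured mean. With stimulation enabled, trials
#' alternate OFF/ON in blocks of `stim_block_len` and laser on/off events are
#' emitted over the stimulation window. Special trials (shortened tone,
#' extended tone, or reward omission) are drawn independently at
#' `special_trial_fraction`.
#'
#' @param config a [session_config()].
#' @param seed integer seed; the sequence is fully reproducible from it.
#' @param params a [ground_truth_params()] (latency model and rates).
#' @return list with `events` (tibble: `time`, `event_type`, `trial_id`),
#'   `trials` (one row per cued trial), and `session_end` (s).
#' @export
generate_trials <- function(config, seed, params = ground_truth_params()) {
  if (config$n_trials <= 0) {
    abort("n_trials must be positive to generate trials", class = "pa_config_error")
  }
  run_seeded(seed, {
    rw <- config$response_window_s
    tone_max <- config$tone_max_s
    n_pav <- if (config$task == "avoidance") config$pavlovian_trials else 0L
    n_cued <- config$n_trials
    n_all <- n_pav + n_cued
    V <- list(
      trial_id = seq_len(n_all), phase = character(n_all),
      tone_on = numeric(n_all), tone_off = numeric(n_all),
      crossing_time = rep(NA_real_, n_all), outcome = character(n_all),
      latency = rep(NA_real_, n_all), stim = logical(n_all),
      block_id = integer(n_all), special = rep("none", n_all),
      shock_time = rep(NA_real_, n_all)
    )
    t_cursor <- config$habituation_s
    draw_iti <- function() runif(1, 0.5 * config$iti_mean_s, 1.5 * config$iti_mean_s)

    for (i in seq_len(n_pav)) {
      V$phase[i] <- "pavlovian"
      V$tone_on[i] <- t_cursor
      V$tone_off[i] <- t_cursor + tone_max
      V$outcome[i] <- "fail"
      V$shock_time[i] <- t_cursor + rw
      t_cursor <- t_cursor + tone_max + draw_iti()
    }

    for (j in seq_len(n_cued)) {
      i <- n_pav + j
      block_id <- (j - 1L) %/% config$stim_block_len + 1L
      stim <- config$stim_enabled && (block_id %% 2L == 0L)
      u <- runif(1)
      f <- config$special_trial_fraction
      special <- if (u < f) {
        if (config$task == "approach") "omission_candidate" else "short"
      } else if (u < 2 * f && config$task == "avoidance") "extended" else "none"

      no_cross <- runif(1) < params$p_no_cross
      lat <- params$latency_shift + rlnorm(1, params$latency_meanlog, params$latency_sdlog)
      if (stim) lat <- lat + params$stim_latency_shift
      tone_on <- t_cursor
      shock_time <- NA_real_
      if (no_cross || lat > tone_max) {
        outcome <- "fail"
        crossing <- NA_real_
        latency <- NA_real_
        tone_off <- tone_on + if (special == "short") 1.5 else tone_max
        if (config$task == "avoidance" && special != "short") {
          shock_time <- tone_on + rw
        }
      } else if (lat <= rw) {
        outcome <- if (config$task == "approach") "approach" else "avoid"
        crossing <- tone_on + lat
        latency <- lat
        tone_off <- if (special == "short") tone_on + 1.5
                    else if (special == "extended") crossing + 1.5
                    else crossing
      } else {
        # crossing after the window but before tone end
        crossing <- tone_on + lat
        latency <- lat
        if (config$task == "avoidance") {
          outcome <- "escape"
          tone_off <- if (special == "short") tone_on + 1.5 else crossing
          if (special != "short") shock_time <- tone_on + rw
        } else {
          outcome <- "fail"
          crossing <- NA_real_
          latency <- NA_real_
          tone_off <- tone_on + rw
        }
      }
      if (special == "omission_candidate") {
        special <- if (outcome == "approach") "omission" else "none"
        if (special == "omission") outcome <- "omission"
      }
      V$phase[i] <- if (config$task == "avoidance") "avoidance" else config$task
      V$tone_on[i] <- tone_on
      V$tone_off[i] <- tone_off
      V$crossing_time[i] <- crossing
      V$outcome[i] <- outcome
      V$latency[i] <- latency
      V$stim[i] <- stim
      V$block_id[i] <- block_id
      V$special[i] <- special
      V$shock_time[i] <- shock_time
      t_cursor <- max(tone_off, crossing, na.rm = TRUE) + draw_iti()
    }

    trials <- as_tibble(V)
    session_end <- t_cursor + 10
    events <- trials_to_events(trials, config)
    list(events = events, trials = select(trials, -"shock_time"),
         session_end = session_end)
  })
}

# expand a trial table into the typed event stream
trials_to_events <- function(trials, config) {
  ev <- list()
  ev$tone_on <- tibble(event_type = "tone_on", time = trials$tone_on,
                       trial_id = trials$trial_id)
  ev$tone_off <- tibble(event_type = "tone_off", time = trials$tone_off,
                        trial_id = trials$trial_id)
  sh <- filter(trials, !is.na(.data$shock_time))
  if (nrow(sh) > 0) {
    ev$shock <- tibble(event_type = "shock_on", time = sh$shock_time,
                       trial_id = sh$trial_id)
  }
  cr <- filter(trials, !is.na(.data$crossing_time))
  if (nrow(cr) > 0) {
    ev$cross <- tibble(event_type = "crossing", time = cr$crossing_time,
                       trial_id = cr$trial_id)
  }
  if (config$task == "approach") {
    rewarded <- filter(trials, .data$outcome == "approach")
    if (nrow(rewarded) > 0) {
      ev$lick <- tibble(event_type = "lick", time = rewarded$crossing_time + 0.5,
                        trial_id = rewarded$trial_id)
    }
  }
  st <- filter(trials, .data$stim)
  if (nrow(st) > 0) {
    ev$laser_on <- tibble(event_type = "laser_on",
                          time = st$tone_on + config$stim_window[1],
                          trial_id = st$trial_id)
    ev$laser_off <- tibble(event_type = "laser_off",
                           time = st$tone_on + config$stim_window[2],
                           trial_id = st$trial_id)
  }
  if (nrow(sh) > 0) {
    ev$first_shock <- tibble(event_type = "first_shock",
                             time = min(sh$shock_time), trial_id = NA_integer_)
  }
  bind_rows(ev) %>% arrange(.data$time, .data$event_type)
}

# draw the latent behavioral schedule (ITI crossings, movement epochs,
# freezing bouts) and package the full ground truth
draw_ground_truth <- function(te, params, config, seed) {
  run_seeded(seed + 1L, {
    trials <- te$trials
    session_end <- te$session_end
    margin <- 7          # keep latent ITI events clear of trials and windows
    min_sep <- 6         # survive the 5 s movement exclusion rule

    spans <- list()
    # habituation span
    if (config$habituation_s > 2 * margin) {
      spans[[1]] <- c(margin, config$habituation_s - margin)
    }
    ends <- pmax(trials$tone_off, ifelse(is.na(trials$crossing_time), -Inf,
                                         trials$crossing_time))
    starts_next <- c(trials$tone_on[-1], session_end)
    for (k in seq_len(nrow(trials))) {
      lo <- ends[k] + margin
      hi <- starts_next[k] - margin
      if (hi - lo > 2) spans[[length(spans) + 1]] <- c(lo, hi)
    }

    place_in_span <- function(span, n, taken) {
      out <- numeric(0)
      if (n == 0) return(out)
      cand <- sort(runif(2 * n + 4, span[1], span[2]))
      for (tm in cand) {
        if (length(out) >= n) break
        others <- c(out, taken)
        if (length(others) == 0 || all(abs(others - tm) >= min_sep)) {
          out <- c(out, tm)
        }
      }
      out
    }

    movement_times <- numeric(0)
    iti_cross_times <- numeric(0)
    for (sp in spans) {
      is_hab <- sp[2] <= config$habituation_s
      n_mov <- if (is_hab) {
        rpois(1, (sp[2] - sp[1]) / params$hab_movement_every)
      } else rpois(1, params$movement_rate)
      # spontaneous crossings occur during habituation at the same per-second
      # rate as in inter-trial intervals
      n_cross <- if (is_hab) {
        rpois(1, (sp[2] - sp[1]) / config$iti_mean_s * params$iti_cross_rate)
      } else rpois(1, params$iti_cross_rate)
      mv <- place_in_span(sp, n_mov, c(movement_times, iti_cross_times))
      movement_times <- c(movement_times, mv)
      cx <- place_in_span(sp, n_cross, c(movement_times, iti_cross_times))
      iti_cross_times <- c(iti_cross_times, cx)
    }
    movement_times <- sort(movement_times)
    iti_cross_times <- sort(iti_cross_times)

    peak_speed <- pmin(30, pmax(12, rlnorm(length(movement_times),
                                           params$movement_peak_meanlog,
                                           params$movement_peak_sdlog)))
    init_lead <- params$bump_sd_s * sqrt(2 * log(10))  # 10% point of the bump
    movement_epochs <- tibble(
      init_time = movement_times - init_lead,
      peak_time = movement_times,
      peak_speed = peak_speed
    )

    # freezing bouts in post-shock ITIs, kept clear of latent movement
    first_shock <- suppressWarnings(
      min(te$events$time[te$events$event_type == "first_shock"]))
    if (!is.finite(first_shock)) first_shock <- NA_real_
    freezing <- list()
    if (!is.na(first_shock) && params$freeze_rate > 0) {
      for (sp in spans) {
        if (sp[1] < first_shock) next
        if (runif(1) > params$freeze_rate) next
        dur <- runif(1, 3, 10)
        lo <- sp[1]
        hi <- sp[2] - dur
        if (hi <= lo) next
        st <- runif(1, lo, hi)
        busy <- c(movement_times, iti_cross_times)
        if (any(busy > st - 2 & busy < st + dur + 2)) next
        freezing[[length(freezing) + 1]] <- c(st, st + dur)
      }
    }
    freezing_bouts <- if (length(freezing) > 0) {
      tibble(start = vapply(freezing, `[`, 0, 1), end = vapply(freezing, `[`, 0, 2))
    } else tibble(start = numeric(0), end = numeric(0))

    kernels <- purrr::map(setNames(MODEL_EVENT_TYPES, MODEL_EVENT_TYPES),
                          true_kernel_vector, params = params, dt = 1 / config$video_rate_hz)

    structure(list(
      params = params,
      kernels = kernels,
      bleach_475 = params$bleach_475,
      bleach_405 = params$bleach_405,
      noise_frac = params$noise_frac,
      post_shock_gain = params$post_shock_gain,
      first_shock = first_shock,
      movement_epochs = movement_epochs,
      iti_cross_times = iti_cross_times,
      freezing_bouts = freezing_bouts,
      session_end = session_end
    ), class = "pa_ground_truth")
  })
}

# model events (time, type, gain) used to drive the photometry signal and,
# without movement/gain, the encoding model
generator_model_events <- function(events, trials, gt, config) {
  me <- encoding_events(events, trials)
  if (length(gt$iti_cross_times) > 0) {
    me <- bind_rows(me, tibble(time = gt$iti_cross_times, event_type = "iti_cross"))
  }
  if (nrow(gt$movement_epochs) > 0) {
    me <- bind_rows(me, tibble(time = gt$movement_epochs$peak_time,
                               event_type = "movement"))
  }
  me <- arrange(me, .data$time)
  gain <- rep(1, nrow(me))
  if (!is.na(gt$first_shock) && gt$post_shock_gain != 1) {
    locked <- me$event_type %in% MOVEMENT_LOCKED_TYPES & me$time > gt$first_shock
    gain[locked] <- gt$post_shock_gain
  }
  me$gain <- gain
  me
}

#' Generate a synthetic speed/position trace
#'
#' Builds the 15 frames/s locomotion trace implied by the trial structure and
#' ground truth: Gaussian speed bumps at every chamber crossing and movement
#' epoch, near-zero speed during freezing bouts, baseline jitter elsewhere, and
#' a chamber x-position that flips sign at each crossing. On stimulation trials
#' the laser-window speed is multiplied by the ground-truth
#' `stim_speed_factor`.
#'
#' @param trials,events output of [generate_trials()].
#' @param gt a `pa_ground_truth` (from [simulate_session()] internals).
#' @param config a [session_config()].
#' @param seed integer seed.
#' @return tibble with `t`, `speed` (cm/s), `x` (cm).
#' @export
generate_speed <- function(trials, events, gt, config, seed) {
  run_seeded(seed + 2L, {
    rate <- config$video_rate_hz
    t <- seq(0, gt$session_end, by = 1 / rate)
    n <- length(t)
    speed <- pmax(0, rnorm(n, 0.5, gt$params$speed_noise_sd))

    add_bump <- function(speed, center, peak, sds) {
      lo <- max(1, floor((center - 4 * sds) * rate) + 1)
      hi <- min(n, ceiling((center + 4 * sds) * rate) + 1)
      idx <- lo:hi
      speed[idx] <- speed[idx] + peak * exp(-0.5 * ((t[idx] - center) / sds)^2)
      speed
    }
    crossings <- unique(sort(c(events$time[events$event_type == "crossing"],
                               gt$iti_cross_times)))
    for (ct in crossings) {
      speed <- add_bump(speed, ct, gt$params$crossing_peak_speed * runif(1, 0.85, 1.15),
                        gt$params$bump_sd_s)
    }
    if (nrow(gt$movement_epochs) > 0) {
      for (k in seq_len(nrow(gt$movement_epochs))) {
        speed <- add_bump(speed, gt$movement_epochs$peak_time[k],
                          gt$movement_epochs$peak_speed[k], gt$params$bump_sd_s)
      }
    }
    if (nrow(gt$freezing_bouts) > 0) {
      for (k in seq_len(nrow(gt$freezing_bouts))) {
        idx <- t >= gt$freezing_bouts$start[k] & t <= gt$freezing_bouts$end[k]
        speed[idx] <- pmax(0, rnorm(sum(idx), 0.03, 0.02))
      }
    }
    if (gt$params$stim_speed_factor != 1) {
      st <- filter(trials, .data$stim)
      for (k in seq_len(nrow(st))) {
        idx <- t >= st$tone_on[k] + config$stim_window[1] &
               t <= st$tone_on[k] + config$stim_window[2]
        speed[idx] <- speed[idx] * gt$params$stim_speed_factor
      }
    }

    # chamber position: +/-15 cm, sign flips at each crossing
    all_cross <- sort(crossings)
    side <- (-1)^(findInterval(t, all_cross))  # starts at +1... flip to start left
    x_step <- -15 * side
    x <- gaussian_smooth(x_step, 7) + rnorm(n, 0, 0.2)

    tibble(t = t, speed = speed, x = x)
  })
}

#' Generate two-channel synthetic photometry
#'
#' Produces raw 405/475 nm traces from the generative counterpart of the
#' dF/F and encoding models: the 475 nm channel is the bleaching curve
#' modulated multiplicatively by the kernel-convolved event signal `s(t)` (in
#' percent), plus the shared motion artifact and white noise; the 405 nm
#' reference carries its own bleaching curve, the same artifact, and
#' independent noise.
#'
#' @param model_events tibble with `time`, `event_type`, and optional `gain`
#'   columns (see [simulate_session()]).
#' @param gt a `pa_ground_truth`.
#' @param config a [session_config()].
#' @param seed integer seed.
#' @return list with `photometry` (tibble `t`, `f405`, `f475`), `signal` (s(t)
#'   in percent on the photometry grid) and `artifact`.
#' @export
generate_photometry <- function(model_events, gt, config, seed) {
  run_seeded(seed + 3L, {
    rate <- config$photometry_rate_hz
    dt <- 1 / rate
    t <- seq(0, gt$session_end, by = dt)
    n <- length(t)
    if (!"gain" %in% names(model_events)) model_events$gain <- 1

    present <- unique(model_events$event_type)
    missing_k <- setdiff(present, names(gt$params$amplitudes))
    if (length(missing_k) > 0) {
      stopf("pa_generation_error", "no kernel defined for event type(s): %s",
            paste(missing_k, collapse = ", "))
    }

    s <- numeric(n)
    for (type in present) {
      kv <- true_kernel_vector(type, gt$params, dt = dt)
      offs <- round(kv$tau / dt)
      ev <- model_events[model_events$event_type == type, ]
      idx0 <- snap_to_grid(ev$time, 0, dt, n)
      for (j in seq_len(nrow(ev))) {
        if (is.na(idx0[j])) next
        rows <- idx0[j] + offs
        ok <- rows >= 1 & rows <= n
        s[rows[ok]] <- s[rows[ok]] + ev$gain[j] * kv$value[ok]
      }
    }

    b475 <- gt$bleach_475
    b405 <- gt$bleach_405
    base475 <- b475[["a"]] * exp(-b475[["b"]] * t) + b475[["c"]]
    base405 <- b405[["a"]] * exp(-b405[["b"]] * t) + b405[["c"]]

    artifact <- numeric(n)
    if (gt$params$artifact_frac > 0) {
      w <- rnorm(n)
      bf <- signal::butter(2, min(0.99, gt$params$artifact_bw_hz / (rate / 2)), "low")
      a <- signal::filtfilt(bf, w)
      artifact <- a / stats::sd(a) * gt$params$artifact_frac * b475[["c"]]
    }

    f475 <- base475 * (1 + s / 100) + artifact +
      rnorm(n, 0, gt$noise_frac * b475[["c"]])
    f405 <- base405 + artifact + rnorm(n, 0, gt$noise_frac * b405[["c"]])

    list(photometry = tibble(t = t, f405 = f405, f475 = f475),
         signal = s, artifact = artifact)
  })
}

#' Generate a synthetic behavior video for freezing detection
#'
#' Renders a dark blob (the animal silhouette, below the mouse pixel
#' threshold) on a light background. The blob is static during ground-truth
#' freezing bouts and performs a random walk of at least `jitter_px` pixels
#' per frame otherwise.
#'
#' @param freezing_bouts tibble with `start`, `end` (s).
#' @param duration_s video length (s).
#' @param frame_shape `c(height, width)` in pixels.
#' @param rate frames per second.
#' @param seed integer seed.
#' @param blob_radius silhouette radius (px).
#' @param jitter_px per-frame displacement while moving (px).
#' @return numeric array `height x width x frames` with values in `[0, 1]`.
#' @export
generate_video <- function(freezing_bouts, duration_s = 120,
                           frame_shape = c(80, 80), rate = 15, seed = 1,
                           blob_radius = 10, jitter_px = 6) {
  h <- frame_shape[1]; w <- frame_shape[2]
  margin <- blob_radius + jitter_px + 2
  if (h < 2 * margin || w < 2 * margin) {
    stopf("pa_config_error",
          "frame_shape %dx%d too small for blob radius %d with jitter %d",
          h, w, blob_radius, jitter_px)
  }
  if (nrow(freezing_bouts) > 0 &&
      any(freezing_bouts$start < 0 | freezing_bouts$end > duration_s)) {
    stopf("pa_config_error", "freezing bouts outside the video duration")
  }
  run_seeded(seed + 4L, {
    n <- floor(duration_s * rate)
    frame_t <- (seq_len(n) - 1) / rate
    frozen <- rep(FALSE, n)
    for (k in seq_len(nrow(freezing_bouts))) {
      frozen <- frozen | (frame_t >= freezing_bouts$start[k] &
                          frame_t < freezing_bouts$end[k])
    }
    rowg <- matrix(seq_len(h), h, w)
    colg <- matrix(seq_len(w), h, w, byrow = TRUE)
    frames <- array(0.8, dim = c(h, w, n))
    cy <- h / 2; cx <- w / 2
    for (i in seq_len(n)) {
      if (i > 1 && !frozen[i]) {
        ang <- runif(1, 0, 2 * pi)
        step <- jitter_px + runif(1, 0, 2)
        dy <- step * sin(ang)
        dx <- step * cos(ang)
        # reflect at the walls so the full displacement is always realized
        if (cy + dy < margin || cy + dy > h - margin) dy <- -dy
        if (cx + dx < margin || cx + dx > w - margin) dx <- -dx
        cy <- cy + dy
        cx <- cx + dx
      }
      mask <- (rowg - cy)^2 + (colg - cx)^2 <= blob_radius^2
      f <- frames[, , i]
      f[mask] <- 0.05
      frames[, , i] <- f
    }
    frames
  })
}

#' Simulate a complete synthetic session
#'
#' Chains the generator stages: trial/event structure, latent behavioral
#' schedule (ITI crossings, movement epochs, freezing bouts), speed/position
#' trace, and (optionally) two-channel photometry and a behavior video. The
#' returned session carries its full ground truth so every downstream analysis
#' can be validated against known answers.
#'
#' @param config a [session_config()].
#' @param seed integer seed; every random draw derives from it.
#' @param params a [ground_truth_params()].
#' @param photometry generate the photometry traces?
#' @param video generate a freezing-detection video?
#' @return an object of class `pa_session`: a list with `photometry`, `speed`,
#'   `events`, `trials`, `config`, `ground_truth`, and optionally `video`.
#' @examples
#' s <- simulate_session(session_config(n_trials = 4, habituation_s = 30), seed = 1)
#' s$trials
#' @export
simulate_session <- function(config, seed, params = ground_truth_params(),
                             photometry = TRUE, video = FALSE) {
  te <- generate_trials(config, seed, params)
  gt <- draw_ground_truth(te, params, config, seed)
  # spontaneous inter-trial crossings are observable tracking events
  if (length(gt$iti_cross_times) > 0) {
    te$events <- bind_rows(
      te$events,
      tibble(event_type = "crossing", time = gt$iti_cross_times,
             trial_id = NA_integer_)
    ) %>% arrange(.data$time, .data$event_type)
  }
  speed <- generate_speed(te$trials, te$events, gt, config, seed)
  phot <- NULL
  if (photometry) {
    me <- generator_model_events(te$events, te$trials, gt, config)
    gen <- generate_photometry(me, gt, config, seed)
    phot <- gen$photometry
    gt$signal <- gen$signal
    gt$artifact <- gen$artifact
    gt$model_events <- me
  }
  vid <- NULL
  if (video) {
    vid <- generate_video(gt$freezing_bouts, duration_s = gt$session_end,
                          rate = config$video_rate_hz, seed = seed)
  }
  structure(list(
    photometry = phot, speed = speed, events = te$events, trials = te$trials,
    config = config, ground_truth = gt, video = vid
  ), class = "pa_session")
}

#' Simulate a cohort of animals
#'
#' @param config a [session_config()] shared by all animals.
#' @param n_animals number of animals.
#' @param seed global seed; animal `i` uses `seed + i`.
#' @param params a single [ground_truth_params()] or a list of one per animal
#'   (e.g. different parameters per optogenetic group).
#' @param ... passed to [simulate_session()].
#' @return list of `pa_session`, named `animal_1` ... `animal_n`.
#' @export
simulate_cohort <- function(config, n_animals, seed, params = ground_truth_params(), ...) {
  if (!inherits(params, "pa_gt_params")) {
    stopifnot(length(params) == n_animals)
  } else {
    params <- rep(list(params), n_animals)
  }
  out <- purrr::map(seq_len(n_animals), function(i) {
    simulate_session(config, seed + i, params = params[[i]], ...)
  })
  names(out) <- paste0("animal_", seq_len(n_animals))
  out
}

#' @export
print.pa_session <- function(x, ...) {
  cat("<pa_session>", x$config$task, "task |", nrow(x$trials), "trials |",
      if (!is.null(x$photometry)) paste0(nrow(x$photometry), " photometry samples |") else "",
      nrow(x$speed), "speed frames\n")
  invisible(x)
}
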