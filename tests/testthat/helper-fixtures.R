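# shared fixtures, all generated in code

# small avoidance session config for fast end-to-end tests
quick_config <- function(...) {
  args <- utils::modifyList(
    list(task = "avoidance", n_trials = 8, habituation_s = 60, iti_mean_s = 25),
    list(...)
  )
  do.call(session_config, args)
}

# a speed trace with Gaussian bumps at given times/heights on a flat baseline
bump_trace <- function(duration = 60, rate = 15, bumps = list(),
                       baseline = 0, bump_sd = 0.4) {
  t <- seq(0, duration, by = 1 / rate)
  v <- rep(baseline, length(t))
  for (b in bumps) {
    v <- v + b$peak * exp(-0.5 * ((t - b$time) / bump_sd)^2)
  }
  tibble::tibble(t = t, speed = v)
}

# triangular bump: linear rise and fall, exact hand-computable initiation
triangle_trace <- function(duration = 30, rate = 15, peak_time = 15,
                           peak = 20, half_width = 2, baseline = 0) {
  t <- seq(0, duration, by = 1 / rate)
  v <- pmax(0, peak * (1 - abs(t - peak_time) / half_width)) + baseline
  tibble::tibble(t = t, speed = v)
}

# ground-truth params with everything silenced except what a test drives
quiet_params <- function(...) {
  base <- list(
    amplitudes = c(tone_on = 0, tone_off = 0, shock = 0, avoid_cross = 0,
                   escape_cross = 0, iti_cross = 0, movement = 0, lick = 0),
    noise_frac = 0, artifact_frac = 0,
    bleach_475 = c(a = 0, b = 0, c = 100),
    bleach_405 = c(a = 0, b = 0, c = 80),
    freeze_rate = 0
  )
  do.call(ground_truth_params, utils::modifyList(base, list(...)))
}

# brute-force cross-covariance oracle: explicit shifted dot products
xcov_oracle <- function(x, y, max_lag) {
  n <- length(x)
  xd <- x - mean(x)
  yd <- y - mean(y)
  vapply(-max_lag:max_lag, function(l) {
    s <- 0
    for (i in seq_len(n)) {
      j <- i - l
      if (j >= 1 && j <= n) s <- s + xd[i] * yd[j]
    }
    s
  }, 0)
}

# interval IoU between two bout tables
bout_iou <- function(a, b, t_max, rate = 15) {
  grid <- seq(0, t_max, by = 1 / (2 * rate))
  ina <- rep(FALSE, length(grid))
  inb <- rep(FALSE, length(grid))
  for (k in seq_len(nrow(a))) ina <- ina | (grid >= a$start[k] & grid < a$end[k])
  for (k in seq_len(nrow(b))) inb <- inb | (grid >= b$start[k] & grid < b$end[k])
  if (!any(ina | inb)) return(1)
  sum(ina & inb) / sum(ina | inb)
}
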