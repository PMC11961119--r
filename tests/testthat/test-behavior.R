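test_that("k-means movement threshold separates a three-component speed mixture", {
  set.seed(1)
  speeds <- c(abs(rnorm(300, 0.5, 0.2)), rnorm(200, 8, 1), rnorm(100, 25, 2))
  thr <- movement_threshold_oft(speeds)
  mid <- speeds[301:500]
  expect_gte(thr, min(mid) - 1e-9)
  expect_lte(thr, max(mid) + 1e-9)
  # reproducible given the seed
  expect_equal(thr, movement_threshold_oft(speeds))
  expect_error(movement_threshold_oft(rep(3, 50)), class = "pa_degenerate_error")
})

test_that("open-field detector applies the initiation and quiescence rules exactly", {
  # single triangular bump 0 -> 20 cm/s: init at first sample > 2 cm/s within 2 s
  tr <- triangle_trace(duration = 30, peak_time = 15, peak = 20, half_width = 2)
  eps <- detect_movements_oft(tr, threshold = 5)
  expect_equal(nrow(eps), 1)
  expect_equal(eps$peak_speed, 20, tolerance = 1e-9)
  # hand-derived: speed = 20 * (1 - |t-15|/2) > 2 first at t > 13.2
  idx <- which(tr$t >= 13 & tr$speed > 2)[1]
  expect_equal(eps$init_time, tr$t[idx])

  # a second bump with busy (supra-threshold) pre-initiation window is excluded
  t2 <- tr
  plateau <- t2$t >= 16.5 & t2$t <= 18.6
  t2$speed[plateau] <- pmax(t2$speed[plateau], 7)  # above threshold until close to bump 2
  t2$speed <- t2$speed + pmax(0, 20 * (1 - abs(t2$t - 20) / 1.5))
  eps2 <- detect_movements_oft(t2, threshold = 5)
  expect_equal(nrow(eps2), 1)
  expect_equal(eps2$peak_time, 15, tolerance = 0.1)

  # constant zero speed: nothing to detect
  flat <- tibble::tibble(t = tr$t, speed = rep(0, nrow(tr)))
  expect_equal(nrow(detect_movements_oft(flat, threshold = 5)), 0)
})

test_that("detected epochs are invariant to prepending sub-threshold padding", {
  tr <- triangle_trace(duration = 30, peak_time = 15, peak = 20, half_width = 2)
  eps <- detect_movements_oft(tr, threshold = 5)
  pad <- tibble::tibble(t = seq(-10, -1 / 15, by = 1 / 15), speed = 0.5)
  padded <- dplyr::bind_rows(pad, tr)
  eps_pad <- detect_movements_oft(padded, threshold = 5)
  expect_equal(eps_pad$peak_time, eps$peak_time)
  expect_equal(eps_pad$init_time, eps$init_time)
})

test_that("ITI detector enforces height, exclusion and smoothing rules", {
  cfg <- session_config()
  win <- tibble::tibble(start = 0, end = 60)
  # two qualifying peaks 3 s apart: only the first kept
  tr <- bump_trace(60, bumps = list(list(time = 20, peak = 18),
                                    list(time = 23, peak = 18)))
  eps <- detect_movements_iti(tr, win, cfg)
  expect_equal(nrow(eps), 1)
  expect_equal(eps$peak_time, 20, tolerance = 0.3)

  # 9 cm/s peak rejected by the absolute height rule
  tr9 <- bump_trace(60, bumps = list(list(time = 30, peak = 9)))
  expect_equal(nrow(detect_movements_iti(tr9, win, cfg)), 0)

  # single-frame spike: the 7-frame Gaussian smoother keeps it under 10 cm/s
  spike <- tibble::tibble(t = seq(0, 60, by = 1 / 15), speed = 0)
  spike$speed[450] <- 30
  w <- exp(-0.5 * ((-3:3) / (7 / 5))^2)
  expect_lt(max(stats::convolve(spike$speed, rev(w / sum(w)), type = "open")), 10)
  expect_equal(nrow(detect_movements_iti(spike, win, cfg)), 0)

  expect_error(
    detect_movements_iti(tr, tibble::tibble(start = c(0, 10), end = c(20, 30)), cfg),
    class = "pa_validation_error"
  )
})

test_that("movement initiation matches analytic cases and a brute-force oracle", {
  # step from 0 to peak at t0
  t <- seq(0, 10, by = 1 / 15)
  step <- tibble::tibble(t = t, speed = ifelse(t >= 5, 20, 0))
  t0 <- t[which(t >= 5)[1]]
  expect_equal(find_movement_initiation(step, t0, 20), t0)

  # linear ramp 0 -> 20 over 2 s: init at the 2 cm/s crossing
  ramp <- tibble::tibble(t = t, speed = pmax(0, (t - 5) / 2) * 20)
  init <- find_movement_initiation(ramp, 7, 20)
  expect_equal(init, t[which(ramp$speed > 2)[1]])

  # brute-force scan oracle on random traces
  oracle <- function(sp, pt, ps, frac = 0.1, win = 2) {
    idx <- which(sp$t >= pt - win & sp$t <= pt)
    v <- sp$speed[idx]
    below <- which(v <= frac * ps)
    if (length(below) == 0) return(NA_real_)
    pos <- max(below) + 1
    if (pos > length(idx)) return(NA_real_)
    sp$t[idx[pos]]
  }
  set.seed(99)
  for (i in 1:20) {
    sp <- tibble::tibble(t = t, speed = abs(cumsum(rnorm(length(t)))))
    pt <- sample(t[t > 3 & t < 9], 1)
    ps <- sp$speed[which.min(abs(sp$t - pt))]
    expect_identical(find_movement_initiation(sp, pt, ps), oracle(sp, pt, ps))
  }
})

test_that("freezing detection labels identical and fully-moving stacks correctly", {
  cfg <- session_config()
  # identical frames: freezing everywhere
  v <- array(0.8, dim = c(40, 40, 60))
  v[15:25, 15:25, ] <- 0.05
  fz <- detect_freezing(v, cfg)
  expect_true(all(fz$trace$freezing))
  expect_equal(nrow(fz$bouts), 1)
  expect_equal(fz$bouts$start, 0)

  # blob translated 10 px/frame with area >> 190: freezing nowhere
  v2 <- array(0.8, dim = c(60, 400, 30))
  for (i in 1:30) {
    x0 <- 10 * (i - 1) + 1
    v2[20:45, x0:(x0 + 25), i] <- 0.05   # 26x26 blob, area 676
  }
  fz2 <- detect_freezing(v2, cfg)
  expect_false(any(fz2$trace$freezing))

  expect_error(detect_freezing(array(1, c(4, 4))), class = "pa_input_error")
})

test_that("freezing bouts recovered from synthetic video overlap ground truth", {
  bouts <- tibble::tibble(start = c(10, 40), end = c(20, 55))
  v <- generate_video(bouts, duration_s = 120, seed = 12)
  fz <- detect_freezing(v)
  expect_gte(bout_iou(fz$bouts, bouts, 120), 0.9)
})

test_that("trials are scored by the response-window rules", {
  cfg <- session_config("avoidance", n_trials = 2)
  ev <- tibble::tibble(
    event_type = c("tone_on", "tone_off", "crossing",
                   "tone_on", "tone_off", "shock_on", "crossing"),
    time = c(10, 13.2, 13.2, 60, 67, 65, 66.1),
    trial_id = c(1L, 1L, 1L, 2L, 2L, 2L, 2L)
  )
  tr <- score_trials(ev, config = cfg)
  expect_equal(tr$outcome, c("avoid", "escape"))
  expect_equal(tr$latency, c(3.2, 6.1))

  # crossing before its tone is a data-ordering error
  bad <- ev
  bad$time[3] <- 9.5
  expect_error(score_trials(bad, config = cfg), class = "pa_data_ordering_error")
})

test_that("scoring generated events reproduces the generator's outcomes", {
  for (seed in c(13, 14)) {
    s <- simulate_session(quick_config(n_trials = 10), seed = seed, photometry = FALSE)
    tr <- score_trials(s$events, s$speed, s$config)
    gen <- dplyr::arrange(s$trials, tone_on)
    expect_equal(tr$outcome, gen$outcome)
    expect_equal(tr$latency, gen$latency)
    expect_equal(tr$stim, gen$stim)
  }
  # approach: omission trials carry a crossing but no lick
  cfga <- session_config("approach", n_trials = 40, habituation_s = 30)
  sa <- simulate_session(cfga, seed = 15, photometry = FALSE)
  tra <- score_trials(sa$events, sa$speed, cfga)
  expect_equal(tra$outcome, dplyr::arrange(sa$trials, tone_on)$outcome)
})

test_that("crossings can be recovered from the position trace", {
  s <- simulate_session(quick_config(n_trials = 8), seed = 16, photometry = FALSE)
  true_cross <- sort(s$events$time[s$events$event_type == "crossing"])
  got <- detect_crossings(s$speed)
  # every true crossing has a detected counterpart within 0.5 s
  match_dist <- vapply(true_cross, function(ct) min(abs(got - ct)), 0)
  expect_lt(max(match_dist), 0.5)
})

test_that("freezing-to-latency ratio counts frames in [tone_on, crossing)", {
  trials <- tibble::tibble(trial_id = 1L, tone_on = 2, crossing_time = 3, latency = 1)
  mk_freezing <- function(flags) {
    structure(list(
      trace = tibble::tibble(t = (seq_along(flags) - 1) / 15,
                             frame = seq_along(flags),
                             changed_pixels = 0, freezing = flags),
      bouts = NULL, rate = 15), class = "pa_freezing")
  }
  n <- 76  # 0..5 s at 15 fps
  none <- mk_freezing(rep(FALSE, n))
  expect_equal(freezing_latency_ratio(trials, none)$ratio, 0)
  all_frozen <- mk_freezing(rep(TRUE, n))
  expect_equal(freezing_latency_ratio(trials, all_frozen)$ratio, 1)
  # 15 frames in [2, 3); freeze 6 of them -> ratio 0.4
  flags <- rep(FALSE, n)
  in_win <- which(none$trace$t >= 2 & none$trace$t < 3)
  flags[in_win[1:6]] <- TRUE
  expect_equal(freezing_latency_ratio(trials, mk_freezing(flags))$ratio, 0.4)
  # zero-latency trial skipped
  tz <- tibble::tibble(trial_id = 1L, tone_on = 2, crossing_time = 2, latency = 0)
  expect_equal(nrow(suppressMessages(freezing_latency_ratio(tz, none))), 0)
})
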