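test_that("peri-event alignment has the right geometry and reproduces kernels", {
  t <- seq(0, 100, by = 1 / 15)
  const <- tibble::tibble(t = t, dff = rep(4, length(t)))
  m <- align_to_event(const, c(20, 50, 80), window = c(-4, 4))
  expect_equal(dim(m$mat), c(3, 121))
  expect_true(all(m$mat == 4))

  # events with partial windows are dropped
  m2 <- suppressMessages(align_to_event(const, c(1, 50), window = c(-4, 4)))
  expect_equal(nrow(m2$mat), 1)

  # alignment to crossings recovers the crossing-locked kernel in the average
  cfg <- quick_config(photometry_rate_hz = 15, n_trials = 8)
  s <- simulate_session(cfg, seed = 31)
  enc_dff <- suppressWarnings(compute_dff(s$photometry))$trace
  cross <- s$trials$crossing_time[s$trials$outcome == "avoid"]
  pm <- align_to_event(enc_dff, cross, window = c(-1, 2))
  avg <- colMeans(pm$mat)
  # the tone terminates at the crossing on avoid trials, so the event-locked
  # truth is the avoidance kernel plus the coincident tone-offset kernel
  ka <- s$ground_truth$kernels[["avoid_cross"]]
  kt <- s$ground_truth$kernels[["tone_off"]]
  truth <- ka$value
  truth[ka$tau >= 0] <- truth[ka$tau >= 0] + kt$value
  expect_gt(cor(avg, truth), 0.95)
})

test_that("pre/peri contrast matches analytic means and is shift-equivariant", {
  t <- seq(0, 100, by = 1 / 15)
  # linear ramp dff = t, crossing at t0: pre mean = t0 - 3, peri mean = t0
  ramp <- tibble::tibble(t = t, dff = t)
  t0 <- 50
  pm <- align_to_event(ramp, t0, window = c(-4, 4))
  pp <- pre_peri_contrast(pm)
  expect_equal(pp$pre, t0 - 3, tolerance = 0.05)
  expect_equal(pp$peri, t0, tolerance = 1e-6)

  const <- tibble::tibble(t = t, dff = rep(2, length(t)))
  ppc <- pre_peri_contrast(align_to_event(const, t0, window = c(-4, 4)))
  expect_equal(ppc$pre, ppc$peri)

  # adding a constant moves both means by that constant
  pp2 <- pre_peri_contrast(align_to_event(dplyr::mutate(ramp, dff = dff + 7),
                                          t0, window = c(-4, 4)))
  expect_equal(pp2$pre - pp$pre, 7, tolerance = 1e-9)
  expect_equal(pp2$peri - pp$peri, 7, tolerance = 1e-9)

  expect_error(pre_peri_contrast(align_to_event(ramp, t0, window = c(-2, 2))),
               class = "pa_config_error")
})

test_that("amplitude correlations behave under construction and exclusion", {
  t <- seq(0, 400, by = 1 / 15)
  set.seed(32)
  cross <- seq(20, 380, by = 24)
  lat <- runif(length(cross), 1, 5)
  trials <- tibble::tibble(trial_id = seq_along(cross), tone_on = cross - lat,
                           crossing_time = cross, latency = lat,
                           outcome = "avoid", stim = FALSE)
  # dff amplitude proportional to speed bump height: r > 0.9
  peaks <- runif(length(cross), 10, 30)
  sp <- tibble::tibble(t = t, speed = 0)
  dff <- tibble::tibble(t = t, dff = 0)
  for (i in seq_along(cross)) {
    sp$speed <- sp$speed + peaks[i] * exp(-0.5 * ((t - cross[i]) / 0.3)^2)
    dff$dff <- dff$dff + 0.3 * peaks[i] * exp(-0.5 * ((t - cross[i]) / 0.3)^2)
  }
  st <- trial_amplitude_stats(dff, trials, sp)
  expect_gt(st$correlations$r_speed, 0.9)
  expect_equal(nrow(st$per_trial), length(cross))

  # fewer than 3 successful trials: excluded
  st2 <- suppressMessages(trial_amplitude_stats(dff, trials[1:2, ], sp))
  expect_null(st2$correlations)
})

test_that("stimulation-window speed analysis applies the early-crossing exclusion", {
  cfg <- session_config()
  t <- seq(0, 100, by = 1 / 15)
  sp <- tibble::tibble(t = t, speed = rep(5, length(t)))
  trials <- tibble::tibble(
    trial_id = 1:3, tone_on = c(10, 40, 70),
    crossing_time = c(10.3, 43, NA), latency = c(0.3, 3, NA),
    outcome = c("avoid", "avoid", "fail"), stim = c(TRUE, TRUE, FALSE)
  )
  res <- stim_speed_analysis(trials, sp, cfg)
  # the 0.3 s crossing trial is excluded: one stim trial remains
  expect_equal(res$n_trials[res$condition == "stim"], 1)
  expect_equal(res$n_trials[res$condition == "no_stim"], 1)
})

test_that("the mixed two-way ANOVA detects a group-specific stimulation effect", {
  set.seed(33)
  mk <- function(group, shift) {
    purrr::map(1:6, function(i) {
      base <- rnorm(1, 10, 1)
      tibble::tibble(animal = paste0(group, i), group = group,
                     condition = c("no_stim", "stim"),
                     mean_speed = c(base, base + shift + rnorm(1, 0, 0.3)))
    }) %>% dplyr::bind_rows()
  }
  df <- dplyr::bind_rows(mk("opsin", -3), mk("control", 0))
  res <- stim_speed_anova(df)
  expect_lt(res$p[res$term == "group:condition"], 0.01)

  tiny <- df[df$animal %in% c("opsin1", "control1"), ]
  expect_warning(out <- stim_speed_anova(tiny), "fewer than 2")
  expect_equal(nrow(out), 0)
})

test_that("crossing-probability histogram conserves mass and matches hand counts", {
  trials <- tibble::tibble(trial_id = 1:10, latency = rep(1.0, 10),
                           stim = FALSE, crossing_time = 1, tone_on = 0,
                           outcome = "avoid")
  h <- crossing_probability_hist(trials)
  bin <- h$hist[h$hist$bin_start == 1.00, ]
  expect_equal(bin$probability, 1.0)
  expect_equal(sum(h$hist$probability), 1.0)

  # hand-tabulated 12-trial example with stim/no-stim conditions
  lat <- c(0.6, 1.1, 1.4, 2.0, 2.6, NA, 0.7, 1.2, 2.2, 4.1, NA, NA)
  trials2 <- tibble::tibble(trial_id = 1:12, latency = lat,
                            stim = rep(c(TRUE, FALSE), each = 6),
                            crossing_time = lat, tone_on = 0, outcome = "avoid")
  h2 <- crossing_probability_hist(trials2)
  # stim: 4 of 6 latencies in [0.5, 2.5); no-stim: 3 of 6
  expect_equal(h2$stim_window_ratio, (4 / 6) / (3 / 6))
  expect_equal(sum(h2$hist$probability[h2$hist$condition == "stim"]), 5 / 6)

  # all-fail condition: probabilities zero, ratio undefined
  trials3 <- dplyr::mutate(trials2, latency = NA_real_, crossing_time = NA_real_)
  h3 <- crossing_probability_hist(trials3)
  expect_true(is.na(h3$stim_window_ratio))
})

test_that("block latency series reflects chunking rules and stim effects", {
  cfg <- session_config(stim_enabled = TRUE)
  lat <- rep(2, 72)
  stim <- rep(rep(c(FALSE, TRUE), each = 6), 6)
  lat[stim] <- 3    # stimulation slows every stim trial by 1 s
  trials <- tibble::tibble(trial_id = 1:72, tone_on = seq(0, by = 40, length.out = 72),
                           latency = lat, stim = stim,
                           crossing_time = seq(0, by = 40, length.out = 72) + lat,
                           outcome = "avoid",
                           block_id = rep(1:12, each = 6))
  b1 <- block_latency_series(trials, "pre6_on6", cfg)
  expect_equal(nrow(b1), 12)
  expect_equal(b1$n_chunks[1], 6)
  expect_equal(b1$mean_latency, rep(c(2, 3), each = 6))

  b2 <- block_latency_series(trials, "on6_post6", cfg)
  expect_equal(b2$n_chunks[1], 5)
  expect_equal(b2$mean_latency, rep(c(3, 2), each = 6))

  b3 <- block_latency_series(trials, "pre3_on6_post3", cfg)
  expect_equal(b3$n_chunks[1], 5)
  expect_equal(b3$mean_latency, c(2, 2, 2, rep(3, 6), 2, 2, 2))
  expect_equal(b3$phase, c(rep("pre", 3), rep("stim", 6), rep("post", 3)))

  # constant latencies give a flat series
  flat <- dplyr::mutate(trials, latency = 2.5)
  bf <- block_latency_series(flat, "pre6_on6", cfg)
  expect_true(all(bf$mean_latency == 2.5))
})

test_that("t-test wrappers agree with closed-form values", {
  # identical vectors: t = 0, p = 1
  x <- c(1.2, 3.4, 2.2, 5.1)
  tt <- pa_t_test(x, x, type = "paired")
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)

  # textbook paired case against the closed form
  a <- c(12.1, 14.2, 13.3, 15.4, 11.8, 14.9)
  b <- c(11.0, 13.1, 13.0, 14.2, 11.1, 13.4)
  d <- a - b
  t_cf <- mean(d) / (sd(d) / sqrt(length(d)))
  p_cf <- 2 * pt(-abs(t_cf), length(d) - 1)
  got <- pa_t_test(a, b, type = "paired")
  expect_equal(got$statistic, t_cf, tolerance = 1e-10)
  expect_equal(got$p_value, p_cf, tolerance = 1e-10)

  # pooled two-sample closed form
  g1 <- c(5.1, 4.8, 6.2, 5.5, 5.9)
  g2 <- c(4.2, 4.5, 3.9, 4.8, 4.1, 4.4)
  sp2 <- ((length(g1) - 1) * var(g1) + (length(g2) - 1) * var(g2)) /
    (length(g1) + length(g2) - 2)
  t2 <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / length(g1) + 1 / length(g2)))
  got2 <- pa_t_test(g1, g2, type = "unpaired")
  expect_equal(got2$statistic, t2, tolerance = 1e-10)

  # one-sample
  t1 <- (mean(x) - 2) / (sd(x) / sqrt(length(x)))
  got1 <- pa_t_test(x, type = "one_sample", mu = 2)
  expect_equal(got1$statistic, t1, tolerance = 1e-10)
})

test_that("repeated-measures ANOVA matches its closed-form F on a textbook layout", {
  df <- tidyr::expand_grid(subject = paste0("s", 1:6), condition = c("a", "b", "c"))
  set.seed(34)
  eff <- c(a = 0, b = 1, c = 2)
  df$value <- rnorm(nrow(df), 10 + eff[df$condition], 1)
  res <- pa_rm_anova(df)

  # closed-form within-subject one-way ANOVA
  m <- matrix(df$value[order(df$subject, df$condition)], ncol = 3, byrow = TRUE)
  gm <- mean(m)
  ss_cond <- nrow(m) * sum((colMeans(m) - gm)^2)
  ss_subj <- ncol(m) * sum((rowMeans(m) - gm)^2)
  ss_tot <- sum((m - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- ncol(m) - 1
  df2 <- (nrow(m) - 1) * (ncol(m) - 1)
  f_cf <- (ss_cond / df1) / (ss_err / df2)
  expect_equal(res$anova$F, f_cf, tolerance = 1e-10)
  expect_equal(res$anova$p_value, pf(f_cf, df1, df2, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_true(is.null(res$posthoc) || nrow(res$posthoc) == 3)
})
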