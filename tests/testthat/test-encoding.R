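t15 <- seq(0, 120, by = 1 / 15)

test_that("design matrix structure follows the kernel windows", {
  # no events: intercept column only
  d0 <- build_design_matrix(tibble::tibble(time = numeric(0), event_type = character(0)),
                            kernel_specs("iti_cross"), t15)
  expect_equal(sum(d0$X[, seq_len(ncol(d0$X) - 1)]), 0)
  expect_equal(d0$X[, ncol(d0$X)], rep(1, length(t15)))

  # one action event: 46 lag columns each containing exactly one 1
  d1 <- build_design_matrix(tibble::tibble(time = 60, event_type = "iti_cross"),
                            kernel_specs("iti_cross"), t15)
  expect_equal(nrow(d1$map), 46)
  expect_equal(colSums(d1$X[, d1$map$column]), rep(1, 46), ignore_attr = TRUE)
  expect_equal(range(d1$map$tau), c(-1, 2))

  # sensory window: 31 taps over 0..2 s
  d2 <- build_design_matrix(tibble::tibble(time = 60, event_type = "tone_off"),
                            kernel_specs("tone_off"), t15)
  expect_equal(nrow(d2$map), 31)
  expect_equal(range(d2$map$tau), c(0, 2))

  expect_error(
    build_design_matrix(tibble::tibble(time = 1, event_type = "mystery"),
                        kernel_specs("tone_on"), t15),
    class = "pa_config_error"
  )
})

test_that("noiseless OLS recovers kernels exactly and overlapping events match the pseudoinverse", {
  set.seed(5)
  p <- ground_truth_params()
  specs <- kernel_specs(c("iti_cross", "tone_off"))
  ev <- tibble::tibble(time = sort(runif(12, 5, 115)),
                       event_type = rep(c("iti_cross", "tone_off"), 6))
  des <- build_design_matrix(ev, specs, t15)
  truth <- c(true_kernel_vector("iti_cross", p)$value,
             true_kernel_vector("tone_off", p)$value)
  y <- as.numeric(des$X %*% c(truth, 0))
  fit <- fit_kernels(des, y)
  expect_lt(max(abs(fit$kernels$coefficient - truth)), 1e-6)
  expect_gte(fit$r2, 1 - 1e-9)

  # overlapping events, noisy signal: matches the SVD pseudoinverse oracle
  y2 <- y + rnorm(length(y), 0, 0.5)
  fit2 <- fit_kernels(des, y2)
  sv <- svd(des$X)
  beta_or <- sv$v %*% (crossprod(sv$u, y2) / sv$d)
  expect_lt(max(abs(c(fit2$kernels$coefficient, fit2$intercept) - beta_or)), 1e-8)

  # residual orthogonality to every design column
  dots <- abs(crossprod(des$X, fit2$residuals))
  norms <- sqrt(colSums(des$X^2)) * sqrt(sum(fit2$residuals^2))
  expect_true(all(dots <= 1e-6 * pmax(norms, 1)))
})

test_that("R2 on pure noise approaches the parameter fraction and is order-invariant", {
  set.seed(6)
  specs <- kernel_specs(c("iti_cross", "tone_off"))
  ev <- tibble::tibble(time = sort(runif(20, 5, 115)),
                       event_type = sample(rep(c("iti_cross", "tone_off"), 10)))
  des <- build_design_matrix(ev, specs, t15)
  n <- length(t15); p <- ncol(des$X)
  r2s <- replicate(30, fit_kernels(des, rnorm(n))$r2)
  # overfit expectation ~ (p-1)/(n-1); allow a Monte-Carlo band
  expect_equal(mean(r2s), (p - 1) / (n - 1), tolerance = 0.35)

  # column (event-type) order does not change R2
  des_rev <- build_design_matrix(ev, specs[nrow(specs):1, ], t15)
  y <- rnorm(n)
  expect_equal(fit_kernels(des, y)$r2, fit_kernels(des_rev, y)$r2, tolerance = 1e-12)
})

test_that("coincident events of two types fall back to the minimum-norm solution", {
  ev <- tibble::tibble(time = c(60, 60), event_type = c("avoid_cross", "escape_cross"))
  des <- build_design_matrix(ev, kernel_specs(c("avoid_cross", "escape_cross")), t15)
  # the two action blocks are identical column-for-column: rank deficient
  y <- rnorm(length(t15))
  expect_warning(fit <- fit_kernels(des, y), "minimum-norm")
  expect_true(all(is.finite(fit$kernels$coefficient)))
})

test_that("shuffling preserves counts, leaves other types untouched, and is uniform", {
  set.seed(7)
  ev <- tibble::tibble(time = sort(runif(30, 0, 100)),
                       event_type = rep(c("iti_cross", "tone_on", "tone_off"), 10))
  sh <- shuffle_events(ev, "iti_cross", c(0, 100), seed = 1)
  expect_equal(sum(sh$event_type == "iti_cross"), 10)
  expect_identical(sh$time[sh$event_type != "iti_cross"],
                   ev$time[ev$event_type != "iti_cross"])
  # deterministic given the seed
  expect_identical(sh, shuffle_events(ev, "iti_cross", c(0, 100), seed = 1))
  # uniformity over many draws
  draws <- unlist(purrr::map(1:100, function(i) {
    shuffle_events(ev, "iti_cross", c(0, 100), seed = i)$time[
      sh$event_type == "iti_cross"]
  }))
  expect_gt(stats::ks.test(draws, "punif", 0, 100)$p.value, 0.01)
})

test_that("delta R2 separates informative from uninformative events", {
  set.seed(8)
  t600 <- seq(0, 600, by = 1 / 15)
  p <- ground_truth_params()
  specs <- kernel_specs(c("iti_cross", "tone_off"))
  ev <- tibble::tibble(time = sort(runif(40, 5, 595)),
                       event_type = rep(c("iti_cross", "tone_off"), 20))
  des <- build_design_matrix(ev, specs, t600)
  truth_a <- true_kernel_vector("iti_cross", p)$value
  y <- as.numeric(des$X[, 1:46] %*% truth_a) + rnorm(length(t600), 0, 1)

  da <- delta_r2(y, ev, specs, t600, "iti_cross", n_shuffles = 20, seed = 1)
  db <- delta_r2(y, ev, specs, t600, "tone_off", n_shuffles = 20, seed = 1)
  expect_gt(da$delta_r2, 0.05)
  expect_lt(abs(db$delta_r2), 0.01)
  expect_equal(length(da$r2_reduced_per_shuffle), 20)

  # single shuffle with fixed seed is deterministic
  d1 <- delta_r2(y, ev, specs, t600, "iti_cross", n_shuffles = 1, seed = 5)
  d2 <- delta_r2(y, ev, specs, t600, "iti_cross", n_shuffles = 1, seed = 5)
  expect_identical(d1$r2_reduced_per_shuffle, d2$r2_reduced_per_shuffle)

  # zero-signal session: delta R2 within Monte-Carlo noise of zero
  y0 <- rnorm(length(t600), 0, 1)
  d0 <- delta_r2(y0, ev, specs, t600, "iti_cross", n_shuffles = 20, seed = 2)
  expect_lt(abs(d0$delta_r2), 0.01)

  expect_error(delta_r2(y, ev, specs, t600, "iti_cross", n_shuffles = 0),
               class = "pa_config_error")
})

test_that("extracted kernels live on their specification grids", {
  set.seed(9)
  specs <- kernel_specs(c("avoid_cross", "tone_on"))
  ev <- tibble::tibble(time = c(30, 60, 90), event_type = c("avoid_cross", "tone_on", "avoid_cross"))
  des <- build_design_matrix(ev, specs, t15)
  fit <- fit_kernels(des, rnorm(length(t15)))
  ka <- extract_kernel(fit, "avoid_cross")
  ks <- extract_kernel(fit, "tone_on")
  expect_equal(range(ka$tau), c(-1, 2))
  expect_equal(nrow(ka), 46)
  expect_equal(range(ks$tau), c(0, 2))
  expect_equal(nrow(ks), 31)
  expect_error(extract_kernel(fit, "shock"), class = "pa_key_error")
})

test_that("end-to-end recovery through preprocessing carries only the baseline-normalization bias", {
  t600 <- seq(0, 600, by = 1 / 15)
  run_case <- function(amp) {
    p <- quiet_params()
    p$amplitudes[["iti_cross"]] <- amp
    ev1 <- tibble::tibble(time = 300, event_type = "iti_cross")
    des1 <- build_design_matrix(ev1, kernel_specs("iti_cross"), t600)
    kv <- true_kernel_vector("iti_cross", p)
    s1 <- as.numeric(des1$X %*% c(kv$value, 0))
    raw <- tibble::tibble(t = t600, f405 = rep(80, length(t600)),
                          f475 = 100 * (1 + s1 / 100))
    d <- suppressWarnings(compute_dff(raw))
    fit1 <- fit_kernels(des1, d$trace$dff)
    list(err = max(abs(fit1$kernels$coefficient - kv$value)),
         bias_bound = 2 * amp * mean(s1) / 100)
  }
  # small transient: recovery to 1e-6
  expect_lt(run_case(0.2)$err, 1e-6)
  # realistic transient: error bounded by the analytic bias ~ k * mean(s) / 100
  big <- run_case(5)
  expect_lt(big$err, big$bias_bound)
})

test_that("averaging recovered kernels across animals converges toward truth", {
  cfg <- quick_config(photometry_rate_hz = 15, n_trials = 6)
  p <- ground_truth_params(artifact_frac = 0.01)
  ks <- purrr::map(1:6, function(i) {
    s <- simulate_session(cfg, seed = 100 + i, params = p)
    # sessions where every trial is avoided have tone offsets coincident with
    # crossings; the minimum-norm fallback then splits the kernel
    enc <- suppressWarnings(encode_session(s))
    extract_kernel(enc$fit, "avoid_cross")$coefficient
  })
  truth <- true_kernel_vector("avoid_cross", p)$value
  err_single <- purrr::map_dbl(ks, ~ sqrt(mean((.x - truth)^2)))
  err_avg <- sqrt(mean((Reduce(`+`, ks) / length(ks) - truth)^2))
  expect_lt(err_avg, mean(err_single))
  expect_gt(cor(Reduce(`+`, ks) / length(ks), truth), 0.95)
})
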