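#' Linear fit of the isosbestic reference to the signal channel
#'
#' Ordinary least squares of the 475 nm signal on the 405 nm reference:
#' finds `(slope, intercept)` minimizing
#' `sum((f475 - (slope * f405 + intercept))^2)`. The fitted reference
#' `slope * f405 + intercept` estimates the calcium-independent component
#' (motion, bleaching) shared with the signal channel.
#'
#' @param f405,f475 numeric vectors of equal length (>= 2 samples).
#' @return list with `slope` and `intercept`.
#' @export
fit_reference <- function(f405, f475) {
  if (length(f405) != length(f475)) {
    abort("channels must have equal length", class = "pa_validation_error")
  }
  if (length(f405) < 2) {
    abort("need at least 2 samples", class = "pa_validation_error")
  }
  vx <- stats::var(f405)
  if (!is.finite(vx) || vx == 0) {
    abort(paste("405 nm reference is constant; the linear fit is degenerate.",
                "Substitute slope = 0, intercept = mean(f475) explicitly if desired."),
          class = "pa_degenerate_fit_error")
  }
  slope <- stats::cov(f405, f475) / vx
  list(slope = slope, intercept = mean(f475) - slope * mean(f405))
}

#' Exponential photobleaching fit
#'
#' Nonlinear least squares of `a * exp(-b * t) + c` to the 475 nm signal with
#' the decay rate constrained to `b >= 0`. The fit is computed by variable
#' projection: for any candidate `b` the conditionally linear pair `(a, c)` has
#' a closed-form solution, so only `b` is searched (golden-section on
#' `[0, 50 / t_range]`). This makes the fit deterministic and exactly
#' scale-equivariant, which in turn makes dF/F exactly invariant to joint
#' rescaling of the channels. If the linear subproblem is degenerate the fit
#' falls back to `(0, 0, mean(f475))` with a warning.
#'
#' @param t time (s), increasing.
#' @param f475 signal channel.
#' @return list with `a`, `b`, `c`, and `rss`.
#' @export
fit_bleach <- function(t, f475) {
  n <- length(t)
  if (n < 4) abort("need at least 4 samples", class = "pa_validation_error")
  t0 <- t - t[1]
  trange <- t0[n]
  if (trange <= 0) abort("time must span a positive range", class = "pa_validation_error")

  fbar <- mean(f475)
  # conditionally linear subproblem in centered form: stable at any b,
  # including the near-flat boundary where exp(-b t) is almost constant
  solve_ac <- function(b) {
    e <- exp(-b * t0)
    ec <- e - mean(e)
    see <- sum(ec * ec)
    if (!is.finite(see) || see <= 0) return(NULL)
    a <- sum(ec * (f475 - fbar)) / see
    c <- fbar - a * mean(e)
    r <- (f475 - fbar) - a * ec
    list(a = a, c = c, rss = sum(r * r), r = r, e = e)
  }
  obj <- function(b) {
    s <- solve_ac(b)
    if (is.null(s)) return(Inf)
    s$rss
  }
  # envelope-theorem gradient of the profiled residual sum of squares in b
  grad <- function(b) {
    s <- solve_ac(b)
    if (is.null(s)) return(NA_real_)
    2 * s$a * sum(s$r * t0 * s$e)
  }
  b_hi <- 50 / trange
  opt <- tryCatch(
    optimize(obj, interval = c(0, b_hi), tol = b_hi * 1e-7),
    error = function(e) NULL
  )
  fallback <- function() {
    warn("photobleaching fit did not converge; falling back to a constant baseline")
    list(a = 0, b = 0, c = mean(f475), rss = sum((f475 - mean(f475))^2))
  }
  if (is.null(opt)) return(fallback())
  b_best <- opt$minimum
  # Polish by bisection on the analytic gradient. The gradient scales by
  # gamma^2 under joint data rescaling, so its sign pattern - and the root -
  # is scale-invariant down to floating-point noise; this pins b far more
  # tightly and reproducibly than the golden-section tolerance alone.
  w <- b_hi * 1e-3
  lo <- max(0, b_best - w)
  hi <- min(b_hi, b_best + w)
  glo <- grad(lo)
  ghi <- grad(hi)
  if (is.finite(glo) && is.finite(ghi) && glo < 0 && ghi > 0) {
    for (iter in 1:100) {
      mid <- (lo + hi) / 2
      gm <- grad(mid)
      if (!is.finite(gm)) break
      if (gm < 0) lo <- mid else hi <- mid
      if (hi - lo < 1e-16 * b_hi) break
    }
    b_best <- (lo + hi) / 2
  }
  best <- solve_ac(b_best)
  if (is.null(best)) return(fallback())
  const_rss <- sum((f475 - mean(f475))^2)
  if (!is.finite(best$rss) || best$rss > const_rss * (1 + 1e-12)) {
    return(list(a = 0, b = 0, c = mean(f475), rss = const_rss))
  }
  list(a = best$a, b = b_best, c = best$c, rss = best$rss)
}


#' Compute dF/F from raw two-channel photometry
#'
#' The reference channel is linearly fitted to the signal channel and
#' subtracted; the difference is divided by an exponential
#' (`a * exp(-b * t) + c`) fitted to the signal channel, and scaled to
#' percent:
#' \deqn{\Delta F/F = 100 \cdot \frac{F_{475} - \widehat{F}_{405}}{a e^{-bt} + c}}
#' Joint rescaling of both channels leaves the result unchanged, and motion
#' artifacts shared between the channels are attenuated by the reference
#' subtraction.
#'
#' If the 405 nm channel is constant the linear fit is degenerate; the
#' documented substitution `slope = 0, intercept = mean(f475)` is applied with
#' a warning.
#'
#' @param raw tibble with columns `t`, `f405`, `f475` (see
#'   [simulate_session()] or [read_session()]).
#' @return list with `trace` (tibble `t`, `dff` in percent) and `fit` (the
#'   `pa_reference_fit`: slope/intercept, bleaching parameters, residual
#'   diagnostics).
#' @examples
#' s <- simulate_session(session_config(n_trials = 3, habituation_s = 20), seed = 2)
#' d <- compute_dff(s$photometry)
#' head(d$trace)
#' @export
compute_dff <- function(raw) {
  validate_photometry(raw)
  ref <- tryCatch(
    fit_reference(raw$f405, raw$f475),
    pa_degenerate_fit_error = function(e) {
      warn("405 nm reference constant; substituting slope = 0, intercept = mean(f475)")
      list(slope = 0, intercept = mean(raw$f475))
    }
  )
  fitted405 <- ref$slope * raw$f405 + ref$intercept
  bl <- fit_bleach(raw$t, raw$f475)
  denom <- bl$a * exp(-bl$b * (raw$t - raw$t[1])) + bl$c
  if (any(denom <= 0)) {
    abort("fitted bleaching curve is non-positive; cannot normalize",
          class = "pa_validation_error")
  }
  dff <- 100 * (raw$f475 - fitted405) / denom
  rate <- 1 / median(diff(raw$t))
  fit <- structure(list(
    slope = ref$slope, intercept = ref$intercept,
    a = bl$a, b = bl$b, c = bl$c,
    ref_rss = sum((raw$f475 - fitted405)^2), bleach_rss = bl$rss,
    n = nrow(raw)
  ), class = "pa_reference_fit")
  list(trace = tibble(t = raw$t, dff = dff), fit = fit, rate_hz = rate)
}

#' @export
print.pa_reference_fit <- function(x, ...) {
  cat(sprintf("<pa_reference_fit> 405->475: slope %.4g, intercept %.4g | bleach: a %.4g, b %.4g, c %.4g\n",
              x$slope, x$intercept, x$a, x$b, x$c))
  invisible(x)
}

#' Lowpass filter and resample dF/F onto the video time base
#'
#' Applies a zero-phase (forward-backward) Butterworth lowpass with half-power
#' frequency `lowpass_hz` (default 7 Hz), then linearly interpolates onto the
#' supplied video timestamps (nominally 15 frames/s). Zero-phase application
#' avoids phase lag that would shift event-locked responses.
#'
#' @param dff tibble `t`, `dff` (from [compute_dff()]).
#' @param video_t target timestamps (s); must lie within the dF/F support.
#' @param lowpass_hz half-power frequency (Hz).
#' @param order Butterworth order (per pass).
#' @return tibble `t`, `dff` sampled exactly at `video_t`.
#' @export
lowpass_resample <- function(dff, video_t, lowpass_hz = 7, order = 2) {
  if (min(video_t) < min(dff$t) - 1e-9 || max(video_t) > max(dff$t) + 1e-9) {
    abort("video_t extends outside the dF/F time support", class = "pa_range_error")
  }
  rate <- 1 / median(diff(dff$t))
  w <- lowpass_hz / (rate / 2)
  y <- dff$dff
  if (w < 1) {
    bf <- signal::butter(order, w, "low")
    y <- signal::filtfilt(bf, y)
  }
  out <- approx(dff$t, y, xout = video_t)$y
  tibble(t = video_t, dff = out)
}
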