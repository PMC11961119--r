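# shared internal helpers

# Snap event times onto an evenly spaced grid; ties at half-sample go to the
# earlier sample. Returns 1-based indices, NA for times outside the grid.
snap_to_grid <- function(times, t0, dt, n) {
  pos <- (times - t0) / dt
  idx <- ceiling(pos - 0.5) + 1L
  idx[idx < 1L | idx > n] <- NA_integer_
  as.integer(idx)
}

# Gaussian-weighted moving average over `window` samples with standard
# deviation window/5 (renormalized at the edges). The width is chosen so a
# single-frame tracking spike of ~30 cm/s is suppressed below the 10 cm/s
# absolute movement threshold.
gaussian_smooth <- function(x, window) {
  if (window <= 1) return(x)
  half <- (window - 1) / 2
  k <- seq(-floor(half), floor(half))
  w <- exp(-0.5 * (k / (window / 5))^2)
  n <- length(x)
  num <- stats::filter(x, w / sum(w), sides = 2)
  # renormalize near the edges where the window is truncated
  den <- stats::filter(rep(1, n), w / sum(w), sides = 2)
  out <- as.numeric(num / den)
  bad <- is.na(out)
  if (any(bad)) {
    # manual edge handling
    for (i in which(bad)) {
      j <- pmax(1, pmin(n, i + k))
      keep <- (i + k) >= 1 & (i + k) <= n
      out[i] <- sum(x[(i + k)[keep]] * w[keep]) / sum(w[keep])
    }
  }
  out
}

# Local maxima with topographic prominence. A sample is a peak when it exceeds
# its left neighbor and is at least as large as its right neighbor (plateaus
# credit their first sample). Prominence is peak height minus the higher of
# the two lowest valleys separating it from higher terrain.
find_peaks <- function(x, min_height = -Inf, min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  is_peak <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(is_peak) == 0) return(integer(0))
  keep <- logical(length(is_peak))
  for (j in seq_along(is_peak)) {
    i <- is_peak[j]
    h <- x[i]
    if (h < min_height) next
    # walk left until strictly higher ground (or the edge)
    li <- i
    lmin <- h
    while (li > 1 && x[li - 1] <= h) {
      li <- li - 1
      if (x[li] < lmin) lmin <- x[li]
    }
    if (li == 1) lmin <- min(x[1:i])
    ri <- i
    rmin <- h
    while (ri < n && x[ri + 1] <= h) {
      ri <- ri + 1
      if (x[ri] < rmin) rmin <- x[ri]
    }
    if (ri == n) rmin <- min(x[i:n])
    prom <- h - max(lmin, rmin)
    keep[j] <- prom >= min_prominence
  }
  is_peak[keep]
}

run_seeded <- function(seed, expr) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, expr)
}

stopf <- function(class, fmt, ...) {
  abort(sprintf(fmt, ...), class = class)
}
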