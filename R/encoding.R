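#' Kernel specifications for the event-encoding model
#'
#' One specification per model event type. Action events (avoidance crossing,
#' escape crossing, inter-trial crossing, movement) use kernels spanning 1 s
#' before to 2 s after the event, covering the action from initiation to
#' termination; sensory events (tone onset/offset, shock onset, lick) start at
#' the event and last 2 s. On the default 15 Hz model grid these windows hold
#' 46 and 31 taps respectively.
#'
#' @param event_types character vector of model event types; defaults to all
#'   types present in the avoidance model.
#' @param dt kernel time step (s); must divide the window endpoints.
#' @return tibble with `event_type`, `klass`, `win_start`, `win_end`, `dt`.
#' @export
kernel_specs <- function(event_types = MODEL_EVENT_TYPES, dt = 1 / 15) {
  if (dt <= 0) abort("dt must be > 0", class = "pa_config_error")
  klass <- event_class(event_types)
  ws <- ifelse(klass == "action", -1, 0)
  we <- rep(2, length(event_types))
  tibble(event_type = event_types, klass = klass,
         win_start = ws, win_end = we, dt = dt)
}

#' Map session events to model event types
#'
#' Translates the raw event stream into the typed events of the encoding
#' model: tone onsets and offsets, shock onsets, avoidance crossings (within
#' the response window), escape crossings (during the shock), inter-trial
#' crossings (no trial attribution), and licks.
#'
#' @param events event table.
#' @param trials trial table used to classify crossings.
#' @return tibble `time`, `event_type` using the model vocabulary.
#' @export
encoding_events <- function(events, trials) {
  out <- list()
  simple <- c(tone_on = "tone_on", tone_off = "tone_off", shock_on = "shock",
              lick = "lick")
  for (raw in names(simple)) {
    tt <- events$time[events$event_type == raw]
    if (length(tt) > 0) out[[raw]] <- tibble(time = tt, event_type = simple[[raw]])
  }
  cr <- filter(events, .data$event_type == "crossing")
  if (nrow(cr) > 0) {
    type <- purrr::map_chr(seq_len(nrow(cr)), function(k) {
      id <- cr$trial_id[k]
      if (is.na(id)) return("iti_cross")
      row <- trials[trials$trial_id == id, ]
      if (nrow(row) == 0) return("iti_cross")
      switch(row$outcome[1],
             avoid = "avoid_cross", approach = "avoid_cross",
             omission = "avoid_cross", escape = "escape_cross",
             "iti_cross")
    })
    out$cross <- tibble(time = cr$time, event_type = type)
  }
  bind_rows(out) %>% arrange(.data$time)
}

#' Build the encoding-model design matrix
#'
#' One column per (event type, kernel lag) pair plus an intercept. Events are
#' snapped to the nearest sample of the evenly spaced model time base (ties
#' toward the earlier sample); the entry in row `i` of column `(e, tau)` is
#' the number of events of type `e` snapped to time `t[i] - tau`. The design
#' matrix times a stacked kernel vector reproduces the superposition signal
#' sample for sample.
#'
#' @param events tibble `time`, `event_type` in model vocabulary (see
#'   [encoding_events()]).
#' @param specs a [kernel_specs()] covering every type present in `events`.
#' @param t evenly spaced model time base (s).
#' @return list with `X` (matrix, last column the intercept), `map` (tibble
#'   `column`, `event_type`, `tau`), `t`.
#' @export
build_design_matrix <- function(events, specs, t) {
  n <- length(t)
  dt <- median(diff(t))
  if (n > 2 && max(abs(diff(t) - dt)) > 1e-6 * dt) {
    abort("model time base must be evenly spaced", class = "pa_validation_error")
  }
  missing_spec <- setdiff(unique(events$event_type), specs$event_type)
  if (length(missing_spec) > 0) {
    stopf("pa_config_error", "no kernel spec for event type(s): %s",
          paste(missing_spec, collapse = ", "))
  }
  blocks <- list()
  maps <- list()
  for (k in seq_len(nrow(specs))) {
    sp <- specs[k, ]
    offs <- seq(round(sp$win_start / sp$dt), round(sp$win_end / sp$dt))
    taus <- offs * sp$dt
    p <- length(offs)
    M <- matrix(0, n, p)
    ev <- events$time[events$event_type == sp$event_type]
    idx0 <- snap_to_grid(ev, t[1], dt, n)
    idx0 <- idx0[!is.na(idx0)]
    if (length(idx0) > 0) {
      for (j in seq_len(p)) {
        rows <- idx0 + offs[j]
        rows <- rows[rows >= 1 & rows <= n]
        if (length(rows) > 0) {
          M[, j] <- M[, j] + tabulate(rows, nbins = n)
        }
      }
    }
    blocks[[k]] <- M
    maps[[k]] <- tibble(event_type = sp$event_type, tau = taus)
  }
  X <- do.call(cbind, c(blocks, list(matrix(1, n, 1))))
  map <- bind_rows(maps)
  map$column <- seq_len(nrow(map))
  list(X = X, map = select(map, "column", "event_type", "tau"), t = t)
}

#' Fit the event-kernel encoding model by least squares
#'
#' Solves the ordinary least-squares problem for the kernel coefficients
#' (minimizing the mean squared error between the superposition model and the
#' recorded dF/F). The normal equations are solved by Cholesky factorization;
#' if the design is rank-deficient (e.g. duplicated event times) the
#' minimum-norm solution is returned via the SVD pseudoinverse with a warning.
#' `r2` is the coefficient of determination against the mean of the signal.
#'
#' @param design output of [build_design_matrix()].
#' @param dff numeric vector (same length as the model time base) or tibble
#'   with a `dff` column.
#' @return object of class `pa_encoding_fit`: kernels (long tibble), the
#'   intercept, `r2`, residuals and fit dimensions.
#' @export
fit_kernels <- function(design, dff) {
  y <- if (is.data.frame(dff)) dff$dff else as.numeric(dff)
  X <- design$X
  if (length(y) != nrow(X)) {
    abort("signal length does not match the design time base",
          class = "pa_validation_error")
  }
  if (nrow(X) <= ncol(X)) {
    abort("need more samples than parameters", class = "pa_validation_error")
  }
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  beta <- tryCatch({
    R <- chol(XtX)
    backsolve(R, forwardsolve(t(R), Xty))
  }, error = function(e) NULL)
  if (is.null(beta) || any(!is.finite(beta))) {
    warn("rank-deficient design; returning the minimum-norm least-squares solution")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  }
  beta <- as.numeric(beta)
  fitted <- as.numeric(X %*% beta)
  resid <- y - fitted
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  kernels <- design$map
  kernels$coefficient <- beta[kernels$column]
  structure(list(
    kernels = select(kernels, "event_type", "tau", "coefficient"),
    intercept = beta[length(beta)],
    r2 = r2, residuals = resid, fitted = fitted,
    n_samples = nrow(X), n_params = ncol(X)
  ), class = "pa_encoding_fit")
}

#' @export
print.pa_encoding_fit <- function(x, ...) {
  cat(sprintf("<pa_encoding_fit> %d samples, %d params, R2 = %.4f | types: %s\n",
              x$n_samples, x$n_params, x$r2,
              paste(unique(x$kernels$event_type), collapse = ", ")))
  invisible(x)
}

#' Extract one fitted kernel
#'
#' @param fit a `pa_encoding_fit`.
#' @param event_type model event type.
#' @return tibble `tau` (s, the kernel window) and `coefficient`
#'   (percent dF/F per event).
#' @export
extract_kernel <- function(fit, event_type) {
  k <- filter(fit$kernels, .data$event_type == !!event_type)
  if (nrow(k) == 0) {
    stopf("pa_key_error", "no kernel for event type '%s'", event_type)
  }
  select(k, "tau", "coefficient")
}

#' Shuffle the times of one event type
#'
#' Replaces the times of `event_type` with draws uniform over the session
#' while leaving every other event untouched; used to build the reduced model
#' whose kernels cannot reflect a genuine event-locked response.
#'
#' @param events tibble `time`, `event_type`.
#' @param event_type type to shuffle.
#' @param t_range session bounds `c(start, end)` (s).
#' @param seed integer seed.
#' @return events tibble with shuffled times for the one type.
#' @export
shuffle_events <- function(events, event_type, t_range, seed) {
  sel <- events$event_type == event_type
  if (!any(sel)) return(events)
  run_seeded(seed, {
    events$time[sel] <- sort(runif(sum(sel), t_range[1], t_range[2]))
  })
  events
}

#' Unique predictive power of an event type (delta R-squared)
#'
#' Compares the full encoding model to reduced models in which the times of
#' one event type are randomly reassigned: all kernels are refitted on each
#' shuffle and \eqn{\Delta R^2 = R^2_{full} - \overline{R^2}_{reduced}}. A
#' positive value means the true event times carry predictive power that
#' random times cannot mimic.
#'
#' @param dff model-grid signal (vector or tibble with `dff`).
#' @param events model events (see [encoding_events()]).
#' @param specs a [kernel_specs()].
#' @param t model time base.
#' @param event_type type whose unique contribution is measured.
#' @param n_shuffles number of shuffles (default 20).
#' @param seed integer seed; shuffle `i` uses `seed + i`.
#' @return object of class `pa_delta_r2`.
#' @export
delta_r2 <- function(dff, events, specs, t, event_type, n_shuffles = 20, seed = 1) {
  if (n_shuffles < 1) abort("n_shuffles must be >= 1", class = "pa_config_error")
  full <- fit_kernels(build_design_matrix(events, specs, t), dff)
  t_range <- range(t)
  r2_shuffles <- purrr::map_dbl(seq_len(n_shuffles), function(i) {
    ev <- shuffle_events(events, event_type, t_range, seed + i)
    fit_kernels(build_design_matrix(ev, specs, t), dff)$r2
  })
  structure(list(
    event_type = event_type,
    r2_full = full$r2,
    r2_reduced_mean = mean(r2_shuffles),
    r2_reduced_per_shuffle = r2_shuffles,
    delta_r2 = full$r2 - mean(r2_shuffles),
    n_shuffles = n_shuffles, seed = seed
  ), class = "pa_delta_r2")
}

#' @export
print.pa_delta_r2 <- function(x, ...) {
  cat(sprintf("<pa_delta_r2> %s: R2 full %.4f, reduced %.4f (n=%d shuffles), delta %.4f\n",
              x$event_type, x$r2_full, x$r2_reduced_mean, x$n_shuffles, x$delta_r2))
  invisible(x)
}

#' Fit the encoding model to a session
#'
#' Convenience wrapper chaining [compute_dff()], [lowpass_resample()],
#' [encoding_events()] and [fit_kernels()] on a session's own traces.
#'
#' @param session a `pa_session`.
#' @param specs kernel specifications; defaults to the types present.
#' @param delta_r2_types event types for which to also compute [delta_r2()].
#' @param n_shuffles,seed shuffle settings.
#' @return list with `fit`, `dff15`, `events`, `t`, and `delta` (named list of
#'   `pa_delta_r2`, possibly empty).
#' @export
encode_session <- function(session, specs = NULL, delta_r2_types = character(0),
                           n_shuffles = 20, seed = 1) {
  d <- compute_dff(session$photometry)
  t15 <- session$speed$t
  dff15 <- lowpass_resample(d$trace, t15, session$config$lowpass_hz)
  ev <- encoding_events(session$events, session$trials)
  if (is.null(specs)) {
    specs <- kernel_specs(unique(ev$event_type), dt = 1 / session$config$video_rate_hz)
  }
  fit <- fit_kernels(build_design_matrix(ev, specs, t15), dff15$dff)
  delta <- purrr::map(setNames(delta_r2_types, delta_r2_types), function(ty) {
    delta_r2(dff15$dff, ev, specs, t15, ty, n_shuffles = n_shuffles, seed = seed)
  })
  list(fit = fit, dff15 = dff15, events = ev, t = t15, delta = delta)
}
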