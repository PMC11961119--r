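#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an encoding fit into one row per kernel coefficient
#'
#' @param x a `pa_encoding_fit`.
#' @param ... unused.
#' @return tibble `event_type`, `tau`, `coefficient`.
#' @exportS3Method generics::tidy
tidy.pa_encoding_fit <- function(x, ...) {
  x$kernels
}

#' One-row fit summary of an encoding fit
#'
#' @param x a `pa_encoding_fit`.
#' @param ... unused.
#' @return tibble `r2`, `n_samples`, `n_params`, `sigma`.
#' @exportS3Method generics::glance
glance.pa_encoding_fit <- function(x, ...) {
  tibble(r2 = x$r2, n_samples = x$n_samples, n_params = x$n_params,
         sigma = sqrt(sum(x$residuals^2) / (x$n_samples - x$n_params)))
}

#' Tidy a delta-R2 result into one row per shuffle
#'
#' @param x a `pa_delta_r2`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.pa_delta_r2 <- function(x, ...) {
  tibble(event_type = x$event_type, shuffle = seq_len(x$n_shuffles),
         r2_reduced = x$r2_reduced_per_shuffle, r2_full = x$r2_full)
}

#' @rdname tidy.pa_delta_r2
#' @exportS3Method generics::glance
glance.pa_delta_r2 <- function(x, ...) {
  tibble(event_type = x$event_type, r2_full = x$r2_full,
         r2_reduced_mean = x$r2_reduced_mean, delta_r2 = x$delta_r2,
         n_shuffles = x$n_shuffles)
}

#' Tidy a peri-event matrix into long form
#'
#' @param x a `pa_peri_matrix`.
#' @param ... unused.
#' @return tibble `trial`, `time`, `value`.
#' @exportS3Method generics::tidy
tidy.pa_peri_matrix <- function(x, ...) {
  tibble(
    trial = rep(seq_len(nrow(x$mat)), each = ncol(x$mat)),
    time = rep(x$time, nrow(x$mat)),
    value = as.numeric(t(x$mat))
  )
}

#' Plot fitted kernels by event type
#'
#' @param fit a `pa_encoding_fit`.
#' @return a ggplot.
#' @export
plot_kernels <- function(fit) {
  ggplot2::ggplot(fit$kernels,
                  ggplot2::aes(x = .data$tau, y = .data$coefficient)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, linewidth = 0.3) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~event_type, scales = "free_y") +
    ggplot2::labs(x = "time from event (s)", y = expression(Delta * "F/F (%) per event"))
}

#' @exportS3Method ggplot2::autoplot
autoplot.pa_encoding_fit <- function(object, ...) plot_kernels(object)

#' Plot a peri-event average with per-trial traces
#'
#' @param peri a `pa_peri_matrix`.
#' @return a ggplot.
#' @export
plot_peri_event <- function(peri) {
  long <- tidy(peri)
  avg <- long %>% group_by(.data$time) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$trial), alpha = 0.15) +
    ggplot2::geom_line(data = avg, linewidth = 1, color = "firebrick") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "time from event (s)", y = peri$value)
}

#' @exportS3Method ggplot2::autoplot
autoplot.pa_peri_matrix <- function(object, ...) plot_peri_event(object)

#' Plot the cross-covariance evolution over a session
#'
#' @param evo output of [xcov_evolution()].
#' @return a ggplot.
#' @export
plot_xcov_evolution <- function(evo) {
  evo$order <- seq_len(nrow(evo))
  ggplot2::ggplot(evo, ggplot2::aes(x = .data$order, y = .data$extremal_value,
                                    color = .data$post_first_shock)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "segment (session order)", y = "extremal cross-covariance",
                  color = "after first shock")
}

#' Plot the crossing-probability histogram
#'
#' @param hist output of [crossing_probability_hist()].
#' @param stim_window laser window annotated on the plot (s).
#' @return a ggplot.
#' @export
plot_crossing_hist <- function(hist, stim_window = c(0.5, 2.5)) {
  ggplot2::ggplot(hist$hist,
                  ggplot2::aes(x = .data$bin_start, y = .data$probability,
                               fill = .data$condition)) +
    ggplot2::geom_col(position = "identity", alpha = 0.5, just = 0,
                      width = hist$hist$bin_end[1] - hist$hist$bin_start[1]) +
    ggplot2::annotate("rect", xmin = stim_window[1], xmax = stim_window[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.1, fill = "orange") +
    ggplot2::labs(x = "crossing latency (s)", y = "crossing probability")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
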