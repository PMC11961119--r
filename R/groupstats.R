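#' Align a trace to events (peri-event matrix)
#'
#' Cuts a window around each event time and stacks the aligned snippets into
#' a trials-by-time matrix (linear interpolation onto the window grid at the
#' trace's own rate). Events whose window extends outside the trace are
#' dropped with a message.
#'
#' @param trace tibble with `t` and one value column (`dff` or `speed`;
#'   the first non-`t` column is used).
#' @param event_times numeric vector of alignment times (s).
#' @param window `c(start, end)` relative to the event (s).
#' @param rate sampling rate of the window grid (Hz).
#' @return object of class `pa_peri_matrix`: list with `mat`
#'   (trials x time), `time` (window grid), `events` (times kept).
#' @export
align_to_event <- function(trace, event_times, window = c(-4, 4), rate = 15) {
  value_col <- setdiff(names(trace), "t")[1]
  v <- trace[[value_col]]
  grid <- seq(window[1], window[2], by = 1 / rate)
  keep <- event_times + window[1] >= min(trace$t) - 1e-9 &
          event_times + window[2] <= max(trace$t) + 1e-9
  if (any(!keep)) {
    inform(sprintf("dropped %d event(s) with partial windows", sum(!keep)))
  }
  ev <- event_times[keep]
  mat <- matrix(NA_real_, length(ev), length(grid))
  for (i in seq_along(ev)) {
    mat[i, ] <- approx(trace$t, v, xout = ev[i] + grid)$y
  }
  structure(list(mat = mat, time = grid, events = ev, value = value_col),
            class = "pa_peri_matrix")
}

#' @export
print.pa_peri_matrix <- function(x, ...) {
  cat(sprintf("<pa_peri_matrix> %d trials x %d samples (%.2f..%.2f s, %s)\n",
              nrow(x$mat), ncol(x$mat), min(x$time), max(x$time), x$value))
  invisible(x)
}

#' Pre/peri contrast around an aligned event
#'
#' Per-trial mean dF/F in a baseline window 4--2 s before the event
#' (half-open, `[-4, -2)`) and a peri-event window 1 s before to 1 s after
#' (`[-1, 1]`). The animal-level means of these two values feed a paired
#' t-test across animals (see [cohort_pre_peri_test()]).
#'
#' @param peri a `pa_peri_matrix` whose window covers `[-4, 1]` s.
#' @param pre,peri_win the two averaging windows (s).
#' @return tibble `trial`, `pre`, `peri`.
#' @export
pre_peri_contrast <- function(peri, pre = c(-4, -2), peri_win = c(-1, 1)) {
  if (min(peri$time) > pre[1] + 1e-9 || max(peri$time) < peri_win[2] - 1e-9) {
    abort("alignment window too short for the pre/peri contrast",
          class = "pa_config_error")
  }
  pre_idx <- peri$time >= pre[1] & peri$time < pre[2]
  peri_idx <- peri$time >= peri_win[1] & peri$time <= peri_win[2]
  tibble(
    trial = seq_len(nrow(peri$mat)),
    pre = rowMeans(peri$mat[, pre_idx, drop = FALSE]),
    peri = rowMeans(peri$mat[, peri_idx, drop = FALSE])
  )
}

#' Paired pre/peri test across animals
#'
#' @param df tibble with `animal`, `pre`, `peri` (per trial or per animal;
#'   per-animal means are taken first).
#' @return tibble with the animal means and the paired t-test.
#' @export
cohort_pre_peri_test <- function(df) {
  by_animal <- df %>% group_by(.data$animal) %>%
    summarise(pre = mean(.data$pre), peri = mean(.data$peri), .groups = "drop")
  tt <- pa_t_test(by_animal$peri, by_animal$pre, type = "paired")
  list(animal_means = by_animal, test = tt)
}

#' Per-trial amplitude statistics and their correlations
#'
#' For each successful trial: the maximum dF/F from 0.5 s before to 1 s after
#' the crossing, the maximum speed within 0.5 s of the crossing, and the
#' latency. Per animal, Pearson correlations of max dF/F with max speed and
#' with latency are computed; animals with fewer than 3 successful trials are
#' excluded (test across animals is a one-sample t on the correlations, see
#' [cohort_correlation_test()]).
#'
#' @param dff15 tibble `t`, `dff`.
#' @param trials trial table.
#' @param speed tibble `t`, `speed`.
#' @return list with `per_trial` tibble and `correlations` (r_speed,
#'   r_latency, n_trials).
#' @export
trial_amplitude_stats <- function(dff15, trials, speed) {
  ok <- filter(trials, .data$outcome %in% c("avoid", "approach", "omission"),
               !is.na(.data$crossing_time))
  if (nrow(ok) < 3) {
    inform("fewer than 3 successful trials; animal excluded from correlations")
    return(list(per_trial = tibble(), correlations = NULL))
  }
  per_trial <- purrr::map(seq_len(nrow(ok)), function(k) {
    ct <- ok$crossing_time[k]
    di <- dff15$t >= ct - 0.5 & dff15$t <= ct + 1
    si <- speed$t >= ct - 0.5 & speed$t <= ct + 0.5
    tibble(trial_id = ok$trial_id[k], latency = ok$latency[k],
           max_dff = max(dff15$dff[di]), max_speed = max(speed$speed[si]))
  }) %>% bind_rows()
  list(
    per_trial = per_trial,
    correlations = tibble(
      r_speed = cor(per_trial$max_dff, per_trial$max_speed),
      r_latency = cor(per_trial$max_dff, per_trial$latency),
      n_trials = nrow(per_trial)
    )
  )
}

#' One-sample t-test of per-animal correlations against zero
#'
#' @param r numeric vector, one correlation per animal.
#' @return tidy test tibble from [pa_t_test()].
#' @export
cohort_correlation_test <- function(r) {
  pa_t_test(r, type = "one_sample")
}

#' Per-animal stimulation-window speeds
#'
#' Mean speed during the laser window (0.5--2.5 s after tone onset) in
#' stimulation versus non-stimulation trials. Trials where the animal crossed
#' before 0.5 s after tone onset (i.e. before the laser would arrive) are
#' excluded.
#'
#' @param trials trial table with `stim`.
#' @param speed tibble `t`, `speed`.
#' @param config a [session_config()].
#' @return tibble `condition` (`stim`/`no_stim`), `mean_speed`, `n_trials`.
#' @export
stim_speed_analysis <- function(trials, speed, config = session_config()) {
  win <- config$stim_window
  tr <- filter(trials,
               is.na(.data$latency) | .data$latency >= win[1])
  mean_in <- vapply(seq_len(nrow(tr)), function(k) {
    lo <- findInterval(tr$tone_on[k] + win[1] - 1e-9, speed$t) + 1L
    hi <- findInterval(tr$tone_on[k] + win[2] + 1e-9, speed$t)
    mean(speed$speed[lo:hi])
  }, 0)
  per_trial <- tibble(stim = tr$stim, speed = mean_in)
  per_trial %>%
    mutate(condition = if_else(.data$stim, "stim", "no_stim")) %>%
    group_by(.data$condition) %>%
    summarise(mean_speed = mean(.data$speed), n_trials = n(), .groups = "drop")
}

#' Two-way (group x stimulation) ANOVA on laser-window speed
#'
#' Mixed two-factor layout with opsin group between animals and stimulation
#' condition within animal. The interaction term asks whether stimulation
#' changes speed differently in the two groups.
#'
#' @param df tibble with `animal`, `group`, `condition`, `mean_speed` (two
#'   rows per animal).
#' @return tibble of ANOVA terms with `F` and `p` (interaction row
#'   `group:condition`).
#' @export
stim_speed_anova <- function(df) {
  if (min(table(df$group)) / 2 < 2) {
    warn("a group has fewer than 2 animals; interaction test skipped")
    return(tibble(term = character(0), F = numeric(0), p = numeric(0)))
  }
  df$animal <- factor(df$animal)
  df$group <- factor(df$group)
  df$condition <- factor(df$condition)
  fit <- aov(mean_speed ~ group * condition + Error(animal), data = df)
  within <- summary(fit)[["Error: Within"]][[1]]
  between <- summary(fit)[["Error: animal"]][[1]]
  tibble(
    term = c("group", "condition", "group:condition"),
    F = c(aov_row(between, "group", "F value"),
          aov_row(within, "condition", "F value"),
          aov_row(within, "group:condition", "F value")),
    p = c(aov_row(between, "group", "Pr(>F)"),
          aov_row(within, "condition", "Pr(>F)"),
          aov_row(within, "group:condition", "Pr(>F)"))
  )
}

# index an aov summary table by trimmed row name
aov_row <- function(tab, row, col) {
  i <- match(row, trimws(rownames(tab)))
  if (is.na(i)) return(NA_real_)
  tab[i, col]
}

#' Crossing-probability histogram and stimulation-window ratio
#'
#' Bins the crossing latencies of all trials into 0.25 s bins from 0 to 7 s
#' and normalizes by the total trial count (so the bin sum is the fraction of
#' trials with a crossing before 7 s). With stimulation trials present, the
#' ratio of summed crossing probability inside the laser window
#' (0.5--2.5 s) between stimulated and non-stimulated trials is reported; an
#' undefined ratio (zero denominator) is `NA`.
#'
#' @param trials trial table.
#' @param config a [session_config()].
#' @return list with `hist` (tibble `bin_start`, `bin_end`, `condition`,
#'   `probability`) and `stim_window_ratio`.
#' @export
crossing_probability_hist <- function(trials, config = session_config()) {
  edges <- seq(config$hist_range_s[1], config$hist_range_s[2], by = config$hist_bin_s)
  mk <- function(tr, label) {
    n_tot <- nrow(tr)
    lat <- tr$latency[!is.na(tr$latency)]
    counts <- vapply(seq_len(length(edges) - 1), function(i) {
      sum(lat >= edges[i] & lat < edges[i + 1])
    }, 0)
    tibble(bin_start = edges[-length(edges)], bin_end = edges[-1],
           condition = label,
           probability = if (n_tot > 0) counts / n_tot else counts * NA_real_)
  }
  any_stim <- any(trials$stim)
  h <- if (any_stim) {
    bind_rows(mk(filter(trials, .data$stim), "stim"),
              mk(filter(trials, !.data$stim), "no_stim"))
  } else mk(trials, "all")
  ratio <- NA_real_
  if (any_stim) {
    win <- config$stim_window
    in_win <- function(cond) {
      hh <- filter(h, .data$condition == cond,
                   .data$bin_start >= win[1] - 1e-9, .data$bin_end <= win[2] + 1e-9)
      sum(hh$probability)
    }
    num <- in_win("stim")
    den <- in_win("no_stim")
    ratio <- if (is.finite(den) && den > 0) num / den else NA_real_
  }
  list(hist = h, stim_window_ratio = ratio)
}

#' Chunked block-structure latency series
#'
#' Sections the alternating OFF/ON stimulation blocks into chunks and averages
#' latency at each relative trial position across chunks, per animal:
#' `pre6_on6` pairs each OFF block with the following ON block (six chunks for
#' 72 trials in 12 blocks of 6); `on6_post6` pairs each ON block with the
#' following OFF block (five chunks; the first OFF and last ON block are not
#' included); `pre3_on6_post3` takes the last 3 pre-stimulation trials, the 6
#' stimulation trials and the first 3 post-stimulation trials (five chunks).
#'
#' @param trials trial table with `stim` and `block_id` (in trial order).
#' @param chunking one of `"pre6_on6"`, `"on6_post6"`, `"pre3_on6_post3"`.
#' @param config a [session_config()].
#' @return tibble `position` (relative trial position), `phase`
#'   (`pre`/`stim`/`post`), `mean_latency`, `n_chunks`.
#' @export
block_latency_series <- function(trials, chunking = c("pre6_on6", "on6_post6",
                                                      "pre3_on6_post3"),
                                 config = session_config()) {
  chunking <- match.arg(chunking)
  len <- config$stim_block_len
  tr <- arrange(trials, .data$tone_on)
  n_blocks <- nrow(tr) %/% len
  extra <- nrow(tr) - n_blocks * len
  if (extra > 0) {
    inform(sprintf("dropping %d trailing trial(s) not filling a block", extra))
    tr <- tr[seq_len(n_blocks * len), ]
  }
  lat <- matrix(tr$latency, nrow = len)  # columns are blocks
  stim_block <- (seq_len(n_blocks) %% 2L) == 0L  # OFF blocks first
  chunks <- switch(chunking,
    pre6_on6 = {
      off <- which(!stim_block)
      purrr::map(off[off + 1 <= n_blocks], function(b) {
        list(lat = c(lat[, b], lat[, b + 1]),
             phase = rep(c("pre", "stim"), each = len))
      })
    },
    on6_post6 = {
      on <- which(stim_block)
      on <- on[on + 1 <= n_blocks]
      purrr::map(on, function(b) {
        list(lat = c(lat[, b], lat[, b + 1]),
             phase = rep(c("stim", "post"), each = len))
      })
    },
    pre3_on6_post3 = {
      on <- which(stim_block)
      on <- on[on - 1 >= 1 & on + 1 <= n_blocks]
      half <- len %/% 2
      purrr::map(on, function(b) {
        list(lat = c(lat[(len - half + 1):len, b - 1], lat[, b],
                     lat[1:half, b + 1]),
             phase = c(rep("pre", half), rep("stim", len), rep("post", half)))
      })
    })
  if (length(chunks) == 0) {
    abort("trial/block structure inconsistent with the requested chunking",
          class = "pa_validation_error")
  }
  m <- do.call(cbind, purrr::map(chunks, "lat"))
  tibble(
    position = seq_len(nrow(m)),
    phase = chunks[[1]]$phase,
    mean_latency = rowMeans(m, na.rm = TRUE),
    n_chunks = length(chunks)
  )
}

#' t-test wrappers used throughout the group analyses
#'
#' Thin wrappers over [stats::t.test()] returning a tidy one-row tibble.
#' All tests are two-tailed; the unpaired test pools variances (the classical
#' two-sample t).
#'
#' @param x,y numeric vectors (`y` omitted for one-sample).
#' @param type `"paired"`, `"unpaired"`, or `"one_sample"`.
#' @param mu null value for the one-sample test.
#' @return tibble `type`, `estimate`, `statistic`, `df`, `p_value`.
#' @export
pa_t_test <- function(x, y = NULL, type = c("paired", "unpaired", "one_sample"),
                      mu = 0) {
  type <- match.arg(type)
  if (length(x) < 2) abort("need at least 2 observations", class = "pa_validation_error")
  # constant data degenerate cases: a zero difference is a clean null result
  if (type %in% c("paired", "one_sample")) {
    d <- if (type == "paired") x - y else x - mu
    if (sd(d) == 0) {
      m <- mean(d)
      return(tibble(type = type, estimate = m,
                    statistic = if (m == 0) 0 else sign(m) * Inf,
                    df = length(d) - 1,
                    p_value = if (m == 0) 1 else 0))
    }
  }
  ht <- switch(type,
    paired = t.test(x, y, paired = TRUE),
    unpaired = t.test(x, y, var.equal = TRUE),
    one_sample = t.test(x, mu = mu)
  )
  tibble(type = type,
         estimate = unname(if (type == "unpaired") diff(rev(ht$estimate)) else ht$estimate),
         statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' One-way repeated-measures ANOVA with post-hoc comparisons
#'
#' Classical within-subject one-way ANOVA (`aov` with a subject error
#' stratum); pairwise post-hoc comparisons use Tukey-adjusted estimated
#' marginal means when the `emmeans` package is available.
#'
#' @param df tibble with `value`, `subject`, `condition`.
#' @return list with `anova` (tibble `F`, `df1`, `df2`, `p_value`) and
#'   `posthoc` (tibble or `NULL`).
#' @export
pa_rm_anova <- function(df) {
  if (length(unique(df$subject)) < 2) {
    abort("need at least 2 subjects", class = "pa_validation_error")
  }
  df$subject <- factor(df$subject)
  df$condition <- factor(df$condition)
  dat <- as.data.frame(df)
  # build the call with the data embedded so post-hoc tools can re-evaluate it
  fit <- do.call(stats::aov, list(value ~ condition + Error(subject), data = dat))
  sm <- summary(fit)[["Error: Within"]][[1]]
  res <- tibble(F = aov_row(sm, "condition", "F value"),
                df1 = aov_row(sm, "condition", "Df"),
                df2 = aov_row(sm, "Residuals", "Df"),
                p_value = aov_row(sm, "condition", "Pr(>F)"))
  posthoc <- NULL
  if (requireNamespace("emmeans", quietly = TRUE) &&
      length(levels(df$condition)) > 2) {
    em <- emmeans::emmeans(fit, "condition", data = dat)
    pr <- as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = "tukey"))
    posthoc <- as_tibble(pr)
  }
  list(anova = res, posthoc = posthoc)
}
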