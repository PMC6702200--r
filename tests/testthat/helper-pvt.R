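# Shared fixtures and independent oracles for the test suite.

# Construct a pvt_session directly from reaction times, bypassing the
# simulator. Default onsets are evenly spaced so the session passes the
# response-gap check whenever it holds at least 11 responded trials.
make_session <- function(rts, onsets = NULL, button_ok = NULL, timeout = NULL,
                         duration = 10, id = "P001", day = 4, time = 10,
                         scheduled = time, actual = time) {
  n <- length(rts)
  if (is.null(onsets)) {
    onsets <- if (n == 0) numeric(0) else
      seq(2.5, duration * 60 - 30, length.out = n)
  }
  if (is.null(button_ok)) button_ok <- rep(1L, n)
  if (is.null(timeout)) timeout <- rep(0L, n)
  structure(
    list(participant_id = id, day = day, time_since_wake = time,
         scheduled_time = scheduled, actual_time = actual,
         duration = duration,
         trials = data.frame(trial_index = seq_len(n), onset_s = onsets,
                             rt_ms = ifelse(timeout == 1, NA_real_, rts),
                             button_ok = as.integer(button_ok),
                             timeout = as.integer(timeout))),
    class = "pvt_session")
}

make_study <- function(sessions, traits = NULL, config = NULL) {
  structure(list(sessions = sessions, traits = traits, config = config),
            class = "pvt_study")
}

# A session whose kept 500-ms lapse count is exactly `k` (out of 30 trials).
make_lapse_session <- function(k, id, time, day = 4) {
  make_session(c(rep(700, k), rep(300, 30 - k)), id = id, day = day,
               time = time)
}

# Independent re-implementation of the feature catalog, written with
# different idioms (stats::quantile, lm(), explicit loops) than the package.
oracle_features <- function(s, catalog) {
  fs_max <- attr(catalog, "false_start_max")
  tr <- s$trials
  out <- rep(NA_real_, nrow(catalog))
  names(out) <- catalog$name
  resp <- tr[tr$timeout == 0, , drop = FALSE]
  n_timeouts <- nrow(tr) - nrow(resp)
  n_fs <- sum(resp$rt_ms < fs_max)
  keep <- resp[resp$rt_ms >= fs_max & resp$button_ok == 1, , drop = FALSE]
  rts <- keep$rt_ms
  onset <- keep$onset_s
  n <- length(rts)
  qu <- function(p) as.numeric(stats::quantile(rts, p / 100, type = 7,
                                               names = FALSE))
  slope <- function(yv, xv) unname(stats::coef(stats::lm(yv ~ xv))[2])
  for (i in seq_len(nrow(catalog))) {
    fam <- catalog$family[i]
    nm <- catalog$name[i]
    p1 <- catalog$p1[i]
    p2 <- catalog$p2[i]
    out[i] <- switch(fam,
      central_tendency = if (n == 0) NA_real_ else switch(nm,
        mean_rt = sum(rts) / n,
        median_rt = stats::median(rts),
        fastest10_mean_rt =
          mean(sort(rts)[seq_len(max(1, ceiling(0.1 * n)))]),
        slowest10_mean_rt =
          mean(rev(sort(rts))[seq_len(max(1, ceiling(0.1 * n)))])),
      reciprocal_rt = if (n == 0) NA_real_ else switch(nm,
        mean_recip_rt = mean(1000 / rts),
        median_recip_rt = stats::median(1000 / rts),
        sd_recip_rt = if (n < 2) NA_real_ else stats::sd(1000 / rts)),
      percentile = if (n == 0) NA_real_ else qu(p1),
      percentile_difference = if (n < 2) NA_real_ else qu(p2) - qu(p1),
      lapse_count = {
        k <- 0
        for (r in rts) if (r > p1) k <- k + 1
        k + n_timeouts
      },
      variability = if (n < 2) NA_real_ else switch(nm,
        sd_rt = stats::sd(rts),
        iqr_rt = qu(75) - qu(25)),
      consecutive_difference = if (nm == "mean_abs_cdiff") {
        if (n < 2) NA_real_ else mean(abs(rts[-1] - rts[-n]))
      } else {
        k <- 0
        if (n >= 2) for (j in 2:n) if (abs(rts[j] - rts[j - 1]) > p1) k <- k + 1
        k
      },
      error_count = if (nm == "n_false_starts") n_fs else n_timeouts,
      time_on_task = switch(nm,
        tot_slope_rt = if (n < 2 || diff(range(onset / 60)) <= 1) NA_real_
          else slope(rts, onset / 60),
        tot_slope_recip_rt =
          if (n < 2 || diff(range(onset / 60)) <= 1) NA_real_
          else slope(1000 / rts, onset / 60),
        first2_minus_last2_mean_rt = {
          a <- rts[onset < 120]
          b <- rts[onset > (s$duration - 2) * 60]
          if (length(a) == 0 || length(b) == 0) NA_real_ else mean(a) - mean(b)
        },
        tot_slope_lapse = {
          grid <- 0:(ceiling(s$duration) - 1)
          counts <- vapply(grid, function(m)
            sum(rts[floor(onset / 60) == m] > p1), 0)
          slope(counts, grid + 0.5)
        }))
  }
  out
}

# Small protocol used where a full 18-session grid is unnecessary.
tiny_protocol <- function(seed = 1L, ...) {
  pvt_protocol(session_times_by_day = list("2" = 10, "3" = 10,
                                           "4" = c(10, 16, 18, 20, 22, 24)),
               seed = seed, ...)
}
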