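# Trial-level PVT simulator. Each trial is a two-component mixture: an
# attentive state with lognormal reaction times, and a lapse state with
# heavy-tailed (shifted Pareto) reaction times above the 500-ms lapse
# threshold. The per-trial lapse-state probability follows a logistic model
# combining trait lapse propensity, a saturating homeostatic sleep-pressure
# term that builds beyond 16 h awake, a circadian modulation, and a
# within-session time-on-task ramp.

# Saturating homeostatic basis: zero before 16 h awake, initial slope 1 per
# hour, saturating with time constant tau (hours). homeo_gain multiplies it,
# so homeo_gain keeps its "lapse log-odds per hour beyond 16 h" reading as
# the initial slope of the response.
homeo_basis <- function(t_awake, tau) {
  h <- pmax(0, t_awake - 16)
  tau * (1 - exp(-h / tau))
}

# Lapse-state log-odds for one participant at time-since-wake t (hours) and
# within-session minute m.
lapse_logodds <- function(traits, t_awake, minute, config) {
  traits$lapse_propensity +
    traits$homeo_gain * homeo_basis(t_awake, config$traits$homeo_tau) +
    traits$circ_amp * cos(2 * pi * (t_awake - traits$circ_phase) / 24) +
    traits$tot_gain * minute
}

#' Simulate a single PVT session
#'
#' Generates a 10-min (configurable) PVT session for one participant: trials
#' are emitted sequentially, separated by inter-stimulus intervals drawn
#' uniformly from `config$isi_range`, until the scheduled duration elapses.
#' Each trial is either an attentive-state response (lognormal RT), a
#' lapse-state response (shifted-Pareto RT of at least 500 ms), a false start
#' (anticipatory RT below 100 ms) or a wrong-button press; a trial with no
#' response within `config$rt_cap` ms is recorded as a timeout.
#'
#' @param traits a one-row `data.frame` of participant traits
#'   (see [sample_cohort()]).
#' @param day protocol day (2, 3 or 4).
#' @param time_since_wake scheduled time since wake in hours.
#' @param config a [pvt_protocol()] object.
#' @param seed optional integer seed for this session's RNG stream; defaults
#'   to a stream derived from `config$seed`, the participant id, day and time.
#' @return An object of class `pvt_session`: a list with fields
#'   `participant_id`, `day`, `time_since_wake`, `scheduled_time`,
#'   `actual_time`, `duration` (minutes) and `trials` (a `data.frame` with
#'   columns `trial_index`, `onset_s`, `rt_ms`, `button_ok`, `timeout`;
#'   `rt_ms` is `NA` for timeouts).
#' @export
simulate_session <- function(traits, day, time_since_wake,
                             config = pvt_protocol(), seed = NULL) {
  assert_that(config$session_duration > 0, "session duration must be positive")
  if (is.null(seed)) {
    pid_num <- sum(utf8ToInt(as.character(traits$participant_id[1])))
    seed <- derive_seed(config$seed, 7L, pid_num, day,
                        as.integer(round(time_since_wake * 10)))
  }
  dur_s <- config$session_duration * 60
  tp <- config$traits

  with_seed(seed, {
    # Renewal process: trial i appears one ISI after the response to trial
    # i - 1; the time-on-task minute entering the lapse-odds model is the
    # stimulus onset time. Random draws are made in chunks, then consumed
    # sequentially so the process is exact.
    cap <- ceiling(dur_s / config$isi_range[1]) + 10
    isi <- stats::runif(cap, config$isi_range[1], config$isi_range[2])
    u_fs <- stats::runif(cap)
    u_lapse <- stats::runif(cap)
    z_attn <- stats::rnorm(cap)
    u_pareto <- stats::runif(cap)
    u_button <- stats::runif(cap)

    onset <- numeric(cap); rt <- numeric(cap); fs <- logical(cap)
    clock <- 0; n <- 0
    for (i in seq_len(cap)) {
      t_on <- clock + isi[i]
      if (t_on >= dur_s) break
      minute <- t_on / 60
      if (u_fs[i] < config$false_start_rate) {
        r <- 10 + 80 * u_pareto[i]
        fs_i <- TRUE
      } else {
        eta <- lapse_logodds(traits, time_since_wake, minute, config)
        if (u_lapse[i] < 1 / (1 + exp(-eta))) {
          r <- tp$lapse_rt_min * u_pareto[i]^(-1 / tp$lapse_rt_alpha)
        } else {
          r <- exp(traits$base_speed + tp$attentive_tot_drift * minute +
                     traits$base_sd * z_attn[i])
        }
        fs_i <- FALSE
      }
      r <- min(r, config$rt_cap)
      n <- n + 1
      onset[n] <- t_on
      rt[n] <- r
      fs[n] <- fs_i
      clock <- t_on + r / 1000
      if (clock >= dur_s) break
    }
    onset <- onset[seq_len(n)]; rt <- rt[seq_len(n)]
    timeout <- as.integer(rt >= config$rt_cap)
    button_ok <- as.integer(u_button[seq_len(n)] >= config$wrong_button_rate)
    trials <- data.frame(
      trial_index = seq_len(n),
      onset_s = onset,
      rt_ms = ifelse(timeout == 1, NA_real_, rt),
      button_ok = button_ok,
      timeout = timeout
    )
    structure(
      list(
        participant_id = as.character(traits$participant_id[1]),
        day = day,
        time_since_wake = time_since_wake,
        scheduled_time = time_since_wake,
        actual_time = time_since_wake,
        duration = config$session_duration,
        trials = trials
      ),
      class = "pvt_session"
    )
  })
}

#' @export
print.pvt_session <- function(x, ...) {
  cat(sprintf("PVT session: %s, day %d, %g h after wake, %g min, %d trials\n",
              x$participant_id, x$day, x$time_since_wake, x$duration,
              nrow(x$trials)))
  invisible(x)
}

# Corrupt a session in one of the four QC-triggering ways. `mode` in
# {"late", "wrong_button", "gap", "truncated"}.
corrupt_session <- function(s, mode, seed) {
  with_seed(seed, {
    switch(mode,
      late = {
        s$actual_time <- s$scheduled_time + stats::runif(1, 1.05, 2)
      },
      wrong_button = {
        n <- nrow(s$trials)
        k <- max(ceiling(0.15 * n), 1)
        s$trials$button_ok[sample.int(n, k)] <- 0L
      },
      gap = {
        # remove all responses inside a 70-s window to leave a >1-min
        # recording gap
        start <- stats::runif(1, 60, s$duration * 60 - 140)
        keep <- s$trials$onset_s < start | s$trials$onset_s > start + 70
        s$trials <- s$trials[keep, , drop = FALSE]
        s$trials$trial_index <- seq_len(nrow(s$trials))
      },
      truncated = {
        cut_min <- stats::runif(1, 5, 7.9)
        s$trials <- s$trials[s$trials$onset_s < cut_min * 60, , drop = FALSE]
        s$trials$trial_index <- seq_len(nrow(s$trials))
        s$duration <- cut_min
      },
      stop("unknown corruption mode: ", mode)
    )
    s
  })
}

#' Simulate a complete study
#'
#' Simulates the full session grid (days 2-4, including the day-4 TSD block)
#' for `n` participants drawn via [sample_cohort()]. With probability
#' `config$invalid_session_rate` a session is corrupted in one of the four
#' ways that trigger session-validity screening (late administration,
#' wrong-button excess, >1-min response gap, truncation).
#'
#' @param n number of participants.
#' @param config a [pvt_protocol()] object.
#' @param cohort optional pre-drawn trait table ([sample_cohort()] layout);
#'   when supplied, `n` is ignored.
#' @return An object of class `pvt_study`: a list with `sessions` (list of
#'   `pvt_session`), `traits` (the ground-truth trait table, for testing
#'   only; never consumed by analysis stages) and `config`.
#' @export
simulate_study <- function(n, config = pvt_protocol(), cohort = NULL) {
  if (is.null(cohort)) cohort <- sample_cohort(n, config)
  modes <- c("late", "wrong_button", "gap", "truncated")
  sessions <- list()
  k <- 0
  for (i in seq_len(nrow(cohort))) {
    tr <- cohort[i, , drop = FALSE]
    for (d in names(config$session_times_by_day)) {
      for (t in config$session_times_by_day[[d]]) {
        k <- k + 1
        s <- simulate_session(tr, as.integer(d), t, config)
        if (config$invalid_session_rate > 0) {
          cseed <- derive_seed(config$seed, 23L, i, as.integer(d),
                               as.integer(round(t * 10)))
          u <- with_seed(cseed, stats::runif(2))
          if (u[1] < config$invalid_session_rate) {
            mode <- modes[ceiling(u[2] * 4)]
            s <- corrupt_session(s, mode, derive_seed(cseed, 1L))
          }
        }
        sessions[[k]] <- s
      }
    }
  }
  structure(list(sessions = sessions, traits = cohort, config = config),
            class = "pvt_study")
}

#' @export
print.pvt_study <- function(x, ...) {
  cat(sprintf("PVT study: %d participants, %d sessions\n",
              nrow(x$traits), length(x$sessions)))
  invisible(x)
}

# Session-level metadata table for a study.
session_index <- function(study) {
  do.call(rbind, lapply(study$sessions, function(s) {
    data.frame(participant_id = s$participant_id, day = s$day,
               time_since_wake = s$time_since_wake,
               scheduled_time = s$scheduled_time, actual_time = s$actual_time,
               duration = s$duration, n_trials = nrow(s$trials),
               stringsAsFactors = FALSE)
  }))
}

#' Write or read trial-level data as CSV
#'
#' The trial CSV dialect has one row per trial with columns
#' `participant_id, day, time_since_wake_h, scheduled_time_h, actual_time_h,
#' duration_min, trial_index, onset_s, rt_ms, button_ok, timeout`. The same
#' dialect is accepted for real data.
#'
#' @param study a `pvt_study` object.
#' @param path CSV file path.
#' @return `write_trials_csv` returns `path` invisibly; `read_trials_csv`
#'   returns a `pvt_study` (without ground-truth traits).
#' @export
write_trials_csv <- function(study, path) {
  rows <- lapply(study$sessions, function(s) {
    if (nrow(s$trials) == 0) return(NULL)
    cbind(data.frame(participant_id = s$participant_id, day = s$day,
                     time_since_wake_h = s$time_since_wake,
                     scheduled_time_h = s$scheduled_time,
                     actual_time_h = s$actual_time,
                     duration_min = s$duration,
                     stringsAsFactors = FALSE),
          s$trials)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "day", "time_since_wake_h", "scheduled_time_h",
            "actual_time_h", "duration_min", "trial_index", "onset_s",
            "rt_ms", "button_ok", "timeout")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("trial CSV missing columns: ", paste(missing_cols, collapse = ", "))
  }
  key <- interaction(df$participant_id, df$day, df$time_since_wake_h,
                     drop = TRUE)
  sessions <- lapply(split(df, key), function(g) {
    g <- g[order(g$onset_s), , drop = FALSE]
    structure(
      list(participant_id = g$participant_id[1], day = g$day[1],
           time_since_wake = g$time_since_wake_h[1],
           scheduled_time = g$scheduled_time_h[1],
           actual_time = g$actual_time_h[1], duration = g$duration_min[1],
           trials = data.frame(trial_index = g$trial_index,
                               onset_s = g$onset_s, rt_ms = g$rt_ms,
                               button_ok = g$button_ok, timeout = g$timeout)),
      class = "pvt_session"
    )
  })
  names(sessions) <- NULL
  structure(list(sessions = sessions, traits = NULL, config = NULL),
            class = "pvt_study")
}

#' Write ground-truth traits as CSV
#'
#' Traits are written separately from trial data and are never read by any
#' analysis stage; they exist for testing the generator only.
#'
#' @param study a `pvt_study` object with traits.
#' @param path CSV file path.
#' @export
write_traits_csv <- function(study, path) {
  assert_that(!is.null(study$traits), "study has no ground-truth traits")
  utils::write.csv(study$traits, path, row.names = FALSE)
  invisible(path)
}
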