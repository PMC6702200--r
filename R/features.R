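# Per-session PVT summary measures. The catalog enumerates, per family, the
# parameterized measures computed from trial-by-trial reaction times; its
# order is fixed and the catalog object is the ground truth for feature
# naming and count.

#' Build a PVT feature catalog
#'
#' Enumerates the per-session summary measures, grouped in nine families:
#' central tendency (mean/median RT, fastest- and slowest-10% mean RT),
#' reciprocal RT (mean/median/SD of 1000/RT, in 1/s), RT percentiles,
#' differences of percentile RTs for every ordered percentile pair, lapse
#' counts at multiple thresholds, variability (SD, IQR), counts of large
#' consecutive-RT differences plus mean |successive difference|, error counts
#' (false starts, timeouts) and time-on-task measures (per-minute OLS slopes
#' of RT, of reciprocal RT and of the per-minute 500-ms lapse count, and the
#' first-two-minutes minus last-two-minutes mean RT difference).
#'
#' @param families optional subset of family names to include (default: all).
#' @param percentile_grid percentiles (in percent) for the `percentile` and
#'   `percentile_difference` families; default `seq(5, 95, by = 5)`.
#' @param lapse_thresholds lapse-count thresholds in ms; default
#'   `c(355, 500, 1000, 2000, 5000)`. The 355-ms entry represents thresholds
#'   tied to eyes-closed probability; all are configurable.
#' @param cdiff_thresholds thresholds (ms) for counting large consecutive-RT
#'   differences; default `c(100, 250, 500, 1000)`.
#' @param false_start_max RTs below this (ms) are anticipatory false starts,
#'   excluded from RT-distribution features and counted as errors;
#'   default 100.
#' @return An object of class `pvt_catalog`: a `data.frame` with columns
#'   `name`, `family`, `p1`, `p2` and the attribute `false_start_max`.
#'   Feature names are unique and the row order is fixed.
#' @export
pvt_catalog <- function(families = NULL,
                        percentile_grid = seq(5, 95, by = 5),
                        lapse_thresholds = c(355, 500, 1000, 2000, 5000),
                        cdiff_thresholds = c(100, 250, 500, 1000),
                        false_start_max = 100) {
  all_families <- c("central_tendency", "reciprocal_rt", "percentile",
                    "percentile_difference", "lapse_count", "variability",
                    "consecutive_difference", "error_count", "time_on_task")
  if (is.null(families)) families <- all_families
  bad <- setdiff(families, all_families)
  if (length(bad) > 0) stop("unknown feature families: ",
                            paste(bad, collapse = ", "))
  if (length(percentile_grid) == 0 || length(lapse_thresholds) == 0 ||
      length(cdiff_thresholds) == 0) {
    stop("feature parameter grids must be non-empty")
  }
  percentile_grid <- sort(unique(percentile_grid))

  rows <- list()
  add <- function(name, family, p1 = NA_real_, p2 = NA_real_) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, family = family, p1 = p1, p2 = p2,
      stringsAsFactors = FALSE)
  }
  if ("central_tendency" %in% families) {
    add("mean_rt", "central_tendency")
    add("median_rt", "central_tendency")
    add("fastest10_mean_rt", "central_tendency", 10)
    add("slowest10_mean_rt", "central_tendency", 90)
  }
  if ("reciprocal_rt" %in% families) {
    add("mean_recip_rt", "reciprocal_rt")
    add("median_recip_rt", "reciprocal_rt")
    add("sd_recip_rt", "reciprocal_rt")
  }
  if ("percentile" %in% families) {
    for (p in percentile_grid) add(sprintf("rt_p%02d", p), "percentile", p)
  }
  if ("percentile_difference" %in% families) {
    for (i in seq_along(percentile_grid)) {
      for (j in seq_along(percentile_grid)) {
        if (j > i) {
          add(sprintf("rt_p%02d_p%02d_diff", percentile_grid[i],
                      percentile_grid[j]),
              "percentile_difference", percentile_grid[i], percentile_grid[j])
        }
      }
    }
  }
  if ("lapse_count" %in% families) {
    for (thr in lapse_thresholds) {
      add(sprintf("lapses_gt%d", thr), "lapse_count", thr)
    }
  }
  if ("variability" %in% families) {
    add("sd_rt", "variability")
    add("iqr_rt", "variability")
  }
  if ("consecutive_difference" %in% families) {
    for (thr in cdiff_thresholds) {
      add(sprintf("cdiff_gt%d", thr), "consecutive_difference", thr)
    }
    add("mean_abs_cdiff", "consecutive_difference")
  }
  if ("error_count" %in% families) {
    add("n_false_starts", "error_count")
    add("n_timeouts", "error_count")
  }
  if ("time_on_task" %in% families) {
    add("tot_slope_rt", "time_on_task")
    add("tot_slope_recip_rt", "time_on_task")
    add("first2_minus_last2_mean_rt", "time_on_task")
    add("tot_slope_lapse", "time_on_task", 500)
  }
  cat <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(cat$name))
  attr(cat, "false_start_max") <- false_start_max
  class(cat) <- c("pvt_catalog", "data.frame")
  cat
}

#' Serialize or restore a feature catalog
#'
#' @param catalog a [pvt_catalog()] object.
#' @param path JSON file path.
#' @export
write_catalog <- function(catalog, path) {
  jsonlite::write_json(
    list(false_start_max = attr(catalog, "false_start_max"),
         features = as.data.frame(catalog)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cat <- x$features
  attr(cat, "false_start_max") <- x$false_start_max
  class(cat) <- c("pvt_catalog", "data.frame")
  cat
}

# ---- single-purpose primitives -------------------------------------------

#' Count lapses above a reaction-time threshold
#'
#' Counts responded reaction times strictly exceeding `threshold` ms.
#' Timeout trials count as lapses for every threshold below the response
#' cap, and are passed via `n_timeouts`.
#'
#' @param rts numeric vector of valid responded reaction times (ms).
#' @param threshold lapse threshold in ms.
#' @param n_timeouts number of timeout trials in the session (default 0).
#' @return Non-negative integer count; an empty `rts` gives `n_timeouts`.
#' @export
lapse_count <- function(rts, threshold, n_timeouts = 0) {
  sum(rts > threshold) + n_timeouts
}

#' Difference of percentile reaction times
#'
#' `P(p_hi) - P(p_lo)` of the empirical quantile function with linear
#' interpolation (`stats::quantile` type 7), stated explicitly because
#' quantile dialects differ. Always non-negative.
#'
#' @param rts numeric vector of reaction times (ms); at least 2 required.
#' @param p_lo,p_hi percentiles in percent with `p_lo < p_hi`.
#' @return Difference in ms, or `NA` when fewer than 2 RTs are available.
#' @export
percentile_difference <- function(rts, p_lo, p_hi) {
  assert_that(p_lo < p_hi, "p_lo must be smaller than p_hi")
  if (length(rts) < 2) return(NA_real_)
  q <- stats::quantile(rts, probs = c(p_lo, p_hi) / 100, names = FALSE,
                       type = 7)
  q[2] - q[1]
}

#' Count large consecutive reaction-time differences
#'
#' Counts adjacent responded-trial pairs (in trial order) whose absolute RT
#' difference strictly exceeds `threshold` ms.
#'
#' @param rts reaction times in trial order (ms).
#' @param threshold difference threshold in ms.
#' @return Non-negative integer count.
#' @export
consecutive_diff_count <- function(rts, threshold) {
  if (length(rts) < 2) return(0L)
  sum(abs(diff(rts)) > threshold)
}

#' Time-on-task slope of reaction time
#'
#' OLS slope of RT (ms) against elapsed minutes within the session.
#'
#' @param rts reaction times (ms) of responded trials, in trial order.
#' @param onset_s stimulus onset times (seconds) of the same trials.
#' @return Slope in ms per minute, or `NA` when fewer than 2 trials or the
#'   trials span no more than 1 minute.
#' @export
time_on_task_slope <- function(rts, onset_s) {
  if (length(rts) < 2) return(NA_real_)
  minutes <- onset_s / 60
  if (diff(range(minutes)) <= 1) return(NA_real_)
  xc <- minutes - mean(minutes)
  sum(xc * (rts - mean(rts))) / sum(xc^2)
}

# ---- full catalog evaluation ---------------------------------------------

#' Compute the feature vector for one session
#'
#' Evaluates every catalog entry on a session. False starts (RT below the
#' catalog's `false_start_max`), timeouts and wrong-button trials are
#' excluded from RT-distribution features; false starts and timeouts are
#' counted by the `error_count` family and timeouts additionally count as
#' lapses. Features that are undefined on the session (e.g. percentile
#' differences with fewer than 2 RTs) are `NA`.
#'
#' @param s a `pvt_session` object.
#' @param catalog a [pvt_catalog()] object.
#' @param valid set to `FALSE` for an invalid session, yielding an
#'   all-missing vector.
#' @return A named numeric vector with one value per catalog entry.
#' @export
compute_features <- function(s, catalog = pvt_catalog(), valid = TRUE) {
  out <- rep(NA_real_, nrow(catalog))
  names(out) <- catalog$name
  if (!valid) return(out)

  fs_max <- attr(catalog, "false_start_max")
  tr <- s$trials
  responded <- tr$timeout == 0
  is_fs <- responded & tr$rt_ms < fs_max
  keep <- responded & !is_fs & tr$button_ok == 1
  rts <- tr$rt_ms[keep]
  onset <- tr$onset_s[keep]
  n_timeouts <- sum(tr$timeout == 1)
  n_fs <- sum(is_fs)
  n <- length(rts)

  recip <- 1000 / rts # 1/s
  dur <- s$duration
  sorted <- sort(rts)

  # type-7 quantile of the pre-sorted sample (matches stats::quantile type 7)
  q7 <- function(p) {
    if (n == 0) return(NA_real_)
    h <- (n - 1) * p / 100 + 1
    lo <- floor(h)
    x_lo <- sorted[lo]
    x_hi <- sorted[pmin(lo + 1, n)]
    x_lo + (h - lo) * (x_hi - x_lo)
  }

  fam <- catalog$family
  nm <- catalog$name
  p1 <- catalog$p1; p2 <- catalog$p2

  i <- which(fam == "central_tendency")
  if (length(i) > 0 && n > 0) {
    k <- max(1L, ceiling(0.1 * n))
    vals <- c(mean_rt = mean(rts), median_rt = stats::median(rts),
              fastest10_mean_rt = mean(sorted[seq_len(k)]),
              slowest10_mean_rt = mean(sorted[n - seq_len(k) + 1]))
    out[i] <- vals[nm[i]]
  }
  i <- which(fam == "reciprocal_rt")
  if (length(i) > 0 && n > 0) {
    vals <- c(mean_recip_rt = mean(recip),
              median_recip_rt = stats::median(recip),
              sd_recip_rt = if (n < 2) NA_real_ else stats::sd(recip))
    out[i] <- vals[nm[i]]
  }
  i <- which(fam == "percentile")
  if (length(i) > 0 && n > 0) out[i] <- q7(p1[i])
  i <- which(fam == "percentile_difference")
  if (length(i) > 0 && n >= 2) out[i] <- q7(p2[i]) - q7(p1[i])
  i <- which(fam == "lapse_count")
  if (length(i) > 0) {
    out[i] <- vapply(p1[i], function(thr) sum(rts > thr), 0) + n_timeouts
  }
  i <- which(fam == "variability")
  if (length(i) > 0 && n >= 2) {
    vals <- c(sd_rt = stats::sd(rts), iqr_rt = q7(75) - q7(25))
    out[i] <- vals[nm[i]]
  }
  i <- which(fam == "consecutive_difference")
  if (length(i) > 0) {
    d <- if (n >= 2) abs(diff(rts)) else numeric(0)
    out[i] <- ifelse(nm[i] == "mean_abs_cdiff",
                     if (n >= 2) mean(d) else NA_real_,
                     vapply(p1[i], function(thr) sum(d > thr), 0))
  }
  i <- which(fam == "error_count")
  if (length(i) > 0) {
    out[i] <- ifelse(nm[i] == "n_false_starts", n_fs, n_timeouts)
  }
  i <- which(fam == "time_on_task")
  for (j in i) {
    out[j] <- switch(nm[j],
      tot_slope_rt = time_on_task_slope(rts, onset),
      tot_slope_recip_rt = time_on_task_slope(recip, onset),
      first2_minus_last2_mean_rt = {
        a <- rts[onset < 120]
        b <- rts[onset > (dur - 2) * 60]
        if (length(a) == 0 || length(b) == 0) NA_real_
        else mean(a) - mean(b)
      },
      tot_slope_lapse = {
        mins <- floor(onset / 60)
        grid <- 0:(ceiling(dur) - 1)
        counts <- vapply(grid, function(m) sum(rts[mins == m] > p1[j]), 0)
        x <- grid + 0.5
        xc <- x - mean(x)
        sum(xc * (counts - mean(counts))) / sum(xc^2)
      })
  }
  out
}

#' Compute features for every session in a study
#'
#' @param study a `pvt_study` object.
#' @param catalog a [pvt_catalog()] object.
#' @param validity optional [validate_study()] table; sessions marked invalid
#'   yield all-missing feature vectors.
#' @return A wide `data.frame` with `participant_id`, `day`,
#'   `time_since_wake`, then one column per catalog entry.
#' @export
compute_feature_table <- function(study, catalog = pvt_catalog(),
                                  validity = NULL) {
  vkey <- NULL
  if (!is.null(validity)) {
    vkey <- paste(validity$participant_id, validity$day,
                  validity$time_since_wake)
  }
  rows <- lapply(study$sessions, function(s) {
    ok <- TRUE
    if (!is.null(vkey)) {
      k <- paste(s$participant_id, s$day, s$time_since_wake)
      m <- match(k, vkey)
      if (!is.na(m)) ok <- validity$is_valid[m]
    }
    c(compute_features(s, catalog, valid = ok))
  })
  meta <- session_index(study)[, c("participant_id", "day",
                                   "time_since_wake")]
  cbind(meta, as.data.frame(do.call(rbind, rows)))
}

#' Write a feature table in long format
#'
#' @param features a [compute_feature_table()] result.
#' @param path CSV file path.
#' @export
write_features_csv <- function(features, path) {
  meta_cols <- c("participant_id", "day", "time_since_wake")
  feat_cols <- setdiff(names(features), meta_cols)
  long <- do.call(rbind, lapply(feat_cols, function(fc) {
    data.frame(features[meta_cols], feature_name = fc,
               value = features[[fc]], stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
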