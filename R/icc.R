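# Intraclass-correlation screening of candidate features. For each feature
# at each baseline time-since-wake, repeated measurements across days 2-4
# are decomposed with a linear mixed model (day as a fixed factor to absorb
# systematic order effects; participant as a Gaussian random intercept,
# fitted by REML). The ICC is the between-participant variance over the sum
# of between- and within-participant variance; features with ICC above the
# screening threshold (default 0.60, the conventional cutoff for
# 'substantial'/'good' agreement) are retained as model candidates.

#' Variance components of a participant-by-day table
#'
#' Fits `value ~ day + (1 | participant)` by REML (via lme4) and returns the
#' random-intercept (between-participant) and residual (within-participant)
#' variance estimates. With `fixed_effect = FALSE` the day term is dropped,
#' which makes the REML estimate comparable to the closed-form one-way ANOVA
#' estimator on balanced data.
#'
#' @param values numeric vector of measurements.
#' @param participant factor or character of participant ids (same length).
#' @param day factor or character of day labels (same length).
#' @param fixed_effect include day as a fixed factor (default `TRUE`).
#' @return A list with `var_between`, `var_within` (both >= 0) and `icc`
#'   (`var_between / (var_between + var_within)`, defined as 0 when both
#'   variances are 0).
#' @export
fit_variance_components <- function(values, participant, day,
                                    fixed_effect = TRUE) {
  ok <- !is.na(values)
  values <- values[ok]
  participant <- factor(participant[ok])
  day <- factor(day[ok])
  assert_that(nlevels(participant) >= 2,
              "at least 2 participants with data are required")
  if (stats::var(values) == 0) {
    return(list(var_between = 0, var_within = 0, icc = 0))
  }
  df <- data.frame(value = values, participant = participant, day = day)
  form <- if (fixed_effect && nlevels(day) >= 2) {
    value ~ day + (1 | participant)
  } else {
    value ~ 1 + (1 | participant)
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = df, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))
  ))
  vc <- lme4::VarCorr(fit)
  var_between <- max(0, as.numeric(vc$participant[1, 1]))
  var_within <- max(0, attr(vc, "sc")^2)
  denom <- var_between + var_within
  list(var_between = var_between, var_within = var_within,
       icc = if (denom > 0) var_between / denom else 0)
}

#' ICC table for every feature at one time point
#'
#' For a single baseline time-since-wake, gathers each feature's values
#' across days 2-4 and computes its variance components and ICC.
#'
#' @param features a [compute_feature_table()] result restricted to matched
#'   sessions (same `time_since_wake`) on days 2, 3 and 4.
#' @param min_coverage a feature observed on fewer than this fraction of
#'   participants is skipped with a warning (default 0.5).
#' @return A `data.frame` with `feature`, `time_since_wake`, `var_between`,
#'   `var_within`, `icc`, `n_participants`, `n_days`.
#' @export
icc_table <- function(features, min_coverage = 0.5) {
  meta_cols <- c("participant_id", "day", "time_since_wake")
  feat_cols <- setdiff(names(features), meta_cols)
  tt <- unique(features$time_since_wake)
  assert_that(length(tt) == 1,
              "icc_table expects sessions at a single time_since_wake")
  n_part <- length(unique(features$participant_id))
  rows <- lapply(feat_cols, function(fc) {
    v <- features[[fc]]
    ok <- !is.na(v)
    covered <- length(unique(features$participant_id[ok])) / n_part
    if (covered < min_coverage || stats::var(v[ok]) == 0 ||
        length(unique(features$day[ok])) < 2) {
      if (covered < min_coverage) {
        warning("feature ", fc, " observed for under ",
                round(100 * min_coverage), "% of participants; skipped",
                call. = FALSE)
      }
      return(data.frame(feature = fc, time_since_wake = tt,
                        var_between = NA_real_, var_within = NA_real_,
                        icc = NA_real_, n_participants = sum(ok),
                        n_days = length(unique(features$day[ok])),
                        stringsAsFactors = FALSE))
    }
    vc <- fit_variance_components(v, features$participant_id, features$day)
    data.frame(feature = fc, time_since_wake = tt,
               var_between = vc$var_between, var_within = vc$var_within,
               icc = vc$icc,
               n_participants = length(unique(features$participant_id[ok])),
               n_days = length(unique(features$day[ok])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Screen features by ICC
#'
#' Returns the names of features whose ICC strictly exceeds `threshold`
#' (default 0.60). Screening is per time point, so models developed at
#' different baseline times may use different candidate sets; features that
#' fail are excluded and not revisited.
#'
#' @param features a [compute_feature_table()] result for one
#'   `time_since_wake` across days 2-4.
#' @param threshold ICC screening threshold (strict; default 0.60).
#' @param min_coverage passed to [icc_table()].
#' @return Character vector of candidate feature names, with the full ICC
#'   table attached as attribute `"icc_table"`.
#' @export
screen_features <- function(features, threshold = 0.60, min_coverage = 0.5) {
  tab <- icc_table(features, min_coverage = min_coverage)
  keep <- tab$feature[!is.na(tab$icc) & tab$icc > threshold]
  structure(keep, icc_table = tab)
}
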