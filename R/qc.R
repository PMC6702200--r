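# Session-validity and participant-inclusion screening.
#
# A session is invalid when it was administered more than an hour after the
# scheduled time, when the wrong response button was used on more than 10% of
# trials, when no reaction time was recorded for more than 1 minute, or when
# the session was truncated to under 8 minutes. A participant is excluded
# when any of the five TSD sessions (16-24 h after wake) is missing or
# invalid; invalid baseline sessions do not exclude a participant.

#' Validate a single PVT session
#'
#' @param s a `pvt_session` object.
#' @param late_margin maximum tolerated administration delay in hours
#'   (default 1).
#' @param wrong_button_max maximum tolerated wrong-button fraction
#'   (default 0.10, strict: a fraction above the cutoff is invalid).
#' @param gap_max maximum tolerated interval without a recorded response, in
#'   seconds (default 60). Gaps are measured between consecutive recorded
#'   response times, and from session start to the first response and last
#'   response to session end.
#' @param min_duration minimum session duration in minutes (default 8).
#' @return A list of class `pvt_validity` with `participant_id`, `day`,
#'   `time_since_wake`, `is_valid` and `reasons` (a character vector drawn
#'   from `late_admin`, `wrong_button_excess`, `response_gap`, `truncated`,
#'   `missing`; empty when valid).
#' @export
validate_session <- function(s, late_margin = 1, wrong_button_max = 0.10,
                             gap_max = 60, min_duration = 8) {
  reasons <- character(0)
  tr <- s$trials
  if (is.null(tr) || nrow(tr) == 0) {
    reasons <- "missing"
  } else {
    if (s$actual_time - s$scheduled_time > late_margin) {
      reasons <- c(reasons, "late_admin")
    }
    # denominator: all recorded trials, timeouts included
    if (mean(tr$button_ok == 0) > wrong_button_max) {
      reasons <- c(reasons, "wrong_button_excess")
    }
    resp_t <- tr$onset_s[tr$timeout == 0] +
      tr$rt_ms[tr$timeout == 0] / 1000
    gaps <- diff(c(0, sort(resp_t), s$duration * 60))
    if (length(resp_t) == 0 || any(gaps > gap_max)) {
      reasons <- c(reasons, "response_gap")
    }
    if (s$duration < min_duration) {
      reasons <- c(reasons, "truncated")
    }
  }
  structure(
    list(participant_id = s$participant_id, day = s$day,
         time_since_wake = s$time_since_wake,
         is_valid = length(reasons) == 0, reasons = reasons),
    class = "pvt_validity"
  )
}

#' Validate every session of a study
#'
#' @param study a `pvt_study` object.
#' @param ... passed to [validate_session()].
#' @return A `data.frame` with one row per session: `participant_id`, `day`,
#'   `time_since_wake`, `is_valid`, `reasons` (comma-separated).
#' @export
validate_study <- function(study, ...) {
  do.call(rbind, lapply(study$sessions, function(s) {
    v <- validate_session(s, ...)
    data.frame(participant_id = v$participant_id, day = v$day,
               time_since_wake = v$time_since_wake, is_valid = v$is_valid,
               reasons = paste(v$reasons, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

#' Select participants with complete, valid TSD data
#'
#' A participant is excluded when one or more of the five sleep-deprivation
#' sessions (scheduled 16, 18, 20, 22 and 24 h after wake on day 4) is
#' missing or invalid, because those sessions define the vulnerability
#' outcome. Invalid baseline sessions never exclude a participant; the
#' affected time point simply contributes no feature vector.
#'
#' @param study a `pvt_study` object.
#' @param validity optional precomputed [validate_study()] table.
#' @param tsd_times the required TSD session times (hours after wake).
#' @return A list with `included` (character vector of participant ids) and
#'   `excluded` (a `data.frame` of id and reason).
#' @export
select_participants <- function(study, validity = NULL,
                                tsd_times = c(16, 18, 20, 22, 24)) {
  if (is.null(validity)) validity <- validate_study(study)
  ids <- unique(vapply(study$sessions, `[[`, "", "participant_id"))
  excluded <- list()
  for (id in ids) {
    v <- validity[validity$participant_id == id & validity$day == 4 &
                    validity$time_since_wake %in% tsd_times, , drop = FALSE]
    msgs <- character(0)
    absent <- setdiff(tsd_times, v$time_since_wake)
    if (length(absent) > 0) {
      msgs <- c(msgs, sprintf("missing TSD session at %g h",
                              absent))
    }
    bad <- v[!v$is_valid, , drop = FALSE]
    if (nrow(bad) > 0) {
      msgs <- c(msgs, sprintf("invalid TSD session at %g h (%s)",
                              bad$time_since_wake, bad$reasons))
    }
    if (length(msgs) > 0) {
      excluded[[id]] <- data.frame(participant_id = id,
                                   reason = paste(msgs, collapse = "; "),
                                   stringsAsFactors = FALSE)
    }
  }
  excluded <- if (length(excluded) > 0) {
    do.call(rbind, excluded)
  } else {
    data.frame(participant_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  }
  list(included = setdiff(ids, excluded$participant_id), excluded = excluded)
}
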