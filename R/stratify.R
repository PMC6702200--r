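# Vulnerability stratification: participants are ranked by their mean number
# of 500-ms lapses across the five TSD sessions (16-24 h after wake); the
# quartile with the fewest lapses is resilient, the quartile with the most is
# vulnerable, and the middle half is intermediate.

#' Mean TSD lapse count for one participant
#'
#' Arithmetic mean of the 500-ms lapse counts of the five sleep-deprivation
#' sessions (16, 18, 20, 22 and 24 h after wake). Timeouts count as lapses.
#'
#' @param study a `pvt_study` object.
#' @param participant_id participant identifier.
#' @param times TSD session times (hours after wake).
#' @param threshold lapse threshold in ms (default 500).
#' @param false_start_max RTs below this (ms) are false starts and are not
#'   counted (default 100).
#' @return Mean lapses per TSD session.
#' @export
tsd_score <- function(study, participant_id, times = c(16, 18, 20, 22, 24),
                      threshold = 500, false_start_max = 100) {
  counts <- session_lapse_counts(study, participant_id, times, threshold,
                                 false_start_max)
  if (anyNA(counts)) {
    stop("participant ", participant_id,
         " is missing a TSD session; it should have been excluded upstream")
  }
  mean(counts)
}

# 500-ms lapse counts for one participant's day-4 sessions at `times`;
# NA where a session is absent.
session_lapse_counts <- function(study, participant_id, times,
                                 threshold = 500, false_start_max = 100) {
  vapply(times, function(tt) {
    for (s in study$sessions) {
      if (s$participant_id == participant_id && s$day == 4 &&
          s$time_since_wake == tt) {
        tr <- s$trials
        keep <- tr$timeout == 0 & tr$rt_ms >= false_start_max &
          tr$button_ok == 1
        return(lapse_count(tr$rt_ms[keep], threshold, sum(tr$timeout == 1)))
      }
    }
    NA_real_
  }, 0)
}

#' Mean TSD lapse counts for many participants
#'
#' @param study a `pvt_study` object.
#' @param ids participant identifiers (default: everyone in the study).
#' @inheritParams tsd_score
#' @return Named numeric vector of mean TSD lapse counts.
#' @export
tsd_scores <- function(study, ids = NULL, times = c(16, 18, 20, 22, 24),
                       threshold = 500, false_start_max = 100) {
  if (is.null(ids)) {
    ids <- unique(vapply(study$sessions, `[[`, "", "participant_id"))
  }
  # index sessions once for speed
  key <- vapply(study$sessions, function(s) {
    paste(s$participant_id, s$day, s$time_since_wake)
  }, "")
  out <- vapply(ids, function(id) {
    counts <- vapply(times, function(tt) {
      m <- match(paste(id, 4, tt), key)
      if (is.na(m)) return(NA_real_)
      tr <- study$sessions[[m]]$trials
      keep <- tr$timeout == 0 & tr$rt_ms >= false_start_max & tr$button_ok == 1
      lapse_count(tr$rt_ms[keep], threshold, sum(tr$timeout == 1))
    }, 0)
    mean(counts)
  }, 0)
  names(out) <- ids
  out
}

#' Assign vulnerability labels from TSD scores
#'
#' Ranks participants by score (ascending); the lowest `floor(n/4)` are
#' resilient, the highest `floor(n/4)` are vulnerable, and the remainder are
#' intermediate. This reproduces the 40/80/40 split at n = 160 and the
#' 15/30/15 split at n = 60. Ties are broken by stable participant-id order
#' (the order of `scores`).
#'
#' @param scores named numeric vector of mean TSD lapse counts (names are
#'   participant ids).
#' @return A `data.frame` with `participant_id`, `tsd_mean_lapses` and
#'   `label` (factor with levels resilient, intermediate, vulnerable).
#' @export
assign_labels <- function(scores) {
  n <- length(scores)
  assert_that(n >= 4, "at least 4 participants are needed for quartile labels")
  q <- floor(n / 4)
  ord <- order(scores, seq_len(n)) # stable: ties broken by input order
  label <- rep("intermediate", n)
  label[ord[seq_len(q)]] <- "resilient"
  label[ord[(n - q + 1):n]] <- "vulnerable"
  data.frame(
    participant_id = if (is.null(names(scores))) as.character(seq_len(n))
                     else names(scores),
    tsd_mean_lapses = unname(scores),
    label = as_vuln_factor(label),
    stringsAsFactors = FALSE
  )
}

#' Select high-performing participants at baseline
#'
#' Returns the ids of participants whose mean 500-ms lapse count across the
#' six day-4 baseline sessions (4-14 h after wake) is at most
#' `max_mean_lapses` (boundary inclusive). The high-performer subgroup is
#' then re-stratified with [assign_labels()] within the subgroup only.
#'
#' @param study a `pvt_study` object.
#' @param ids candidate participant ids (default: everyone).
#' @param baseline_times day-4 baseline session times (hours after wake).
#' @param max_mean_lapses inclusion cutoff on the mean baseline lapse count
#'   (default 2).
#' @return Character vector of included participant ids.
#' @export
select_high_performers <- function(study, ids = NULL,
                                   baseline_times = c(4, 6, 8, 10, 12, 14),
                                   max_mean_lapses = 2) {
  base <- tsd_scores(study, ids, times = baseline_times)
  names(base)[!is.na(base) & base <= max_mean_lapses]
}

#' Write vulnerability labels as CSV
#'
#' @param labels an [assign_labels()] result.
#' @param path CSV file path.
#' @param cohort cohort tag recorded in the file (`"full"` or
#'   `"high_performer"`).
#' @export
write_labels_csv <- function(labels, path, cohort = "full") {
  labels$cohort <- cohort
  utils::write.csv(labels, path, row.names = FALSE)
  invisible(path)
}
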