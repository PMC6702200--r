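# Performance metrics for the three-class vulnerability classifier:
# accuracy, Cohen's kappa, per-task (resilient-vs-rest and
# vulnerable-vs-rest) sensitivity/specificity/PPV/NPV, modal group
# assignment over repeated CV runs, and group lapse time courses.

#' Three-class confusion matrix
#'
#' @param truth true labels.
#' @param predicted predicted labels (`NA`s are dropped pairwise).
#' @return 3x3 matrix of counts `N[true, predicted]` in canonical class
#'   order.
#' @export
confusion3 <- function(truth, predicted) {
  t_f <- as_vuln_factor(truth)
  p_f <- as_vuln_factor(predicted)
  ok <- !is.na(t_f) & !is.na(p_f)
  m <- table(true = t_f[ok], predicted = p_f[ok])
  matrix(as.integer(m), 3, 3,
         dimnames = list(true = .classes, predicted = .classes))
}

#' Classification accuracy
#'
#' Proportion of participants whose predicted group matches the true group:
#' the trace of the confusion matrix over its total.
#'
#' @param conf a [confusion3()] matrix.
#' @return Proportion in `[0, 1]`.
#' @export
accuracy <- function(conf) {
  total <- sum(conf)
  assert_that(total > 0, "empty confusion matrix")
  sum(diag(conf)) / total
}

#' Cohen's kappa
#'
#' Accuracy discounted by the agreement expected from the marginal label
#' distributions: `(p_o - p_e) / (1 - p_e)` with `p_o` the observed accuracy
#' and `p_e = sum_k (row_k/total)(col_k/total)`. Defined as 0 in the
#' degenerate case `p_e = 1`.
#'
#' @param conf a [confusion3()] matrix.
#' @return Kappa value.
#' @export
kappa3 <- function(conf) {
  total <- sum(conf)
  assert_that(total > 0, "empty confusion matrix")
  p_o <- sum(diag(conf)) / total
  p_e <- sum(rowSums(conf) * colSums(conf)) / total^2
  if (p_e >= 1) return(0)
  (p_o - p_e) / (1 - p_e)
}

#' Chance-level accuracy of label-independent prediction
#'
#' Expected accuracy when predictions are a uniformly random permutation of
#' the true label multiset: `sum_k (n_k / n)^2`. For the 40/80/40 cohort
#' this is 0.375.
#'
#' @param class_counts vector of per-class counts.
#' @return Proportion in `[0, 1]`.
#' @export
chance_accuracy <- function(class_counts) {
  assert_that(all(class_counts > 0) && sum(class_counts) > 0,
              "class counts must be positive")
  sum((class_counts / sum(class_counts))^2)
}

#' Binary one-vs-rest metrics
#'
#' Collapses the three-class confusion to `target`-vs-rest and computes
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive predictive
#' value `TP/(TP+FP)` and negative predictive value `TN/(TN+FN)`. A rate
#' with a zero denominator is reported as `NA` with a warning, never as 0 by
#' convention.
#'
#' @param conf a [confusion3()] matrix.
#' @param target `"resilient"` or `"vulnerable"`.
#' @return Named numeric vector `c(sensitivity, specificity, ppv, npv)`.
#' @export
binary_metrics <- function(conf, target = c("vulnerable", "resilient")) {
  target <- match.arg(target)
  pos <- which(.classes == target)
  tp <- conf[pos, pos]
  fn <- sum(conf[pos, -pos])
  fp <- sum(conf[-pos, pos])
  tn <- sum(conf[-pos, -pos])
  rate <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  c(sensitivity = rate(tp, tp + fn, "sensitivity"),
    specificity = rate(tn, tn + fp, "specificity"),
    ppv = rate(tp, tp + fp, "PPV"),
    npv = rate(tn, tn + fn, "NPV"))
}

#' Modal group assignment across repeated CV runs
#'
#' Each participant receives one prediction per CV run; the most common
#' prediction determines the participant's assigned group. Ties are broken
#' by the canonical class order (resilient before intermediate before
#' vulnerable).
#'
#' @param predictions an n x repeats matrix of predictions: integer codes
#'   (1..3 in canonical order) or label strings. `NA`s are ignored.
#' @return Factor of assigned labels, one per participant.
#' @export
modal_assignment <- function(predictions) {
  predictions <- as.matrix(predictions)
  if (!is.numeric(predictions)) {
    predictions <- matrix(as.integer(as_vuln_factor(predictions)),
                          nrow(predictions), ncol(predictions))
  }
  lab <- apply(predictions, 1, function(row) {
    row <- row[!is.na(row)]
    if (length(row) == 0) return(NA_integer_)
    counts <- tabulate(row, 3)
    which.max(counts) # first maximum = lowest class in canonical order
  })
  factor(.classes[lab], levels = .classes)
}

#' Cross-validated performance metrics in the style of a results table
#'
#' Runs repeated stratified k-fold cross-validation for a fixed feature
#' subset and cost matrix, computes every metric within each run, and
#' summarizes each metric as mean and SD across runs. Also returns the
#' per-run prediction matrix so modal group assignments can be formed.
#'
#' @param x feature matrix or data.frame.
#' @param labels vulnerability labels.
#' @param subset feature subset (character).
#' @param cost cost scalar or 3x3 matrix.
#' @param cv a [cv_config()].
#' @return A list of class `cv_metrics` with `summary` (a `data.frame` of
#'   metric mean/sd), `predictions` (n x repeats integer matrix),
#'   `modal` (factor of modal assignments), `chance` (chance-level
#'   accuracy) and `n_evaluated`.
#' @export
cv_metrics <- function(x, labels, subset, cost = 1, cv = cv_config()) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  y <- as.integer(as_vuln_factor(labels))
  if (is.numeric(cost) && !is.matrix(cost)) cost <- make_cost_matrix(cost)
  res <- cv_run(X[, subset, drop = FALSE], y, list(cost), cv,
                keep_predictions = TRUE)
  pred <- res$predictions[[1]]
  per_run <- lapply(seq_len(cv$repeats), function(r) {
    ok <- !is.na(pred[, r])
    conf <- confusion3(.classes[y[ok]], .classes[pred[ok, r]])
    suppressWarnings({
      bm_r <- binary_metrics(conf, "resilient")
      bm_v <- binary_metrics(conf, "vulnerable")
      c(accuracy = accuracy(conf), kappa = kappa3(conf),
        stats::setNames(bm_r, paste0("resilient_", names(bm_r))),
        stats::setNames(bm_v, paste0("vulnerable_", names(bm_v))))
    })
  })
  M <- do.call(rbind, per_run)
  summary <- data.frame(
    metric = colnames(M),
    mean = colMeans(M, na.rm = TRUE),
    sd = apply(M, 2, stats::sd, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(
    list(summary = summary, predictions = pred,
         modal = modal_assignment(pred),
         chance = chance_accuracy(tabulate(y, 3)),
         n_evaluated = res$n_evaluated, repeats = cv$repeats),
    class = "cv_metrics"
  )
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf("Cross-validated metrics (%d runs, %d participants; chance %.3f)\n",
              x$repeats, x$n_evaluated, x$chance))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-24s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Group lapse time courses
#'
#' Mean and standard error of the per-session 500-ms lapse counts at every
#' scheduled session time (days 2-4), within each assigned group. Used to
#' compare the time courses of predicted-vulnerable and predicted-resilient
#' groups across baseline and sleep deprivation.
#'
#' @param study a `pvt_study` object.
#' @param assignment named factor/character of group labels (names are
#'   participant ids), e.g. a [modal_assignment()] result named by
#'   participant.
#' @param threshold lapse threshold in ms (default 500).
#' @return A `data.frame` with `group`, `day`, `time_since_wake`,
#'   `mean_lapses`, `sem`, `n`.
#' @export
group_time_course <- function(study, assignment, threshold = 500) {
  ids <- names(assignment)
  assert_that(!is.null(ids), "assignment must be named by participant id")
  rows <- list()
  for (s in study$sessions) {
    g <- assignment[s$participant_id]
    if (is.na(g)) next
    tr <- s$trials
    keep <- tr$timeout == 0 & tr$rt_ms >= 100 & tr$button_ok == 1
    rows[[length(rows) + 1]] <- data.frame(
      group = as.character(g), day = s$day,
      time_since_wake = s$time_since_wake,
      lapses = lapse_count(tr$rt_ms[keep], threshold, sum(tr$timeout == 1)),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(lapses ~ group + day + time_since_wake, df,
                          function(v) c(mean = mean(v),
                                        sem = stats::sd(v) / sqrt(length(v)),
                                        n = length(v)))
  out <- data.frame(group = agg$group, day = agg$day,
                    time_since_wake = agg$time_since_wake,
                    mean_lapses = agg$lapses[, "mean"],
                    sem = agg$lapses[, "sem"], n = agg$lapses[, "n"],
                    stringsAsFactors = FALSE)
  out[order(out$group, out$day, out$time_since_wake), ]
}
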