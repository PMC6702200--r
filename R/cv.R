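# Repeated stratified k-fold cross-validation. Fold assignment is performed
# within each vulnerability group separately so the 1:2:1 group proportions
# stay constant across folds; prediction performance is averaged over
# repeated runs to reduce the variance of 5-fold cross-validation.

#' Cross-validation configuration
#'
#' @param folds number of folds (default 5).
#' @param repeats number of repeated CV runs (default 100; 10 is a useful
#'   fast setting).
#' @param seed master seed; each repeat uses a deterministic stream derived
#'   from it, so results are a pure function of (data, config, seed).
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(folds = 5, repeats = 100, seed = 1L) {
  assert_that(folds >= 2, "folds must be >= 2")
  assert_that(repeats >= 1, "repeats must be >= 1")
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Stratified fold assignment
#'
#' Within each class, members are shuffled and dealt round-robin into `k`
#' folds, so per-fold class counts differ from exact proportionality by at
#' most 1. With the 40/80/40 cohort and k = 5 every fold holds exactly
#' 8/16/8; with 15/30/15, exactly 3/6/3.
#'
#' @param labels vulnerability labels.
#' @param k number of folds.
#' @param seed integer seed for the shuffle.
#' @return Integer vector of fold ids (1..k), one per observation.
#' @export
stratified_folds <- function(labels, k, seed) {
  y <- as_vuln_factor(labels)
  counts <- table(y)
  if (any(counts[counts > 0] < k)) {
    stop("every represented class needs at least k members for k folds")
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      if (length(idx) == 0) next
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# One full repeated-CV pass for a fixed feature subset. Fits each fold model
# on the training folds only (z-scoring parameters included), scores the
# held-out fold, and applies the expected-cost decision rule for every cost
# matrix in `costs`. Returns per-repeat pooled accuracies (repeats x costs)
# and, optionally, the per-cost prediction arrays (n x repeats).
cv_run <- function(X, y, costs, cv, keep_predictions = FALSE) {
  n <- length(y)
  n_cost <- length(costs)
  acc <- matrix(NA_real_, cv$repeats, n_cost)
  preds <- if (keep_predictions) {
    lapply(seq_len(n_cost), function(i) matrix(NA_integer_, n, cv$repeats))
  } else NULL
  complete <- if (ncol(X) == 0) rep(TRUE, n) else stats::complete.cases(X)
  n_eval <- sum(complete)
  for (r in seq_len(cv$repeats)) {
    fold <- stratified_folds(.classes[y[complete]], cv$folds,
                             derive_seed(cv$seed, 811L, r))
    pred_r <- matrix(NA_integer_, n, n_cost)
    idx_c <- which(complete)
    for (f in seq_len(cv$folds)) {
      tr <- idx_c[fold != f]
      te <- idx_c[fold == f]
      core <- lda3_core(X[tr, , drop = FALSE], y[tr])
      post <- softmax_rows(lda3_scores(core, X[te, , drop = FALSE]))
      for (ci in seq_len(n_cost)) {
        pred_r[te, ci] <- decide_cost(post, costs[[ci]])
      }
    }
    acc[r, ] <- colSums(pred_r[idx_c, , drop = FALSE] == y[idx_c]) / n_eval
    if (keep_predictions) {
      for (ci in seq_len(n_cost)) preds[[ci]][, r] <- pred_r[, ci]
    }
  }
  list(accuracy = acc, predictions = preds, n_evaluated = n_eval,
       n_dropped = n - n_eval)
}

#' Cross-validated accuracy of a feature subset
#'
#' Scores a candidate feature subset by repeated stratified k-fold
#' cross-validation: in each repeat the model is fitted on four fifths of the
#' participants (z-scoring parameters estimated on training folds only, so
#' no information leaks from held-out folds), held-out predictions are
#' pooled, and the three-class accuracy is recorded. When several cost
#' matrices are supplied each is applied at decision time; fold models are
#' shared across costs.
#'
#' @param x feature matrix or data.frame (participants in rows, named
#'   columns).
#' @param labels vulnerability labels.
#' @param subset character vector of feature names (may be empty: the model
#'   then reduces to the class priors).
#' @param costs cost scalar(s) or list of 3x3 cost matrices (default 1).
#' @param cv a [cv_config()].
#' @param keep_predictions also return the per-cost n x repeats prediction
#'   arrays (labels as integers in canonical class order).
#' @return A list with `mean_accuracy` and `sd_accuracy` (one per cost),
#'   `accuracy` (repeats x costs matrix), `best_cost_index`, `n_dropped`
#'   (participants removed for missing subset features) and, optionally,
#'   `predictions`.
#' @export
evaluate_subset <- function(x, labels, subset, costs = 1, cv = cv_config(),
                            keep_predictions = FALSE) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  missing_cols <- setdiff(subset, colnames(X))
  if (length(missing_cols) > 0) {
    stop("unknown features in subset: ", paste(missing_cols, collapse = ", "))
  }
  y <- as.integer(as_vuln_factor(labels))
  if (!is.list(costs)) costs <- lapply(costs, make_cost_matrix)
  costs <- lapply(costs, check_cost_matrix)
  Xs <- if (length(subset) == 0) X[, 0, drop = FALSE]
        else X[, subset, drop = FALSE]
  res <- cv_run(Xs, y, costs, cv, keep_predictions = keep_predictions)
  if (res$n_dropped > 0) {
    message(res$n_dropped,
            " participant(s) dropped for missing features in this subset")
  }
  m <- colMeans(res$accuracy)
  list(mean_accuracy = m,
       sd_accuracy = apply(res$accuracy, 2, stats::sd),
       accuracy = res$accuracy,
       best_cost_index = which.max(m),
       n_dropped = res$n_dropped,
       predictions = res$predictions)
}
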