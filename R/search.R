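# Wrapper feature-subset selection: forward-selection best-first search over
# (feature subset x cost scalar), scored by mean cross-validated three-class
# accuracy. The search starts from the empty subset, always expands the
# highest-scoring unexpanded subset by adding every single unused candidate
# feature (each child is scored at every cost in the grid and keeps its best
# cost), and terminates after a fixed number of consecutive expansions with
# no strict improvement of the global best score.

#' Best-first wrapper search for a feature subset and cost matrix
#'
#' @param x feature matrix or data.frame with named columns.
#' @param labels vulnerability labels.
#' @param candidates character vector of candidate feature names (typically
#'   the ICC screen survivors).
#' @param cost_grid cost scalars evaluated jointly with each subset
#'   (default [cost_grid_default()], i.e. 1 to 5 in 0.5 steps).
#' @param cv a [cv_config()].
#' @param max_no_improve stop after this many consecutive expansions without
#'   strict improvement of the global best (default 5).
#' @param max_expansions hard cap on node expansions (default `Inf`).
#' @param beam_width keep at most this many unexpanded nodes (default `Inf`,
#'   i.e. pure best-first with an unbounded open list).
#' @return A list of class `bfs_search` with `subset` (best feature subset),
#'   `cost` (best cost scalar), `score` (its mean CV accuracy), `sd`
#'   (its SD over repeats), `trace` (a `data.frame` of every evaluation:
#'   `iteration`, `subset`, `cost`, `mean_acc`, `sd_acc`) and `expansions`.
#' @export
best_first_search <- function(x, labels, candidates,
                              cost_grid = cost_grid_default(),
                              cv = cv_config(),
                              max_no_improve = 5,
                              max_expansions = Inf,
                              beam_width = Inf) {
  assert_that(length(candidates) > 0, "candidates must be non-empty")
  X <- as.matrix(x)
  missing_cols <- setdiff(candidates, colnames(X))
  if (length(missing_cols) > 0) {
    stop("unknown candidate features: ", paste(missing_cols, collapse = ", "))
  }
  costs <- lapply(cost_grid, make_cost_matrix)

  evaluated <- new.env(parent = emptyenv()) # subset key -> TRUE
  subset_key <- function(subset) {
    if (length(subset) == 0) "(empty)" else paste(sort(subset), collapse = ";")
  }
  trace <- list()
  score_node <- function(subset, iteration) {
    ev <- evaluate_subset(X, labels, subset, costs = costs, cv = cv)
    ci <- ev$best_cost_index
    trace[[length(trace) + 1]] <<- data.frame(
      iteration = iteration,
      subset = paste(subset, collapse = ";"),
      cost = cost_grid[ci],
      mean_acc = ev$mean_accuracy[ci],
      sd_acc = ev$sd_accuracy[ci],
      stringsAsFactors = FALSE)
    list(subset = subset, cost = cost_grid[ci],
         score = ev$mean_accuracy[ci], sd = ev$sd_accuracy[ci])
  }

  root <- score_node(character(0), 0L)
  assign(subset_key(character(0)), TRUE, envir = evaluated)
  open <- list(root)
  best <- root
  no_improve <- 0L
  expansions <- 0L

  while (length(open) > 0 && no_improve < max_no_improve &&
         expansions < max_expansions) {
    scores <- vapply(open, `[[`, 0, "score")
    pick <- which.max(scores) # ties: first inserted (stable)
    node <- open[[pick]]
    open[[pick]] <- NULL
    expansions <- expansions + 1L
    improved <- FALSE
    for (f in setdiff(candidates, node$subset)) {
      child_subset <- c(node$subset, f)
      key <- subset_key(child_subset)
      if (isTRUE(get0(key, envir = evaluated))) next
      assign(key, TRUE, envir = evaluated)
      child <- score_node(child_subset, expansions)
      open[[length(open) + 1]] <- child
      if (child$score > best$score) {
        best <- child
        improved <- TRUE
      }
    }
    no_improve <- if (improved) 0L else no_improve + 1L
    if (is.finite(beam_width) && length(open) > beam_width) {
      keep <- order(vapply(open, `[[`, 0, "score"),
                    decreasing = TRUE)[seq_len(beam_width)]
      open <- open[sort(keep)]
    }
  }

  structure(
    list(subset = best$subset, cost = best$cost, score = best$score,
         sd = best$sd, trace = do.call(rbind, trace),
         expansions = expansions),
    class = "bfs_search"
  )
}

#' @export
print.bfs_search <- function(x, ...) {
  cat("Best-first wrapper search\n")
  cat(sprintf("  best subset (%d features): %s\n", length(x$subset),
              if (length(x$subset) == 0) "(empty)"
              else paste(x$subset, collapse = ", ")))
  cat(sprintf("  best cost scalar: %g; CV accuracy: %.3f +/- %.3f\n",
              x$cost, x$score, x$sd))
  cat(sprintf("  %d expansions, %d evaluations\n", x$expansions,
              nrow(x$trace)))
  invisible(x)
}

#' Fit the final model after feature selection
#'
#' Applies the selected feature subset and cost matrix to the entire
#' dataset, refitting the z-score parameters and discriminant coefficients
#' on all participants.
#'
#' @param x feature matrix or data.frame.
#' @param labels vulnerability labels.
#' @param search a [best_first_search()] result (or a list with `subset` and
#'   `cost`).
#' @param shrinkage passed to [lda3()].
#' @return An [lda3()] fit on the full data.
#' @export
fit_final <- function(x, labels, search, shrinkage = 0) {
  X <- as.matrix(x)
  if (length(search$subset) == 0) {
    return(lda3(X[, 0, drop = FALSE], labels,
                cost = make_cost_matrix(search$cost), shrinkage = shrinkage))
  }
  complete <- stats::complete.cases(X[, search$subset, drop = FALSE])
  lda3(X[complete, search$subset, drop = FALSE],
       labels[complete], cost = make_cost_matrix(search$cost),
       shrinkage = shrinkage)
}
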