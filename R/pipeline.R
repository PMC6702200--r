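# End-to-end orchestration: simulate (or ingest) -> session QC ->
# feature extraction -> stratification -> ICC screening -> wrapper search ->
# final per-time-point models -> evaluation. One discriminant model is
# developed per baseline time point, for the full cohort or the
# high-performer (<= 2 baseline lapses) subgroup.

#' Run the full classification pipeline
#'
#' @param protocol a [pvt_protocol()]; its `seed` drives the simulation.
#' @param n number of participants to simulate (ignored when `study` is
#'   given). Default 160.
#' @param study optional pre-built `pvt_study` (e.g. read from CSV).
#' @param catalog a [pvt_catalog()] (default: the full catalog).
#' @param time_points baseline times to model (default: the protocol's
#'   day-4 baseline times, 4-14 h).
#' @param cohort `"full"` or `"high_performer"` (the <= 2 mean baseline
#'   lapses subgroup, re-stratified within itself).
#' @param icc_threshold ICC screening threshold (default 0.60).
#' @param max_candidates cap on the number of screened candidates entering
#'   the wrapper search, keeping the highest-ICC features (default `Inf`).
#' @param cost_grid cost scalars searched jointly with feature subsets.
#' @param cv a [cv_config()]; its seed is re-derived per time point.
#' @param max_no_improve,max_expansions,beam_width search controls, see
#'   [best_first_search()].
#' @param out_dir optional directory for artifact files (labels, validity
#'   report, ICC tables, search traces, model JSONs, metrics and time-course
#'   CSVs).
#' @return An object of class `pvt_run`: a list with `labels`, `validity`,
#'   `selection`, `cohort_ids`, and per-time-point `models` (each holding
#'   `candidates`, `icc_table`, `search`, `final`, `metrics`, `modal`,
#'   `time_course`).
#' @export
run_pipeline <- function(protocol = pvt_protocol(), n = 160, study = NULL,
                         catalog = pvt_catalog(),
                         time_points = NULL,
                         cohort = c("full", "high_performer"),
                         icc_threshold = 0.60,
                         max_candidates = Inf,
                         cost_grid = cost_grid_default(),
                         cv = cv_config(),
                         max_no_improve = 5,
                         max_expansions = Inf,
                         beam_width = Inf,
                         out_dir = NULL) {
  cohort <- match.arg(cohort)
  if (is.null(time_points)) time_points <- baseline_times(protocol)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  if (is.null(study)) study <- simulate_study(n, protocol)
  validity <- validate_study(study)
  selection <- select_participants(study, validity,
                                   tsd_times = tsd_times(protocol))

  ids <- selection$included
  if (cohort == "high_performer") {
    ids <- select_high_performers(study, ids,
                                  baseline_times = baseline_times(protocol))
  }
  assert_that(length(ids) >= 8,
              "too few participants survive selection to stratify and fold")
  labels <- assign_labels(tsd_scores(study, ids, times = tsd_times(protocol)))

  # features only where needed: scheduled sessions at the modeled time points
  sub_study <- study
  sub_study$sessions <- Filter(function(s) {
    s$time_since_wake %in% time_points && s$participant_id %in% ids
  }, study$sessions)
  features <- compute_feature_table(sub_study, catalog, validity)

  lab_vec <- stats::setNames(as.character(labels$label),
                             labels$participant_id)

  models <- list()
  for (tt in time_points) {
    ft <- features[features$time_since_wake == tt, , drop = FALSE]
    cand <- screen_features(ft, threshold = icc_threshold)
    icc_tab <- attr(cand, "icc_table")
    cand <- as.character(cand)
    if (is.finite(max_candidates) && length(cand) > max_candidates) {
      icc_vals <- icc_tab$icc[match(cand, icc_tab$feature)]
      cand <- cand[order(icc_vals, decreasing = TRUE)][seq_len(max_candidates)]
    }
    day4 <- ft[ft$day == 4, , drop = FALSE]
    day4 <- day4[match(labels$participant_id, day4$participant_id), ,
                 drop = FALSE]
    X <- as.matrix(day4[, setdiff(names(day4),
                                  c("participant_id", "day",
                                    "time_since_wake")), drop = FALSE])
    rownames(X) <- labels$participant_id
    y <- lab_vec[labels$participant_id]
    cv_tt <- cv_config(cv$folds, cv$repeats,
                       derive_seed(cv$seed, 37L, round(tt * 10)))
    if (length(cand) == 0) {
      warning("no feature passed the ICC screen at ", tt,
              " h; skipping this time point", call. = FALSE)
      next
    }
    search <- best_first_search(X, y, cand, cost_grid = cost_grid,
                                cv = cv_tt, max_no_improve = max_no_improve,
                                max_expansions = max_expansions,
                                beam_width = beam_width)
    final <- fit_final(X, y, search)
    metrics <- cv_metrics(X, y, search$subset, cost = search$cost,
                          cv = cv_tt)
    modal <- stats::setNames(metrics$modal, labels$participant_id)
    tc <- group_time_course(study, modal)
    models[[as.character(tt)]] <- list(
      time_since_wake = tt, candidates = cand, icc_table = icc_tab,
      search = search, final = final, metrics = metrics, modal = modal,
      time_course = tc)

    if (!is.null(out_dir)) {
      pfx <- file.path(out_dir, sprintf("%s_t%02g", cohort, tt))
      utils::write.csv(icc_tab, paste0(pfx, "_icc.csv"), row.names = FALSE)
      utils::write.csv(search$trace, paste0(pfx, "_trace.csv"),
                       row.names = FALSE)
      lda3_to_json(final, paste0(pfx, "_model.json"))
      utils::write.csv(metrics$summary, paste0(pfx, "_metrics.csv"),
                       row.names = FALSE)
      utils::write.csv(tc, paste0(pfx, "_time_course.csv"),
                       row.names = FALSE)
    }
  }

  run <- structure(
    list(labels = labels, validity = validity, selection = selection,
         cohort = cohort, cohort_ids = ids, time_points = time_points,
         models = models, protocol = protocol),
    class = "pvt_run"
  )
  if (!is.null(out_dir)) {
    write_labels_csv(labels, file.path(out_dir, paste0(cohort, "_labels.csv")),
                     cohort = cohort)
    utils::write.csv(validity, file.path(out_dir, "validity.csv"),
                     row.names = FALSE)
    utils::write.csv(metrics_table(run),
                     file.path(out_dir, paste0(cohort, "_metrics_table.csv")),
                     row.names = FALSE)
  }
  run
}

#' Results-table summary of a pipeline run
#'
#' Arranges the cross-validated metrics as a table with one row per metric
#' and one column per baseline time point, each cell `mean +/- SD` over the
#' CV runs.
#'
#' @param run a [run_pipeline()] result.
#' @return A `data.frame`.
#' @export
metrics_table <- function(run) {
  cols <- lapply(run$models, function(m) {
    s <- m$metrics$summary
    pct <- s$metric != "kappa" # all rates as percentages, kappa on its own scale
    stats::setNames(
      ifelse(pct,
             sprintf("%.1f ± %.1f", 100 * s$mean, 100 * s$sd),
             sprintf("%.2f ± %.2f", s$mean, s$sd)),
      s$metric)
  })
  metrics <- names(cols[[1]])
  out <- data.frame(metric = metrics, stringsAsFactors = FALSE)
  for (nm in names(cols)) {
    out[[paste0(nm, "h")]] <- cols[[nm]][metrics]
  }
  out
}

#' @export
print.pvt_run <- function(x, ...) {
  cat(sprintf("PVT vulnerability pipeline run (%s cohort, %d participants)\n",
              x$cohort, length(x$cohort_ids)))
  cat(sprintf("  label counts: %s\n",
              paste(sprintf("%s=%d", levels(x$labels$label),
                            table(x$labels$label)), collapse = " ")))
  for (m in x$models) {
    acc <- m$metrics$summary
    a <- acc[acc$metric == "accuracy", ]
    k <- acc[acc$metric == "kappa", ]
    cat(sprintf("  %2g h: %d features, cost %g, accuracy %.1f%% +/- %.1f, kappa %.2f\n",
                m$time_since_wake, length(m$search$subset), m$search$cost,
                100 * a$mean, 100 * a$sd, k$mean))
  }
  invisible(x)
}
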