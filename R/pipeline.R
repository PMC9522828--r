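#' Run the full random-split validation protocol
#'
#' For each of `n_runs` seeded splits: re-derives the marker panels from the
#' tissue samples and that run's reserved reference noncancer plasma, builds
#' the four feature-profile views for the training and test plasma samples,
#' trains the stacked detection model (and, optionally, the
#' tissue-of-origin model on the training cancer plasma), scores the test
#' set, and computes AUROC, sensitivity at `n_fp` false positives, and TOO
#' accuracy/precision. Metrics are averaged across runs with 95% confidence
#' intervals; TOO confusion matrices are accumulated over runs.
#'
#' @param cohort `cfalpha_cohort` (or a list with `reads`, `meta`,
#'   `regions`).
#' @param n_runs independent random splits (default 10).
#' @param seed master seed.
#' @param params [discovery_params()].
#' @param tasks subset of `c("detection", "too")`.
#' @param reserve reference noncancer plasma per run (default 30).
#' @param test_frac test fraction (default 0.25).
#' @param n_fp allowed false positives for the sensitivity operating point.
#' @param C,n_trees,k_folds,conf_threshold model hyperparameters (see
#'   [train_stacked()]).
#' @return list of class `pipeline_result`: `runs` (per-run metric table),
#'   `summary` (mean + 95% CI per metric), `confusion` (accumulated TOO
#'   confusion), `scores` (per-run test detection scores), `splits`,
#'   `seed`.
#' @export
run_pipeline <- function(cohort, n_runs = 10, seed = 1,
                         params = discovery_params(),
                         tasks = c("detection", "too"),
                         reserve = 30, test_frac = 0.25, n_fp = 1,
                         C = 1, n_trees = 2000, k_folds = 5,
                         conf_threshold = 2.5) {
  tasks <- match.arg(tasks, several.ok = TRUE)
  meta <- as.data.table(cohort$meta)
  at <- build_distributions(cohort$reads, cohort$regions, params$min_cpg)
  raw_totals <- setNames(meta$raw_read_count, meta$sample_id)
  splits <- make_splits(meta, n_runs = n_runs, seed = seed,
                        test_frac = test_frac, reserve = reserve)
  run_rows <- list()
  score_rows <- list()
  confusion <- NULL
  for (sp in splits) {
    fams <- c(if ("detection" %in% tasks) "detection",
              if ("too" %in% tasks) "too", "tissue")
    panels <- build_marker_panels(
      at, meta, ref_samples = sp$reference_ids, params = params,
      regions = cohort$regions, seed = .subseed(seed, 400L + sp$run),
      families = fams)
    test_meta <- meta[sample_id %in% sp$test_ids]
    train_meta <- meta[sample_id %in% sp$train_ids]
    row <- list(run = sp$run)

    if ("detection" %in% tasks) {
      vt <- build_profile_views(at, train_meta$sample_id, panels,
                                raw_totals, "detection")
      mdl <- train_stacked(vt, train_meta$condition, task = "detection",
                           seed = .subseed(seed, 500L + sp$run), C = C,
                           n_trees = n_trees, k_folds = k_folds)
      vx <- build_profile_views(at, test_meta$sample_id, panels,
                                raw_totals, "detection")
      scores <- predict_detection(mdl, vx)
      is_cancer <- test_meta$condition == "cancer"
      row$auroc <- auroc(scores, is_cancer)
      sa <- sensitivity_at_fp(scores, is_cancer, n_fp = n_fp)
      row$sensitivity_at_fp <- sa$sensitivity
      row$specificity <- sa$specificity
      score_rows[[length(score_rows) + 1L]] <- data.table(
        run = sp$run, sample_id = test_meta$sample_id, score = scores,
        label = is_cancer, type = test_meta$type,
        threshold = sa$threshold)
    }

    if ("too" %in% tasks) {
      train_cancer <- train_meta[condition == "cancer"]
      test_cancer <- test_meta[condition == "cancer"]
      if (length(unique(train_cancer$type)) >= 2L &&
          nrow(test_cancer) > 0L) {
        vt <- build_profile_views(at, train_cancer$sample_id, panels,
                                  raw_totals, "too")
        mdl <- train_stacked(vt, train_cancer$type, task = "too",
                             seed = .subseed(seed, 600L + sp$run), C = C,
                             n_trees = n_trees, k_folds = k_folds,
                             conf_threshold = conf_threshold)
        vx <- build_profile_views(at, test_cancer$sample_id, panels,
                                  raw_totals, "too")
        pred <- predict_too(mdl, vx)
        tm <- too_metrics(pred, test_cancer$type,
                          classes = sort(unique(
                            meta[condition == "cancer"]$type)))
        row$too_accuracy <- tm$accuracy
        row$too_no_call_frac <- tm$n_no_call /
          (tm$n_called + tm$n_no_call)
        confusion <- if (is.null(confusion)) tm$confusion else
          confusion + tm$confusion
      } else {
        row$too_accuracy <- NA_real_
        row$too_no_call_frac <- NA_real_
      }
    }
    run_rows[[length(run_rows) + 1L]] <- as.data.table(row)
  }
  runs <- rbindlist(run_rows, fill = TRUE)
  structure(list(
    runs = runs,
    summary = if (nrow(runs) >= 2L) summarize_runs(runs) else NULL,
    confusion = confusion,
    scores = rbindlist(score_rows),
    splits = splits,
    seed = seed),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Random-split validation over", nrow(x$runs), "run(s)\n")
  if (!is.null(x$summary)) {
    print(x$summary)
  } else {
    print(x$runs)
  }
  if (!is.null(x$confusion)) {
    cat("\nAccumulated TOO confusion matrix (truth x call):\n")
    print(x$confusion)
  }
  invisible(x)
}

#' Write per-run and summary pipeline outputs as TSVs
#' @param result `pipeline_result`.
#' @param dir output directory.
#' @return invisibly `dir`.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(result$runs, file.path(dir, "run_metrics.tsv"), sep = "\t")
  if (!is.null(result$summary)) {
    fwrite(result$summary, file.path(dir, "summary.tsv"), sep = "\t")
  }
  if (nrow(result$scores) > 0L) {
    fwrite(result$scores, file.path(dir, "test_scores.tsv"), sep = "\t")
  }
  if (!is.null(result$confusion)) {
    cm <- as.data.table(as.data.frame.matrix(result$confusion),
                        keep.rownames = "truth")
    fwrite(cm, file.path(dir, "confusion.tsv"), sep = "\t")
  }
  invisible(dir)
}

#' Planted-DMR recovery of a discovered marker set
#'
#' Compares a discovered marker set against the simulator's planted truth
#' for the matching contrast: precision is the fraction of reported markers
#' that are planted, recall the fraction of planted regions recovered.
#'
#' @param marker_set discovered `marker_set`.
#' @param truth_regions character vector of planted region ids (same
#'   direction/contrast).
#' @return `list(precision, recall, n_found, n_true)`.
#' @export
recovery_metrics <- function(marker_set, truth_regions) {
  found <- marker_set$region_id
  tp <- sum(found %in% truth_regions)
  list(precision = if (length(found)) tp / length(found) else NA_real_,
       recall = if (length(truth_regions)) tp / length(truth_regions)
       else NA_real_,
       n_found = length(found), n_true = length(truth_regions))
}
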