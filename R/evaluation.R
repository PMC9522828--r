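.round_half_up <- function(x) floor(x + 0.5)

#' Random-split validation plans
#'
#' Implements the random-split protocol on the plasma cohort: per run, 25%
#' of cancer and 25% of noncancer plasma samples form the test set; from the
#' remaining noncancer samples, `reserve` (30 by default) are reserved
#' solely for marker discovery (reference noncancer plasma, re-drawn each
#' run); everything else trains the models. Counts are rounded half-up.
#'
#' @param meta metadata table; plasma rows with `condition` in
#'   `cancer`/`noncancer` are split.
#' @param n_runs number of independent splits (default 10).
#' @param seed integer seed.
#' @param test_frac test fraction (default 0.25).
#' @param reserve reference noncancer plasma count (default 30).
#' @return list of `split_plan`s: each
#'   `list(run, train_ids, test_ids, reference_ids, seed)`.
#' @export
make_splits <- function(meta, n_runs = 10, seed = 1, test_frac = 0.25,
                        reserve = 30) {
  meta <- as.data.table(meta)
  plasma <- meta[material == "plasma"]
  cancer <- plasma[condition == "cancer"]$sample_id
  noncancer <- plasma[condition == "noncancer"]$sample_id
  if (length(cancer) == 0L || length(noncancer) == 0L) {
    stop("cohort must contain cancer and noncancer plasma samples")
  }
  n_test_c <- .round_half_up(test_frac * length(cancer))
  n_test_n <- .round_half_up(test_frac * length(noncancer))
  if (length(noncancer) - n_test_n < reserve) {
    stop("too few noncancer samples to reserve ", reserve,
         " for marker discovery")
  }
  lapply(seq_len(n_runs), function(r) {
    set.seed(.subseed(seed, 300L + r))
    test <- c(sample(cancer, n_test_c), sample(noncancer, n_test_n))
    rest_n <- setdiff(noncancer, test)
    reference <- sample(rest_n, reserve)
    train <- setdiff(c(cancer, noncancer), c(test, reference))
    structure(list(run = r, train_ids = train, test_ids = test,
                   reference_ids = reference, seed = seed),
              class = "split_plan")
  })
}

#' Area under the ROC curve
#'
#' Computed with the rank (Mann-Whitney) formula; equals the probability
#' that a random positive scores above a random negative, counting ties as
#' one half.
#'
#' @param scores numeric prediction scores.
#' @param labels logical (or 0/1) vector, `TRUE` = positive.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUROC needs both positive and negative samples")
  }
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Sensitivity at a fixed number of false positives
#'
#' The ROC operating point allowing at most `n_fp` false positives: samples
#' scoring strictly above the `(n_fp + 1)`-th highest negative score are
#' called positive. With tie-free negative scores the specificity is exactly
#' `1 - n_fp / #negatives` (e.g. 47/48 = 97.9% for 48 negatives at 1 false
#' positive); ties straddling the cut are handled conservatively (the
#' achieved false-positive count, at most `n_fp`, is reported).
#'
#' @param scores numeric prediction scores.
#' @param labels logical vector, `TRUE` = positive (cancer).
#' @param n_fp allowed false positives (default 1).
#' @return `list(sensitivity, specificity, threshold, achieved_fp)`;
#'   positives are calls with `score > threshold`.
#' @export
sensitivity_at_fp <- function(scores, labels, n_fp = 1) {
  labels <- as.logical(labels)
  neg <- sort(scores[!labels], decreasing = TRUE)
  pos <- scores[labels]
  if (length(neg) < n_fp + 1L) {
    stop("need at least n_fp + 1 negative samples")
  }
  thr <- neg[n_fp + 1L]
  achieved_fp <- sum(neg > thr)
  list(sensitivity = mean(pos > thr),
       specificity = 1 - achieved_fp / length(neg),
       threshold = thr,
       achieved_fp = achieved_fp)
}

#' Tissue-of-origin metrics for one run
#'
#' Accuracy is computed over called samples (no-calls excluded); per-type
#' precision is the fraction of samples predicted as a type that truly are
#' that type; the confusion matrix is truth x call over called samples.
#'
#' @param predictions `data.table` from [predict_too()] (needs `call`).
#' @param truth character vector of true types, parallel to `predictions`.
#' @param classes fixed class universe for the confusion matrix (default:
#'   classes seen in `truth` or the calls).
#' @return `list(accuracy, precision, confusion, n_called, n_no_call)`;
#'   `accuracy` is `NA` (flagged) when nothing was called.
#' @export
too_metrics <- function(predictions, truth, classes = NULL) {
  call <- predictions$call
  truth <- as.character(truth)
  if (is.null(classes)) {
    classes <- sort(unique(c(truth, call[!is.na(call)])))
  }
  called <- !is.na(call)
  confusion <- table(factor(truth[called], levels = classes),
                     factor(call[called], levels = classes))
  names(dimnames(confusion)) <- c("truth", "call")
  if (!any(called)) {
    return(list(accuracy = NA_real_, precision = setNames(
      rep(NA_real_, length(classes)), classes),
      confusion = confusion, n_called = 0L, n_no_call = sum(!called)))
  }
  accuracy <- mean(call[called] == truth[called])
  pred_tot <- colSums(confusion)
  precision <- ifelse(pred_tot > 0, diag(confusion) / pred_tot, NA_real_)
  names(precision) <- classes
  list(accuracy = accuracy, precision = precision, confusion = confusion,
       n_called = sum(called), n_no_call = sum(!called))
}

#' Mean and 95% confidence interval of metrics across runs
#'
#' @param run_metrics `data.frame`/`data.table`, one row per run, numeric
#'   metric columns.
#' @param method `"percentile"` (2.5/97.5 empirical percentiles across
#'   runs, default) or `"normal"` (mean +/- 1.96 sd).
#' @return `data.table` with `metric`, `mean`, `ci_lo`, `ci_hi`.
#' @export
summarize_runs <- function(run_metrics, method = c("percentile", "normal")) {
  method <- match.arg(method)
  run_metrics <- as.data.table(run_metrics)
  num <- names(run_metrics)[vapply(run_metrics, is.numeric, TRUE)]
  num <- setdiff(num, "run")
  if (nrow(run_metrics) < 2L) stop("need at least 2 runs to summarise")
  rbindlist(lapply(num, function(m) {
    x <- run_metrics[[m]]
    x <- x[!is.na(x)]
    if (length(x) == 0L) {
      return(data.table(metric = m, mean = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_))
    }
    if (method == "percentile") {
      ci <- unname(quantile(x, c(0.025, 0.975), type = 7))
    } else {
      ci <- mean(x) + c(-1.96, 1.96) * sd(x)
    }
    data.table(metric = m, mean = mean(x), ci_lo = ci[1L], ci_hi = ci[2L])
  }))
}

#' Per-group sensitivity breakdown at a fixed threshold
#'
#' Used for per-stage and per-type sensitivity; a group's sensitivity is
#' reported only if its average number of test cancer patients per run is
#' at least `min_avg_n`.
#'
#' @param dt `data.table` with columns `run`, `group`, `score`, and the
#'   per-run `threshold` (from [sensitivity_at_fp()]).
#' @param min_avg_n minimum average group size per run (default 4).
#' @return `data.table` with `group`, `avg_n`, `sensitivity` (NA when the
#'   group is too small).
#' @export
sensitivity_by_group <- function(dt, min_avg_n = 4) {
  dt <- as.data.table(dt)
  n_runs <- length(unique(dt$run))
  out <- dt[, .(avg_n = .N / n_runs,
                sensitivity = mean(score > threshold)), by = "group"]
  out[avg_n < min_avg_n, sensitivity := NA_real_]
  out[]
}
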