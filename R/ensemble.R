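.fit_scaler <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2L, sd)
  s[!is.finite(s) | s == 0] <- 1
  list(center = mu, scale = s)
}

.apply_scaler <- function(X, sc) {
  sweep(sweep(X, 2L, sc$center, "-"), 2L, sc$scale, "/")
}

# binary linear SVM with oriented decision scores (higher = positive class)
.fit_lsvm <- function(X, y_pos, C) {
  yf <- factor(ifelse(y_pos, "pos", "neg"), levels = c("neg", "pos"))
  fit <- e1071::svm(X, yf, type = "C-classification", kernel = "linear",
                    cost = C, scale = FALSE)
  dv <- as.numeric(attr(predict(fit, X, decision.values = TRUE),
                        "decision.values"))
  flip <- if (mean(dv[y_pos]) < mean(dv[!y_pos])) -1 else 1
  list(fit = fit, flip = flip)
}

.score_lsvm <- function(m, X) {
  dv <- attr(predict(m$fit, X, decision.values = TRUE), "decision.values")
  as.numeric(dv) * m$flip
}

#' Train a level-1 linear SVM on one feature view
#'
#' One linear support vector machine (L2 penalty, cost `C = 1` by default)
#' per marker type, on per-feature standardised profiles. Binary mode
#' returns one oriented decision score (higher = positive class);
#' one-vs-rest mode fits one binary machine per class.
#'
#' @param X profile matrix (samples x markers), ideally carrying a
#'   `panel_hash` attribute.
#' @param labels class labels (length `nrow(X)`).
#' @param mode `"binary"` or `"ovr"` (one-vs-rest multiclass).
#' @param positive positive class for binary mode (default `"cancer"` when
#'   present, else the last sorted label).
#' @param C SVM cost parameter.
#' @return object of class `level1_model`.
#' @export
train_level1 <- function(X, labels, mode = c("binary", "ovr"),
                         positive = NULL, C = 1) {
  mode <- match.arg(mode)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("level-1 training needs at least 2 classes")
  X <- as.matrix(X)
  sc <- .fit_scaler(X)
  Xs <- .apply_scaler(X, sc)
  if (ncol(X) == 0L) {
    # a marker panel can come out empty (e.g. reference filtration removed
    # every candidate); the view then contributes a constant zero score
    if (is.null(positive)) {
      positive <- if ("cancer" %in% classes) "cancer" else tail(classes, 1L)
    }
    fits <- list()
    return(structure(list(mode = mode, classes = classes,
                          positive = positive, scaler = sc, fits = fits,
                          C = C, empty = TRUE,
                          panel_hash = attr(X, "panel_hash")),
                     class = "level1_model"))
  }
  if (mode == "binary") {
    if (is.null(positive)) {
      positive <- if ("cancer" %in% classes) "cancer" else tail(classes, 1L)
    }
    fits <- list(.fit_lsvm(Xs, labels == positive, C))
    names(fits) <- positive
  } else {
    fits <- lapply(classes, function(cl) .fit_lsvm(Xs, labels == cl, C))
    names(fits) <- classes
  }
  structure(list(mode = mode, classes = classes, positive = positive,
                 scaler = sc, fits = fits, C = C,
                 panel_hash = attr(X, "panel_hash")),
            class = "level1_model")
}

#' Decision scores of a level-1 model
#' @param model `level1_model`.
#' @param X profile matrix with the same columns as at training.
#' @return numeric matrix `samples x 1` (binary) or `samples x classes`
#'   (one-vs-rest).
#' @export
predict_level1 <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(model$panel_hash) && !is.null(attr(X, "panel_hash")) &&
      !identical(model$panel_hash, attr(X, "panel_hash"))) {
    stop("profile panel does not match the panel the model was trained on")
  }
  if (isTRUE(model$empty)) {
    k <- if (model$mode == "binary") 1L else length(model$classes)
    out <- matrix(0, nrow(X), k)
    colnames(out) <- if (model$mode == "binary") model$positive else
      model$classes
    rownames(out) <- rownames(X)
    return(out)
  }
  Xs <- .apply_scaler(X, model$scaler)
  out <- vapply(model$fits, function(m) .score_lsvm(m, Xs),
                numeric(nrow(Xs)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(Xs))
  colnames(out) <- names(model$fits)
  rownames(out) <- rownames(X)
  out
}

# stratified fold assignment; k reduced with a warning if a class is
# smaller than k
.make_folds <- function(labels, k, seed) {
  n <- length(labels)
  if (k >= n) return(seq_len(n))
  min_class <- min(table(labels))
  if (min_class < k) {
    warning("smallest class has ", min_class, " members; reducing folds")
    k <- max(2L, min_class)
  }
  folds <- integer(n)
  set.seed(.subseed(seed, 7L))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Cross-fitted level-1 outputs
#'
#' Every sample's level-1 output is produced by a model that never saw that
#' sample, so the level-2 learner is not exposed to level-1 training-set
#' optimism.
#'
#' @inheritParams train_level1
#' @param k_folds stratified folds (`k_folds >= nrow(X)` gives
#'   leave-one-out).
#' @param seed fold-assignment seed.
#' @param folds optional precomputed fold vector (shared across views).
#' @return matrix of out-of-fold scores, same shape as [predict_level1()].
#' @export
cross_fit_level1 <- function(X, labels, mode = c("binary", "ovr"),
                             positive = NULL, C = 1, k_folds = 5, seed = 1,
                             folds = NULL) {
  mode <- match.arg(mode)
  labels <- as.character(labels)
  X <- as.matrix(X)
  if (is.null(folds)) folds <- .make_folds(labels, k_folds, seed)
  ph <- attr(X, "panel_hash")
  ncol_out <- if (mode == "binary") 1L else length(sort(unique(labels)))
  out <- matrix(NA_real_, nrow(X), ncol_out)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    Xtr <- X[tr, , drop = FALSE]
    attr(Xtr, "panel_hash") <- ph
    m <- train_level1(Xtr, labels[tr], mode = mode, positive = positive,
                      C = C)
    Xte <- X[!tr, , drop = FALSE]
    attr(Xte, "panel_hash") <- ph
    sc <- predict_level1(m, Xte)
    if (ncol(sc) != ncol_out) {
      stop("a cross-fit fold lost a class; use fewer folds")
    }
    out[!tr, ] <- sc
  }
  colnames(out) <- if (mode == "binary") {
    if (is.null(positive) && "cancer" %in% labels) "cancer" else positive %||% tail(sort(unique(labels)), 1L)
  } else sort(unique(labels))
  rownames(out) <- rownames(X)
  out
}

.stack_features <- function(score_list) {
  Z <- do.call(cbind, lapply(names(score_list), function(v) {
    s <- score_list[[v]]
    colnames(s) <- paste(v, colnames(s), sep = ".")
    s
  }))
  Z
}

#' Train the two-level stacked ensemble
#'
#' Level 1: one linear SVM per feature view (binary for detection,
#' one-vs-rest for tissue-of-origin). Level 2: a random forest (2000 trees
#' by default) trained on the stacked cross-fitted level-1 outputs — the
#' signed decision score of each view for detection, each view's per-class
#' one-vs-rest scores for TOO (fitted as one forest per class).
#'
#' @param views named list of 4 profile matrices covering identical samples
#'   in identical order (e.g. from [build_profile_views()]).
#' @param labels class labels (detection: `cancer`/`noncancer`; TOO: cancer
#'   types).
#' @param task `"detection"` or `"too"`.
#' @param seed integer seed (folds and forest).
#' @param C level-1 SVM cost.
#' @param n_trees level-2 forest size.
#' @param k_folds stratified cross-fitting folds.
#' @param conf_threshold TOO confidence (top-2 probability fold change)
#'   below which no call is made.
#' @return object of class `stacked_model`.
#' @export
train_stacked <- function(views, labels, task = c("detection", "too"),
                          seed = 1, C = 1, n_trees = 2000, k_folds = 5,
                          conf_threshold = 2.5) {
  task <- match.arg(task)
  labels <- as.character(labels)
  rn <- lapply(views, rownames)
  if (length(unique(vapply(views, nrow, 0L))) != 1L ||
      (any(!vapply(rn, is.null, TRUE)) &&
       length(unique(rn[!vapply(rn, is.null, TRUE)])) != 1L)) {
    stop("the four views must cover identical samples in identical order")
  }
  mode <- if (task == "detection") "binary" else "ovr"
  positive <- if (task == "detection") {
    if ("cancer" %in% labels) "cancer" else tail(sort(unique(labels)), 1L)
  } else NULL
  folds <- .make_folds(labels, k_folds, seed)
  level1 <- lapply(views, train_level1, labels = labels, mode = mode,
                   positive = positive, C = C)
  oof <- lapply(views, cross_fit_level1, labels = labels, mode = mode,
                positive = positive, C = C, folds = folds, seed = seed)
  Z <- .stack_features(oof)
  classes <- sort(unique(labels))
  if (task == "detection") {
    yf <- factor(labels, levels = c(setdiff(classes, positive), positive))
    set.seed(.subseed(seed, 991L))
    level2 <- randomForest::randomForest(Z, yf, ntree = n_trees)
  } else {
    level2 <- lapply(seq_along(classes), function(ci) {
      yf <- factor(ifelse(labels == classes[ci], "yes", "no"),
                   levels = c("no", "yes"))
      set.seed(.subseed(seed, 900L + ci))
      randomForest::randomForest(Z, yf, ntree = n_trees)
    })
    names(level2) <- classes
  }
  structure(list(task = task, level1 = level1, level2 = level2,
                 classes = classes, positive = positive,
                 view_names = names(views),
                 panel_hashes = lapply(views, attr, "panel_hash"),
                 params = list(C = C, n_trees = n_trees, k_folds = k_folds,
                               conf_threshold = conf_threshold),
                 seed = seed),
            class = "stacked_model")
}

.check_views <- function(model, views) {
  if (!identical(sort(names(views)), sort(model$view_names))) {
    stop("view names do not match the trained model")
  }
  for (v in model$view_names) {
    hm <- model$panel_hashes[[v]]
    hx <- attr(views[[v]], "panel_hash")
    if (!is.null(hm) && !is.null(hx) && !identical(hm, hx)) {
      stop("panel hash mismatch for view ", v,
           ": profiles were built against a different marker panel")
    }
  }
  invisible(TRUE)
}

.level2_features <- function(model, views) {
  sc <- lapply(model$view_names, function(v)
    predict_level1(model$level1[[v]], views[[v]]))
  names(sc) <- model$view_names
  .stack_features(sc)
}

#' Cancer-detection probability of the stacked ensemble
#'
#' @param model `stacked_model` trained with `task = "detection"`.
#' @param views named list of the 4 profile matrices for the samples to
#'   score.
#' @return numeric vector in `[0, 1]`: the forest's probability of the
#'   cancer class (thresholding is the evaluator's job).
#' @export
predict_detection <- function(model, views) {
  stopifnot(model$task == "detection")
  .check_views(model, views)
  Z <- .level2_features(model, views)
  pr <- predict(model$level2, Z, type = "prob")
  unname(pr[, model$positive])
}

#' Tissue-of-origin prediction with confidence gating
#'
#' One-vs-rest membership probabilities are normalised to sum to 1; the top
#' class is called only when the confidence — the fold change between the
#' highest and second-highest membership probability — reaches the model's
#' threshold (2.5 by default).
#'
#' @param model `stacked_model` trained with `task = "too"`.
#' @param views named list of the 4 profile matrices.
#' @return `data.table` with one row per sample: per-class probabilities,
#'   `top_type`, `confidence`, `call` (`NA` when below threshold).
#' @export
predict_too <- function(model, views) {
  stopifnot(model$task == "too")
  .check_views(model, views)
  Z <- .level2_features(model, views)
  raw <- vapply(model$classes, function(cl)
    predict(model$level2[[cl]], Z, type = "prob")[, "yes"],
    numeric(nrow(Z)))
  if (!is.matrix(raw)) raw <- matrix(raw, nrow = nrow(Z),
                                     dimnames = list(NULL, model$classes))
  s <- rowSums(raw)
  probs <- raw / ifelse(s > 0, s, 1)
  probs[s == 0, ] <- 1 / length(model$classes)
  calls <- lapply(seq_len(nrow(probs)), function(i)
    too_call(probs[i, ], model$params$conf_threshold))
  out <- as.data.table(probs)
  out[, `:=`(
    sample_id = rownames(Z) %||% as.character(seq_len(nrow(probs))),
    top_type = vapply(calls, `[[`, "", "top_type"),
    confidence = vapply(calls, `[[`, 0, "confidence"),
    call = vapply(calls, function(x) x$call %||% NA_character_, ""))]
  setcolorder(out, c("sample_id"))
  out[]
}

#' Confidence-gated tissue-of-origin call from membership probabilities
#'
#' @param probs named per-class membership probabilities (sum 1).
#' @param threshold confidence threshold (default 2.5).
#' @return `list(top_type, confidence, call)`; `confidence` is
#'   `p(1st) / p(2nd)` (`Inf` when the runner-up probability is 0, 1 on a
#'   top-2 tie); `call` is `NULL` below threshold.
#' @export
too_call <- function(probs, threshold = 2.5) {
  stopifnot(length(probs) >= 2L, all(probs >= 0),
            abs(sum(probs) - 1) < 1e-6)
  ord <- order(probs, decreasing = TRUE)
  p1 <- probs[ord[1L]]; p2 <- probs[ord[2L]]
  confidence <- if (p2 == 0) Inf else unname(p1 / p2)
  top_type <- names(probs)[ord[1L]] %||% as.character(ord[1L])
  list(top_type = top_type, confidence = confidence,
       call = if (confidence >= threshold) top_type else NULL)
}
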