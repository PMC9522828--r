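test_that("a linear SVM separates separable blobs and scores deterministically", {
  set.seed(8)
  d <- 10; n <- 40
  X <- rbind(matrix(rnorm(n / 2 * d, mean = 2), n / 2, d),
             matrix(rnorm(n / 2 * d, mean = -2), n / 2, d))
  y <- rep(c("cancer", "noncancer"), each = n / 2)
  m <- train_level1(X, y, positive = "cancer")
  s <- predict_level1(m, X)[, 1]
  expect_equal(mean((s > 0) == (y == "cancer")), 1)  # training accuracy 1
  # duplicating every sample leaves decision scores identical
  s2 <- predict_level1(m, rbind(X, X))[, 1]
  expect_equal(s2, c(s, s))
  expect_error(train_level1(X, rep("cancer", n)), "2 classes")
})

test_that("permuted labels give chance-level cross-validated discrimination", {
  aucs <- vapply(1:20, function(r) {
    set.seed(100 + r)
    X <- matrix(rnorm(60 * 8), 60, 8)
    y <- sample(rep(c("cancer", "noncancer"), each = 30))
    oof <- cross_fit_level1(X, y, positive = "cancer", k_folds = 5,
                            seed = r)
    auroc(oof[, 1], y == "cancer")
  }, 0)
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})

test_that("cross-fitting is seeded, supports leave-one-out, and curbs optimism", {
  set.seed(9)
  X <- matrix(rnorm(6 * 4), 6, 4)
  y <- rep(c("a", "b"), 3)
  oof <- cross_fit_level1(X, y, positive = "b", k_folds = 6, seed = 2)
  expect_equal(dim(oof), c(6L, 1L))
  oof2 <- cross_fit_level1(X, y, positive = "b", k_folds = 6, seed = 2)
  expect_identical(oof, oof2)
  # on pure noise, in-sample scores separate but out-of-fold scores do not
  set.seed(10)
  Xn <- matrix(rnorm(40 * 50), 40, 50)  # p > n: heavy overfit potential
  yn <- rep(c("cancer", "noncancer"), each = 20)
  m <- train_level1(Xn, yn, positive = "cancer")
  in_auc <- auroc(predict_level1(m, Xn)[, 1], yn == "cancer")
  oof_auc <- auroc(cross_fit_level1(Xn, yn, positive = "cancer",
                                    k_folds = 5, seed = 3)[, 1],
                   yn == "cancer")
  expect_gt(in_auc, 0.95)
  expect_lt(oof_auc, in_auc - 0.1)
})

test_that("stacked training is deterministic and rejects mismatched views", {
  mv <- make_multiview(1, n_train = 40, n_test = 40)
  labs <- ifelse(mv$y_train, "cancer", "noncancer")
  m1 <- train_stacked(mv$train, labs, task = "detection", seed = 5,
                      n_trees = 300)
  m2 <- train_stacked(mv$train, labs, task = "detection", seed = 5,
                      n_trees = 300)
  p1 <- predict_detection(m1, mv$test)
  p2 <- predict_detection(m2, mv$test)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  bad <- mv$train
  bad[[1]] <- bad[[1]][-1, , drop = FALSE]
  expect_error(train_stacked(bad, labs, task = "detection"),
               "identical samples")
})

test_that("detection scores track the class signal end to end", {
  co <- small_cohort()
  at <- small_alpha_table()
  meta <- as.data.frame(co$meta)
  plasma <- meta[meta$material == "plasma", ]
  refs <- plasma[plasma$condition == "noncancer", "sample_id"][1:10]
  rest <- plasma[!plasma$sample_id %in% refs, ]
  test_ids <- c(rest[rest$condition == "cancer", "sample_id"][1:8],
                rest[rest$condition == "noncancer", "sample_id"][1:8])
  train <- rest[!rest$sample_id %in% test_ids, ]
  panels <- build_marker_panels(at, co$meta, ref_samples = refs,
                                regions = co$regions, seed = 5)
  rt <- setNames(co$meta$raw_read_count, co$meta$sample_id)
  vt <- build_profile_views(at, train$sample_id, panels, rt, "detection")
  mdl <- suppressWarnings(train_stacked(vt, train$condition,
                                        task = "detection", seed = 6,
                                        n_trees = 500))
  vx <- build_profile_views(at, test_ids, panels, rt, "detection")
  sc <- predict_detection(mdl, vx)
  truth <- test_ids %in% plasma[plasma$condition == "cancer", "sample_id"]
  expect_gt(auroc(sc, truth), 0.8)
  expect_gt(mean(sc[truth]), mean(sc[!truth]))
  # panel mismatch is caught
  vbad <- vx
  attr(vbad$cancer_hyper, "panel_hash") <- "deadbeef"
  expect_error(predict_detection(mdl, vbad), "panel hash")
})

test_that("the TOO call rule is exact on enumerated probability vectors", {
  p <- c(colon = 0.6, liver = 0.2, lung = 0.15, stomach = 0.05)
  cl <- too_call(p)
  expect_equal(cl$confidence, 3)
  expect_equal(cl$call, "colon")
  cl2 <- too_call(c(a = 0.4, b = 0.3, c = 0.2, d = 0.1))
  expect_equal(cl2$confidence, 4 / 3, tolerance = 1e-12)
  expect_null(cl2$call)
  cl3 <- too_call(c(a = 1, b = 0, c = 0, d = 0))
  expect_equal(cl3$confidence, Inf)
  expect_equal(cl3$call, "a")
  # top-2 tie -> confidence 1 -> no call
  cl4 <- too_call(c(a = 0.5, b = 0.5))
  expect_equal(cl4$confidence, 1)
  expect_null(cl4$call)
  # exhaustive sweep over a simplex grid: call iff p1/p2 >= 2.5
  step <- 0.05
  for (p1 in seq(step, 1, step)) for (p2 in seq(0, 1 - p1, step)) {
    p3 <- round(1 - p1 - p2, 10)
    if (p3 < 0 || p2 < p3) next
    pr <- sort(c(p1, p2, p3), decreasing = TRUE)
    names(pr) <- c("x", "y", "z")
    cl <- too_call(pr)
    expect_equal(cl$confidence >= 2.5, !is.null(cl$call))
    expect_gte(cl$confidence, 1)
  }
})

test_that("TOO predictions carry normalised probabilities and gated calls", {
  mv <- make_multiview(2, n_train = 60, n_test = 24)
  types <- rep(c("colon", "liver", "lung"), length.out = 60)
  # inject per-class structure so one-vs-rest has something to learn
  for (v in seq_along(mv$train)) {
    mv$train[[v]][types == "liver", 1:2] <-
      mv$train[[v]][types == "liver", 1:2] + 2
  }
  mdl <- suppressWarnings(train_stacked(mv$train, types, task = "too",
                                        seed = 4, n_trees = 300))
  pred <- predict_too(mdl, mv$test)
  pr <- as.matrix(pred[, c("colon", "liver", "lung")])
  expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-9)
  expect_true(all(pred$confidence >= 1))
  expect_equal(!is.na(pred$call), pred$confidence >= 2.5)
})
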