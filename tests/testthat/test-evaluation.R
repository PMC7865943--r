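# metrics, printed-table reconstruction, baselines, protocols

test_that("evaluate agrees with a brute-force count on random labels", {
  set.seed(1)
  for (i in 1:100) {
    C <- sample(2:6, 1)
    n <- sample(10:60, 1)
    classes <- paste0("k", seq_len(C))
    yt <- sample(classes, n, replace = TRUE)
    yp <- sample(classes, n, replace = TRUE)
    ev <- evaluate(yt, yp, classes = classes)
    # brute force: count every (true, pred) pair with loops
    cnt <- matrix(0L, C, C, dimnames = list(classes, classes))
    for (j in seq_len(n))
      cnt[yt[j], yp[j]] <- cnt[yt[j], yp[j]] + 1L
    expect_identical(unname(ev$counts), unname(cnt))
    expect_equal(ev$accuracy, 100 * sum(diag(cnt)) / n,
                 tolerance = 1e-12)
    prec <- rec <- fm <- numeric(C)
    for (c in seq_len(C)) {
      tp <- cnt[c, c]; fp <- sum(cnt[, c]) - tp; fn <- sum(cnt[c, ]) - tp
      prec[c] <- if (tp + fp > 0) tp / (tp + fp) else 0
      rec[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
      fm[c] <- if (prec[c] + rec[c] > 0)
        2 * prec[c] * rec[c] / (prec[c] + rec[c]) else 0
    }
    expect_equal(ev$precision, 100 * mean(prec), tolerance = 1e-12)
    expect_equal(ev$recall, 100 * mean(rec), tolerance = 1e-12)
    expect_equal(ev$f_measure, 100 * mean(fm), tolerance = 1e-12)
  }
})

test_that("metric identities: macro recall vs diagonal, accuracy weights", {
  set.seed(2)
  classes <- har_activities()
  yt <- sample(classes, 140, replace = TRUE)
  yp <- sample(classes, 140, replace = TRUE)
  ev <- evaluate(yt, yp)
  expect_equal(ev$recall, mean(diag(ev$percent)), tolerance = 1e-10)
  w <- rowSums(ev$counts) / sum(ev$counts)
  expect_equal(ev$accuracy, sum(w * diag(ev$percent)), tolerance = 1e-10)
  # perfect predictions: all four indicators are 100
  evp <- evaluate(yt, yt)
  expect_equal(c(evp$accuracy, evp$precision, evp$recall, evp$f_measure),
               rep(100, 4))
})

test_that("a class never predicted scores zero precision, not NaN", {
  ev <- evaluate(c("a", "a", "b"), c("b", "b", "b"),
                 classes = c("a", "b"))
  expect_identical(ev$per_class$precision[1], 0)
  expect_false(anyNA(ev$per_class))
})

test_that("label vectors rebuilt from a row-percent matrix rescore it", {
  pct <- rbind(c(80, 20), c(10, 90))
  rownames(pct) <- colnames(pct) <- c("u", "v")
  lv <- labels_from_confusion(pct, n_per_class = 10)
  ev <- evaluate(lv$y_true, lv$y_pred, classes = c("u", "v"))
  expect_equal(unname(ev$percent), unname(pct))
  expect_error(labels_from_confusion(rbind(c(85, 15), c(10, 90)), 10),
               "not consistent")
})

test_that("1-NN returns the label of an exactly matching training point", {
  set.seed(3)
  X <- matrix(rnorm(5 * 8), 5, 8)
  y <- paste0("c", 1:8)
  pred <- knn_classify(X, y, X[, 3, drop = FALSE], k = 1)
  expect_identical(pred, "c3")
})

test_that("every baseline kind learns an easy split", {
  set.seed(4)
  n <- 60
  y <- rep(c("p", "q"), each = n / 2)
  X <- matrix(rnorm(6 * n), 6, n)
  X[1, y == "q"] <- X[1, y == "q"] + 6
  Xtest <- matrix(rnorm(6 * 20), 6, 20)
  ytest <- rep(c("p", "q"), each = 10)
  Xtest[1, ytest == "q"] <- Xtest[1, ytest == "q"] + 6
  for (kind in c("knn", "svm", "tree")) {
    pred <- baseline_fit_predict(kind, X, y, Xtest)
    expect_gte(mean(pred == ytest), 0.9)
  }
})

test_that("OS protocol only ever reads target labels for scoring", {
  co <- small_cohort(n_subjects = 2, difficulty = 0.5,
                     segments_per_class = 6)
  src <- co$features[[1]]; tgt <- co$features[[2]]
  scrambled <- tgt
  scrambled$y <- sample(tgt$y)
  p1 <- baseline_protocol("knn", "OS", src, tgt)
  p2 <- baseline_protocol("knn", "OS", src, scrambled)
  expect_identical(p1, p2)
})

test_that("SS protocol partitions 70 segments into 10 stratified folds", {
  y <- rep(har_activities(), each = 10)
  fold <- ipljpda:::.stratified_folds(y, 10, seed = 1)
  expect_identical(sort(unique(fold)), 1:10)
  expect_identical(as.vector(table(fold)), rep(7L, 10))
  # within every class each fold appears exactly once
  for (cl in har_activities())
    expect_identical(sort(fold[y == cl]), 1:10)
  # fewer segments than folds: fold count is reduced with a message
  y2 <- rep(c("SIT", "RUN"), each = 4)
  expect_message(f2 <- ipljpda:::.stratified_folds(y2, 10, seed = 1),
                 "reducing folds")
  expect_identical(max(f2), 4L)
})

test_that("SS protocol predicts every probe segment out of fold", {
  co <- small_cohort(n_subjects = 2, difficulty = 0,
                     segments_per_class = 10)
  probe <- select_target_segments(co$features[[2]], per_class = 10,
                                  seed = 2)
  pred <- baseline_protocol("knn", "SS", target_features = probe,
                            seed = 3)
  expect_identical(length(pred), 70L)
  expect_gte(mean(pred == probe$y), 0.9)   # self-data is easy at no shift
})

test_that("a target subject contributes 10 segments per class (70 total)", {
  co <- small_cohort(n_subjects = 2, difficulty = 1,
                     segments_per_class = 12)
  probe <- select_target_segments(co$features[[1]], per_class = 10,
                                  seed = 7)
  expect_identical(ncol(probe$X), 70L)
  expect_identical(as.vector(table(probe$y)), rep(10L, 7))
  # deterministic under the seed
  probe2 <- select_target_segments(co$features[[1]], per_class = 10,
                                   seed = 7)
  expect_identical(probe$X, probe2$X)
  expect_error(select_target_segments(co$features[[1]], per_class = 13),
               "only 12")
})

test_that("group experiment has the benchmark-table shape and is seeded", {
  co <- small_cohort(n_subjects = 4, difficulty = 0.5,
                     segments_per_class = 10)
  ex <- run_group_experiment(co$cohort, n_source = 3, per_class = 10,
                             models = c("knn-os", "ipl-jpda"),
                             seed = 5, T_iter = 2)
  expect_identical(nrow(ex$table), 2L)
  expect_identical(names(ex$table),
                   c("model", "accuracy", "f_measure", "precision",
                     "recall"))
  expect_identical(length(ex$source_subjects), 3L)
  expect_identical(length(ex$target_subjects), 1L)
  ex2 <- run_group_experiment(co$cohort, n_source = 3, per_class = 10,
                              models = c("knn-os", "ipl-jpda"),
                              seed = 5, T_iter = 2)
  expect_identical(ex$table, ex2$table)
  expect_error(run_group_experiment(co$cohort, n_source = 4), "at least")
})

test_that("source-size sweep returns one mean/sd pair per size", {
  co <- small_cohort(n_subjects = 4, difficulty = 0.5,
                     segments_per_class = 10)
  sw <- run_source_size_sweep(co$cohort, sizes = 1:2,
                              combos_per_size = 2, n_test_targets = 1,
                              seed = 6, T_iter = 2)
  expect_identical(nrow(sw), 2L)
  expect_identical(names(sw), c("size", "mean_accuracy", "sd_accuracy"))
  expect_true(all(is.finite(sw$mean_accuracy)))
})
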