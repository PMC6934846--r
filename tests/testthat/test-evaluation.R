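test_that("weighted F1 matches hand-computed values", {
  expect_equal(weighted_f1(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  y_true <- c(1, 1, 1, 0, 0, 0)
  y_pred <- c(1, 1, 0, 0, 0, 1)
  expect_equal(weighted_f1(y_true, y_pred), 2 / 3)
  expect_equal(weighted_f1(y_true, y_pred, variant = "literal_eq10"), 4 / 9)
  # degenerate prediction: F1 for the missed class is 0
  expect_equal(weighted_f1(c("a", "a", "b", "b"), rep("a", 4)),
               0.5 * (2 * 0.5 * 1 / 1.5) + 0)
  expect_error(weighted_f1(c(1, 2), c(1)), "differ")
})

test_that("weighted F1 is invariant under consistent label renaming", {
  set.seed(41)
  for (i in 1:20) {
    y <- sample(c("a", "b", "c"), 30, replace = TRUE)
    p <- sample(c("a", "b", "c"), 30, replace = TRUE)
    map <- c(a = "x", b = "y", c = "z")
    expect_equal(weighted_f1(map[y], map[p]), weighted_f1(y, p))
    f <- weighted_f1(y, p)
    expect_gte(f, 0); expect_lte(f, 1)
  }
})

test_that("stratified folds preserve class proportions within one", {
  labels <- rep(c("case", "ctl"), each = 30)
  folds <- stratified_kfold(labels, k = 10, seed = 3)
  expect_equal(attr(folds, "k"), 10L)
  for (i in 1:10) {
    expect_equal(sum(folds == i & labels == "case"), 3L)
    expect_equal(sum(folds == i & labels == "ctl"), 3L)
  }
  # partition: every index in exactly one fold
  expect_equal(sort(unique(folds)), 1:10)
  expect_length(folds, 60L)

  expect_identical(stratified_kfold(labels, 10, seed = 3), folds)
  expect_false(identical(stratified_kfold(labels, 10, seed = 4), folds))

  expect_warning(small <- stratified_kfold(c("a", "a", "b", "b", "b"), 3),
                 "reducing k")
  expect_equal(attr(small, "k"), 2L)
  expect_error(stratified_kfold(c("a", "b"), 5), "more folds")
})

test_that("cross-validation separates separable clusters perfectly", {
  set.seed(51)
  x <- rbind(matrix(rnorm(100, 0), ncol = 2),
             matrix(rnorm(100, 8), ncol = 2))
  y <- rep(c("a", "b"), each = 50)
  for (clf in c("k_nearest_neighbours", "gaussian_naive_bayes",
                "decision_tree")) {
    res <- cross_validate(x, y, classifier = clf, k = 10, seed = 2)
    expect_s3_class(res, "kmotif_eval")
    expect_equal(res$mean, 1)
    expect_equal(res$mean, mean(res$fold_scores))
    expect_equal(res$sd, sd(res$fold_scores))
    expect_length(res$fold_scores, 10L)
  }
})

test_that("random features score near chance for balanced labels", {
  set.seed(61)
  means <- replicate(10, {
    x <- matrix(rnorm(200 * 4), ncol = 4)
    y <- rep(c("a", "b"), 100)
    cross_validate(x, y, "k_nearest_neighbours", k = 10,
                   seed = sample.int(1e6, 1))$mean
  })
  expect_gt(mean(means), 0.35)
  expect_lt(mean(means), 0.65)
})

test_that("the MLP classifier plugs into the harness", {
  set.seed(71)
  x <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 6), ncol = 2))
  y <- rep(c("a", "b"), each = 30)
  res <- cross_validate(x, y, "multilayer_perceptron", k = 5, seed = 2)
  expect_gte(res$mean, 0.9)
})

test_that("baseline feature methods reduce segments as documented", {
  segs <- trajectory_set(list(
    trajectory(c(0, 2), c(1, 1), class_label = "a", session_id = "s1"),
    trajectory(c(5, 5, 5), c(1, 2, 3), class_label = "b", session_id = "s2")))
  mv <- baseline_features(segs, "means_variances")
  expect_equal(unname(mv["s1", ]), c(1, 1, 1, 0))
  expect_equal(unname(mv["s2", c("mean_x", "var_x")]), c(5, 0))

  fd <- baseline_features(segs, "full_data")
  expect_equal(dim(fd), c(2L, 4L))  # truncated to the 2-frame minimum
  expect_equal(unname(fd["s1", ]), c(0, 2, 1, 1))
})

test_that("folds cannot be stratified over a single-member class", {
  expect_error(suppressWarnings(
    stratified_kfold(c(rep("a", 5), "b"), k = 2)), "fewer than 2")
})
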