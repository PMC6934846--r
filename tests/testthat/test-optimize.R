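test_that("per-subject holdout split matches the 90/10 protocol", {
  # 10 sessions x 3 segments per subject = 30 segments each
  subs <- paste0("rat", 1:4)
  segs <- unlist(lapply(subs, function(s)
    lapply(1:30, function(i)
      trajectory(1:10, 1:10, subject_id = s,
                 session_id = paste0(s, "_", i),
                 class_label = if (s %in% subs[1:2]) "case" else "ctl"))),
    recursive = FALSE)
  data <- trajectory_set(segs)
  sp <- split_holdout(data, fraction = 0.10, seed = 9)
  hold_subj <- vapply(sp$holdout$trajectories, function(t) t$subject_id,
                      character(1))
  expect_equal(as.integer(table(hold_subj)[subs]), rep(3L, 4))
  expect_length(sp$dev, 108L)
  # partition: no segment in both, all segments somewhere
  ids <- function(ts) vapply(ts$trajectories, function(t) t$session_id,
                             character(1))
  expect_length(intersect(ids(sp$dev), ids(sp$holdout)), 0L)
  expect_setequal(c(ids(sp$dev), ids(sp$holdout)), ids(data))

  expect_error(split_holdout(data, 0), "between 0 and 1")
  expect_error(split_holdout(data, 1), "between 0 and 1")
})

test_that("hill-climbing finds the optimum of a concave objective", {
  obj <- function(w, alpha, k, measure)
    -(w - 10)^2 - (alpha - 5)^2 - (k - 3)^2
  space <- list(w = c(5L, 15L), alpha = c(2L, 8L), k = c(1L, 6L),
                measures = "I2")
  for (seed in 1:3) {
    res <- hill_climb(obj, space, seed = seed, restarts = 2)
    expect_equal(res$best_params[c("w", "alpha", "k")],
                 list(w = 10, alpha = 5, k = 3))
    expect_equal(res$inner_score, 0)
  }
})

test_that("climb traces are strictly improving and reproducible", {
  set.seed(99)
  noisy <- local({
    vals <- array(runif(6 * 6 * 6), c(6, 6, 6))
    function(w, alpha, k, measure) vals[w, alpha, k]
  })
  space <- list(w = c(1L, 6L), alpha = c(1L, 6L), k = c(1L, 6L),
                measures = c("I1", "I2"))
  r1 <- hill_climb(noisy, space, seed = 5, restarts = 3)
  r2 <- hill_climb(noisy, space, seed = 5, restarts = 3)
  expect_identical(r1$best_params, r2$best_params)
  expect_identical(r1$trace, r2$trace)
  for (cl in unique(r1$trace$climb)) {
    sc <- r1$trace$score[r1$trace$climb == cl]
    if (length(sc) > 1) expect_true(all(diff(sc) > 0))
  }
  expect_equal(r1$inner_score, max(r1$trace$score))
})

test_that("on a tiny unimodal grid the climb matches exhaustive search", {
  # unimodal: negative distance to a peak inside a 3x3x3 grid
  obj <- function(w, alpha, k, measure)
    -abs(w - 2) - abs(alpha - 3) - abs(k - 1)
  space <- list(w = c(1L, 3L), alpha = c(1L, 3L), k = c(1L, 3L),
                measures = "I1")
  res <- hill_climb(obj, space, seed = 1, restarts = 2)
  grid <- expand.grid(w = 1:3, alpha = 1:3, k = 1:3)
  grid_max <- max(mapply(obj, grid$w, grid$alpha, grid$k, "I1"))
  expect_equal(res$inner_score, grid_max)
  expect_lte(res$inner_score, grid_max)
})

test_that("the full tuning loop runs end to end on a small cohort", {
  cohort <- tiny_cohort(n_per_class = 2, session_s = 500, seed = 12)
  segs <- segment_set(cohort, 50)  # 20 segments per class
  res <- tune_kmotif(segs,
                     space = list(w = c(8L, 12L), alpha = c(3L, 6L),
                                  k = c(2L, 3L), measures = "I2"),
                     relations = c("absolute_position", "nearest_object"),
                     classifier = "k_nearest_neighbours", folds = 4,
                     seed = 2, restarts = 1, holdout_fraction = 0.10)
  expect_s3_class(res, "kmotif_search")
  expect_true(res$best_params$w %in% 8:12)
  expect_gte(res$inner_score, 0); expect_lte(res$inner_score, 1)
  expect_gte(res$holdout_score, 0); expect_lte(res$holdout_score, 1)
  expect_s3_class(res$fit, "kmotif")
  # the reported optimum is the best point of the recorded trace
  expect_equal(res$inner_score, max(res$trace$score))
})
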