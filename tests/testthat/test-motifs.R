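test_that("candidate collection aggregates rule expansions and counts", {
  g <- induce_grammar(make_table1_sequence())
  cand <- collect_candidates(list(g))
  expect_equal(nrow(cand), 2L)
  cand <- cand[order(cand$length), ]
  expect_equal(cand$key, c("a b", "a b c a b d"))
  expect_equal(cand$frequency, c(4L, 2L))
  expect_equal(cand$length, c(2L, 6L))
  expect_equal(cand$diversity, c(2L, 4L))

  # two identical segments double every frequency
  two <- collect_candidates(list(g, g))
  two <- two[order(two$length), ]
  expect_equal(two$frequency, c(8L, 4L))

  flat <- collect_candidates(list(induce_grammar(letters[1:5])))
  expect_equal(nrow(flat), 0L)
})

test_that("interestingness measures follow their definitions", {
  expect_equal(interestingness(4, 2, 2, "I1"), 16)
  expect_equal(interestingness(4, 2, 2, "I2"), 4 * log(2) * log(2))
  expect_equal(interestingness(4, 2, 2, "I3"), 2 * log(4) * log(2))
  expect_equal(interestingness(4, 2, 2, "I4"), 2 * log(4) * log(2))
  # diversity-1 motifs are worthless under the log measures
  expect_equal(interestingness(7, 5, 1, "I2"), 0)
  expect_equal(interestingness(7, 5, 1, "I3"), 0)
  cand <- data.frame(frequency = c(4, 2), length = c(2, 6),
                     diversity = c(2, 4))
  expect_equal(interestingness(cand, measure = "I1"), c(16, 48))
})

test_that("top-k selection matches an exhaustive-sort oracle", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    seqs <- replicate(n, paste(sample(letters[1:4], sample(2:6, 1),
                                      replace = TRUE), collapse = " "))
    seqs <- unique(seqs)
    cand <- data.frame(key = seqs, stringsAsFactors = FALSE)
    cand$sequence <- I(strsplit(seqs, " ", fixed = TRUE))
    cand$length <- lengths(cand$sequence)
    cand$diversity <- vapply(cand$sequence, function(s)
      length(unique(s)), integer(1))
    cand$frequency <- sample(2:6, nrow(cand), replace = TRUE)
    k <- sample(1:5, 1)
    m <- sample(c("I1", "I2", "I3", "I4"), 1)
    got <- suppressWarnings(select_top_k(cand, k, m))
    # oracle: full deterministic sort, then head
    sc <- interestingness(cand, measure = m)
    ord <- order(-sc, -cand$length, cand$key, method = "radix")
    expect_equal(got$key, cand$key[head(ord, k)])
    expect_equal(got$score, sc[head(ord, k)])
  }
})

test_that("top-k tie-breaking and short candidate pools", {
  cand <- data.frame(key = c("a b", "c d", "e f"),
                     frequency = c(5L, 5L, 3L),
                     length = c(2L, 2L, 2L), diversity = c(2L, 2L, 2L),
                     stringsAsFactors = FALSE)
  cand$sequence <- I(strsplit(cand$key, " "))
  top <- select_top_k(cand, 2, "I1")
  expect_equal(top$key, c("a b", "c d"))  # equal scores: lexicographic
  expect_warning(all3 <- select_top_k(cand, 5, "I1"), "only 3")
  expect_equal(nrow(all3), 3L)
  expect_error(select_top_k(cand, 0, "I1"), "positive")
})

test_that("motif counting is greedy and non-overlapping by default", {
  s <- make_table1_sequence()
  expect_equal(count_motif(c("a", "b"), s), 4L)
  expect_equal(count_motif(letters[1:20], s), 0L)
  expect_equal(count_motif(c("a", "a"), c("a", "a", "a")), 1L)
  expect_equal(count_motif(c("a", "a"), c("a", "a", "a"), overlap = TRUE), 2L)
  expect_equal(count_motif(c("q", "r"), s), 0L)  # foreign alphabet

  # agreement with the plain R scanning oracle on random cases
  set.seed(14)
  for (i in 1:30) {
    s <- random_sequence(3, sample(10:80, 1))
    pat <- random_sequence(3, sample(2:4, 1))
    expect_equal(count_motif(pat, s), greedy_count(s, pat))
  }
})

test_that("feature vectors count per relation in motif-set order", {
  motifs <- data.frame(key = c("a b", "c d"), relation = "absolute_position",
                       source_class = "ctl", stringsAsFactors = FALSE)
  motifs$sequence <- I(strsplit(motifs$key, " "))
  seg <- list(absolute_position = symbol_series(
    c("a", "b", "c", "d", "a", "b")))
  expect_equal(build_feature_vector(seg, motifs), c(2L, 1L))
  none <- list(absolute_position = symbol_series(rep("z", 6)))
  expect_equal(build_feature_vector(none, motifs), c(0L, 0L))
  expect_error(build_feature_vector(list(other = seg[[1]]), motifs),
               "missing relation")
})

test_that("fitted models produce k*n*r features across configurations", {
  cohort <- tiny_cohort(n_per_class = 2, session_s = 300, seed = 42)
  segs <- segment_set(cohort, 100)
  for (cfg in list(list(k = 2, r = c("absolute_position", "nearest_object")),
                   list(k = 3, r = "nearest_object"),
                   list(k = 1, r = c("absolute_position",
                                     "relative_position",
                                     "nearest_object",
                                     "nearest_boundary")))) {
    fit <- kmotif(segs, w = 10, alpha = 4, k = cfg$k, measure = "I1",
                  relations = cfg$r)
    expect_equal(nrow(fit$motifs), cfg$k * 2L * length(cfg$r))
    pred <- predict(fit, segs)
    expect_equal(ncol(pred) - 2L, cfg$k * 2L * length(cfg$r))
    expect_equal(nrow(pred), length(segs))
  }
})

test_that("relative-position motif counts are translation invariant", {
  set.seed(33)
  x <- 100 + cumsum(rnorm(600, 0, 0.5))
  y <- 100 + cumsum(rnorm(600, 0, 0.5))
  t1 <- trajectory(x, y, class_label = "a")
  t2 <- trajectory(x + 15, y - 22, class_label = "a")
  a <- arena_spec(side = 400)
  fitdata <- trajectory_set(list(t1,
    trajectory(x + rnorm(600, 0, 0.1), y, class_label = "b")))
  fit <- kmotif(fitdata, arena = a, w = 5, alpha = 4, k = 2, measure = "I1",
                relations = "relative_position")
  p1 <- predict(fit, trajectory_set(t1))
  p2 <- predict(fit, trajectory_set(t2))
  expect_equal(p1[, -(1:2)], p2[, -(1:2)])
})
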