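test_that("normal-quantile bins match the fitted normal's quantiles", {
  set.seed(42)
  v <- rnorm(1e5)
  b <- fit_bins(v, alpha = 4, mode = "normal_quantile")
  expect_equal(b$lower_limits[1], -Inf)
  # interior limits approach the standard-normal quartiles
  expect_equal(b$lower_limits[2:4], c(-0.6745, 0, 0.6745), tolerance = 0.02)
  # and are exactly the fitted normal's quantiles
  expect_equal(b$lower_limits[2:4],
               b$fitted_mean + b$fitted_sd * qnorm(c(0.25, 0.5, 0.75)))

  b2 <- fit_bins(v, alpha = 2)
  expect_equal(b2$lower_limits[2], b2$fitted_mean)

  expect_error(fit_bins(rep(3, 10), alpha = 4, mode = "normal_quantile"),
               "degenerate")
})

test_that("equal-width bins reproduce the four-bin illustration", {
  b <- fit_bins(c(-4, 4), alpha = 4, mode = "equal_width")
  expect_equal(b$lower_limits, c(-4, -2, 0, 2))
  s <- discretize(c(-3, 1.5, 3.9), b)
  expect_equal(unclass(s), c("0", "2", "3"), ignore_attr = TRUE)
})

test_that("paa averages windows and pads with the last value", {
  expect_equal(paa(c(1, 2, 3, 4, 5, 6), 3), c(2, 5))
  expect_equal(paa(c(1, 2, 3, 4), 3), c(2, 4))
  x <- rnorm(17)
  expect_equal(paa(x, 1), x)
  expect_error(paa(numeric(0), 2), "empty")

  set.seed(8)
  for (i in 1:50) {
    n <- sample(1:200, 1); w <- sample(1:20, 1)
    expect_length(paa(rnorm(n), w), ceiling(n / w))
  }
})

test_that("discretize uses half-open bins and is monotone", {
  b <- fit_bins(c(-4, 4), alpha = 4, mode = "equal_width")
  expect_equal(unclass(discretize(-2, b)), "1", ignore_attr = TRUE)
  expect_equal(unclass(discretize(c(5, 5, 5), b)),
               rep("3", 3), ignore_attr = TRUE)

  set.seed(9)
  bn <- fit_bins(rnorm(1000), alpha = 7)
  v <- sort(rnorm(500, sd = 3))
  lab <- as.integer(unclass(discretize(v, bn)))
  expect_true(all(diff(lab) >= 0))
  expect_true(all(lab >= 0 & lab <= 6))
})

test_that("sax_transform equals windowed-mean plus search-based labelling", {
  # independent oracle: explicit per-window mean, then linear search for the
  # highest bin whose lower limit does not exceed the value
  oracle <- function(x, w, bins) {
    n_out <- ceiling(length(x) / w)
    x <- c(x, rep(x[length(x)], n_out * w - length(x)))
    vapply(seq_len(n_out), function(p) {
      m <- mean(x[((p - 1) * w + 1):(p * w)])
      lab <- 0L
      for (i in seq_along(bins$lower_limits))
        if (bins$lower_limits[i] <= m) lab <- i - 1L
      as.character(lab)
    }, character(1))
  }
  set.seed(10)
  for (i in 1:25) {
    x <- rnorm(sample(5:300, 1), sd = sample(1:5, 1))
    w <- sample(1:15, 1)
    b <- fit_bins(rnorm(500), alpha = sample(2:9, 1))
    expect_equal(unclass(sax_transform(x, w, b)), oracle(x, w, b),
                 ignore_attr = TRUE)
  }
  b <- fit_bins(rnorm(100), 3)
  expect_equal(length(unique(unclass(sax_transform(rep(0, 4), w = 2, b)))), 1L)
})

test_that("dimension pairing zips per-dimension labels", {
  sx <- symbol_series(c("0", "2"), 1L, 4L)
  sy <- symbol_series(c("1", "3"), 1L, 4L)
  p <- pair_dimensions(sx, sy)
  expect_equal(unclass(p), c("0:1", "2:3"), ignore_attr = TRUE)
  expect_equal(attr(p, "arity"), 2L)
  expect_equal(attr(p, "alphabet_size"), 16L)

  s <- symbol_series(c("1", "1"), 1L, 2L)
  expect_equal(unclass(pair_dimensions(s, s)), c("1:1", "1:1"),
               ignore_attr = TRUE)
  e <- symbol_series(character(0), 1L, 2L)
  expect_length(pair_dimensions(e, e), 0L)
  expect_error(pair_dimensions(sx, symbol_series("1", 1L, 4L)), "lengths")
})

test_that("visit entropy measures uniformity of bin visits", {
  expect_equal(visit_entropy(symbol_series(c("a", "b", "c", "d"))), 2)
  expect_equal(visit_entropy(symbol_series(rep("a", 10))), 0)
  expect_equal(visit_entropy(symbol_series(c("a", "a", "b", "c"))), 1.5)
})

test_that("normal-quantile bins equalise visit proportions on normal data", {
  set.seed(1234)
  v <- rnorm(1e5)
  alpha <- 10
  b <- fit_bins(v, alpha)
  s <- discretize(v, b)
  counts <- table(factor(unclass(s), levels = as.character(0:(alpha - 1))))
  gof <- chisq.test(counts)
  expect_gt(gof$p.value, 0.01)
  expect_equal(visit_entropy(s), log2(alpha), tolerance = 0.01)

  # equal-width bins on the same data are visibly less uniform
  s_lin <- discretize(v, fit_bins(v, alpha, mode = "equal_width"))
  expect_lt(visit_entropy(s_lin), visit_entropy(s))
})
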