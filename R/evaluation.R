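#' Class-size-weighted F1 score
#'
#' Computes per-class precision `P(c)` and recall `R(c)`, combines them
#' into per-class F1 scores `2 P R / (P + R)` (defined as 0 when
#' `P + R = 0`), and averages them weighted by class support. Two variants
#' are offered:
#' \describe{
#'   \item{`standard`}{`sum_c (|c| / N) * F1(c)` — the usual weighted F1,
#'     bounded in `[0, 1]`;}
#'   \item{`literal_eq10`}{`sum_c 2 P(c) R(c) / (|c| (P(c) + R(c)))` — a
#'     published variant that divides by the class size instead of
#'     weighting by the class proportion; it shrinks with class size and is
#'     provided for auditability only.}
#' }
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param variant `"standard"` (default) or `"literal_eq10"`.
#' @return A single numeric score.
#' @export
weighted_f1 <- function(y_true, y_pred,
                        variant = c("standard", "literal_eq10")) {
  variant <- match.arg(variant)
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred lengths differ")
  if (length(y_true) < 1L) stop("empty label vectors")
  classes <- sort(unique(y_true))
  n <- length(y_true)
  total <- 0
  for (cl in classes) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    size <- tp + fn
    if (variant == "standard") {
      f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
      total <- total + size / n * f1
    } else {
      total <- total + if (p + r > 0) 2 * p * r / (size * (p + r)) else 0
    }
  }
  total
}

#' Stratified k-fold assignment
#'
#' Partitions indices into `k` folds such that every fold's class counts
#' differ from exact proportionality by less than one: within each class,
#' shuffled indices are dealt round-robin over the folds. If some class has
#' fewer than `k` members, `k` is reduced to the smallest class size with a
#' warning.
#'
#' @param labels Vector of class labels.
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling the shuffle.
#' @return Integer vector of fold ids (1..k), one per label, with the
#'   effective `k` as attribute `"k"`.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  k <- as.integer(k)
  if (k > n) stop("more folds than samples")
  if (k < 2L) stop("k must be at least 2")
  smallest <- min(table(labels))
  if (smallest < k) {
    warning(sprintf("smallest class has %d members; reducing k from %d",
                    smallest, k))
    k <- as.integer(smallest)
    if (k < 2L) stop("smallest class has fewer than 2 members")
  }
  folds <- integer(n)
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(folds, k = k)
}

# Evaluate an expression with a temporary RNG state, restoring the
# caller's afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Pluggable classifiers behind a fit/predict contract. Hyperparameters are
# the widely used defaults of each implementation (kNN: 5 neighbours;
# MLP: one hidden layer of 100 units, weight decay 1e-4, 200 iterations).
.km_classifier <- function(name = c("k_nearest_neighbours",
                                    "gaussian_naive_bayes",
                                    "decision_tree",
                                    "multilayer_perceptron")) {
  name <- match.arg(name)
  switch(name,
    gaussian_naive_bayes = list(
      fit = function(x, y) e1071::naiveBayes(x, factor(y)),
      predict = function(model, x)
        as.character(predict(model, x, eps = 1e-9))),
    decision_tree = list(
      fit = function(x, y) {
        df <- as.data.frame(x)
        df$.class <- factor(y)
        rpart::rpart(.class ~ ., data = df, method = "class")
      },
      predict = function(model, x)
        as.character(predict(model, as.data.frame(x), type = "class"))),
    multilayer_perceptron = list(
      fit = function(x, y)
        nnet::nnet(x, nnet::class.ind(factor(y)), size = 100,
                   decay = 1e-4, maxit = 200, MaxNWts = 1e5,
                   softmax = TRUE, trace = FALSE),
      predict = function(model, x) {
        pr <- predict(model, x)
        colnames(pr)[max.col(pr, ties.method = "first")]
      }),
    k_nearest_neighbours = list(
      fit = function(x, y) list(x = x, y = factor(y)),
      predict = function(model, x)
        as.character(class::knn(model$x, x, model$y, k = 5))))
}

#' Cross-validated classifier evaluation of a feature matrix
#'
#' Runs stratified k-fold cross-validation of one of four standard
#' classifiers (Gaussian naive Bayes, decision tree, multilayer perceptron,
#' k-nearest neighbours) on a precomputed feature matrix, scoring each
#' held-out fold with the standard class-size-weighted F1.
#'
#' @param features Numeric matrix or data frame of features (rows =
#'   samples). Non-numeric columns such as `segment_id` are dropped.
#' @param labels Class labels, one per row.
#' @param classifier Classifier name (see above; default
#'   `"k_nearest_neighbours"`).
#' @param k Number of folds (default 10).
#' @param seed Integer seed (fold assignment and classifier initialisation).
#' @param method Optional description stored in the result.
#' @return An object of class `"kmotif_eval"` with `fold_scores`, `mean`,
#'   `sd`, `classifier` and `method`.
#' @export
cross_validate <- function(features, labels,
                           classifier = "k_nearest_neighbours",
                           k = 10L, seed = 1L, method = "features") {
  if (is.data.frame(features)) {
    keep <- vapply(features, is.numeric, logical(1))
    features <- as.matrix(features[, keep, drop = FALSE])
  }
  labels <- as.character(labels)
  if (nrow(features) != length(labels))
    stop("feature rows and labels differ in length")
  folds <- stratified_kfold(labels, k = k, seed = seed)
  clf <- .km_classifier(classifier)
  scores <- vapply(seq_len(attr(folds, "k")), function(i) {
    train <- folds != i
    if (length(unique(labels[train])) < 2L) {
      warning("single-class training fold; scoring 0")
      return(0)
    }
    pred <- with_seed(seed + i, {
      model <- clf$fit(features[train, , drop = FALSE], labels[train])
      clf$predict(model, features[!train, , drop = FALSE])
    })
    weighted_f1(labels[!train], pred)
  }, numeric(1))
  structure(list(method = method, classifier = classifier,
                 fold_scores = scores, mean = mean(scores),
                 sd = stats::sd(scores)),
            class = "kmotif_eval")
}

#' @export
print.kmotif_eval <- function(x, ...) {
  cat(sprintf("%s / %s: weighted F1 = %.3f +/- %.3f (%d folds)\n",
              x$method, x$classifier, x$mean, x$sd, length(x$fold_scores)))
  invisible(x)
}

#' Baseline feature representations
#'
#' Two reference quantification methods against which motif features are
#' compared:
#' \describe{
#'   \item{`full_data`}{no reduction — the flattened `(x, y)` coordinate
#'     sequence of each segment (segments are truncated to the cohort
#'     minimum frame count so vectors align);}
#'   \item{`means_variances`}{each segment reduced to four numbers:
#'     `mean(x), var(x), mean(y), var(y)` (population variances).}
#' }
#'
#' @param data A [trajectory_set()] of segments.
#' @param method `"means_variances"` (default) or `"full_data"`.
#' @return Numeric feature matrix, one row per segment.
#' @export
baseline_features <- function(data,
                              method = c("means_variances", "full_data")) {
  method <- match.arg(method)
  stopifnot(inherits(data, "trajectory_set"))
  lens <- vapply(data$trajectories, function(t) length(t$x), integer(1))
  if (any(lens == 0L)) stop("empty segment")
  if (method == "full_data") {
    nmin <- min(lens)
    m <- t(vapply(data$trajectories, function(t)
      c(t$x[seq_len(nmin)], t$y[seq_len(nmin)]), numeric(2L * nmin)))
  } else {
    pvar <- function(v) mean((v - mean(v))^2)
    m <- t(vapply(data$trajectories, function(t)
      c(mean(t$x), pvar(t$x), mean(t$y), pvar(t$y)), numeric(4L)))
    colnames(m) <- c("mean_x", "var_x", "mean_y", "var_y")
  }
  rownames(m) <- vapply(data$trajectories, function(t) t$session_id,
                        character(1))
  m
}

#' Cross-validated evaluation of the full k-motif pipeline
#'
#' Stratified k-fold cross-validation in which motif selection is redone
#' inside every training split (`reselect = TRUE`, the default), so that
#' the held-out segments never influence which motifs are used. SAX bins
#' are fitted once on all segments passed in, mirroring the protocol of
#' fitting bins on all available data to obtain one shared alphabet.
#' Symbol series and per-segment grammars depend only on `(w, alpha)` and
#' are computed once and reused across folds.
#'
#' @inheritParams kmotif
#' @param classifier,folds,seed Passed to the classifier harness (see
#'   [cross_validate()]).
#' @param reselect Redo motif selection within each training split
#'   (default) or select once on all data (cheaper, mild leakage).
#' @return A `"kmotif_eval"` object (see [cross_validate()]).
#' @export
kmotif_cv <- function(data, arena = arena_spec(), w = 15, alpha = 10,
                      k = 10, measure = c("I2", "I1", "I3", "I4"),
                      relations = c("absolute_position", "relative_position",
                                    "nearest_object", "nearest_boundary"),
                      binning = c("normal_quantile", "equal_width"),
                      classifier = "k_nearest_neighbours", folds = 10L,
                      seed = 1L, reselect = TRUE, overlap = FALSE) {
  measure <- match.arg(measure)
  binning <- match.arg(binning)
  relations <- match.arg(relations, several.ok = TRUE)
  prep <- .km_prepare(data, arena, w, alpha, relations, binning)
  .km_cv_prepared(prep, k, measure, classifier, folds, seed, reselect,
                  overlap)
}

# CV loop over an existing pipeline cache (used by kmotif_cv and the
# hyperparameter search, which reuses `prep` across (k, measure) values).
.km_cv_prepared <- function(prep, k, measure, classifier, folds, seed,
                            reselect = TRUE, overlap = FALSE) {
  labels <- prep$labels
  fold_id <- stratified_kfold(labels, k = folds, seed = seed)
  clf <- .km_classifier(classifier)
  all_idx <- seq_along(labels)
  motifs_all <- if (!reselect)
    .km_select_motifs(prep, all_idx, k, measure)
  scores <- vapply(seq_len(attr(fold_id, "k")), function(i) {
    train <- all_idx[fold_id != i]
    test <- all_idx[fold_id == i]
    if (length(unique(labels[train])) < 2L) {
      warning("single-class training fold; scoring 0")
      return(0)
    }
    motifs <- if (reselect)
      .km_select_motifs(prep, train, k, measure) else motifs_all
    xtr <- .km_features(prep, train, motifs, overlap)
    xte <- .km_features(prep, test, motifs, overlap)
    pred <- with_seed(seed + i, {
      model <- clf$fit(xtr, labels[train])
      clf$predict(model, xte)
    })
    weighted_f1(labels[test], pred)
  }, numeric(1))
  structure(list(method = "k-motifs", classifier = classifier,
                 fold_scores = scores, mean = mean(scores),
                 sd = stats::sd(scores),
                 params = list(w = prep$w, alpha = NA, k = k,
                               measure = measure)),
            class = "kmotif_eval")
}
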