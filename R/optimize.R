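#' Split a cohort into development and holdout sets
#'
#' Per-subject stratified split: for each subject,
#' `round(fraction * n_segments)` of its segments are held out (seeded
#' uniform draw), the rest form the development set used for
#' hyperparameter search. With 30 segments per animal and the default
#' fraction, 3 segments per animal are held out.
#'
#' @param data A [trajectory_set()] of segments.
#' @param fraction Holdout fraction in (0, 1); default 0.10.
#' @param seed Integer seed.
#' @return A list with [trajectory_set()] elements `dev` and `holdout`.
#' @export
split_holdout <- function(data, fraction = 0.10, seed = 1L) {
  stopifnot(inherits(data, "trajectory_set"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must be strictly between 0 and 1")
  subjects <- vapply(data$trajectories, function(t) t$subject_id,
                     character(1))
  hold <- logical(length(subjects))
  with_seed(seed, {
    for (s in unique(subjects)) {
      idx <- which(subjects == s)
      m <- round(fraction * length(idx))
      if (m > 0L) hold[sample(idx, m)] <- TRUE
    }
  })
  list(dev = trajectory_set(data$trajectories[!hold]),
       holdout = trajectory_set(data$trajectories[hold]))
}

#' Hill-climbing search over the integer parameter grid
#'
#' Maximises `objective(w, alpha, k, measure)` by steepest-ascent
#' hill-climbing on the integer grid for `(w, alpha, k)` — neighbourhood:
#' one step of +/-1 in exactly one coordinate — combined with exhaustive
#' search over the interestingness measures. Each climb starts from a
#' seeded uniform draw over the grid and stops at a local maximum (every
#' accepted move strictly improves the objective, so climbs cannot cycle);
#' the best point across all restarts and measures is returned. Objective
#' evaluations are memoised.
#'
#' @param objective A function `f(w, alpha, k, measure)` returning a single
#'   numeric score to maximise.
#' @param space A list with integer ranges `w`, `alpha`, `k` (each
#'   `c(lower, upper)`) and a character vector `measures`.
#' @param seed Integer seed for the restart draws.
#' @param restarts Number of random starts per measure (default 5).
#' @return An object of class `"kmotif_search"`: `best_params` (list `w`,
#'   `alpha`, `k`, `measure`), `inner_score`, `trace` (data frame of
#'   accepted states per climb) and `evaluations` (all memoised points).
#' @export
hill_climb <- function(objective,
                       space = list(w = c(5L, 50L), alpha = c(2L, 15L),
                                    k = c(1L, 10L),
                                    measures = c("I1", "I2", "I3", "I4")),
                       seed = 1L, restarts = 5L) {
  for (nm in c("w", "alpha", "k")) {
    rg <- space[[nm]]
    if (is.null(rg) || length(rg) != 2L || rg[1L] > rg[2L] || rg[1L] < 1L)
      stop("invalid range for ", nm)
  }
  if (length(space$measures) < 1L) stop("no interestingness measures given")
  cache <- new.env(parent = emptyenv())
  eval_pt <- function(w, a, k, m) {
    key <- paste(w, a, k, m, sep = "|")
    if (is.null(cache[[key]]))
      cache[[key]] <- as.numeric(objective(w, a, k, m))
    cache[[key]]
  }
  clamp_grid <- function(v, rg) v >= rg[1L] && v <= rg[2L]

  starts <- with_seed(seed, {
    data.frame(
      w = sample(space$w[1L]:space$w[2L], restarts, replace = TRUE),
      alpha = sample(space$alpha[1L]:space$alpha[2L], restarts,
                     replace = TRUE),
      k = sample(space$k[1L]:space$k[2L], restarts, replace = TRUE))
  })

  trace <- list()
  best <- list(score = -Inf)
  climb_no <- 0L
  for (m in space$measures) {
    for (r in seq_len(restarts)) {
      climb_no <- climb_no + 1L
      cur <- c(w = starts$w[r], alpha = starts$alpha[r], k = starts$k[r])
      cur_score <- eval_pt(cur["w"], cur["alpha"], cur["k"], m)
      step <- 1L
      trace[[length(trace) + 1L]] <-
        data.frame(climb = climb_no, step = step, measure = m,
                   w = cur["w"], alpha = cur["alpha"], k = cur["k"],
                   score = cur_score)
      repeat {
        cand <- list()
        for (nm in c("w", "alpha", "k")) {
          for (d in c(-1L, 1L)) {
            nb <- cur
            nb[nm] <- nb[nm] + d
            if (clamp_grid(nb[nm], space[[nm]])) cand[[length(cand) + 1L]] <- nb
          }
        }
        scores <- vapply(cand, function(nb)
          eval_pt(nb["w"], nb["alpha"], nb["k"], m), numeric(1))
        if (length(scores) == 0L || max(scores) <= cur_score) break
        pick <- which.max(scores)
        cur <- cand[[pick]]
        cur_score <- scores[pick]
        step <- step + 1L
        trace[[length(trace) + 1L]] <-
          data.frame(climb = climb_no, step = step, measure = m,
                     w = cur["w"], alpha = cur["alpha"], k = cur["k"],
                     score = cur_score)
      }
      if (cur_score > best$score)
        best <- list(w = unname(cur["w"]), alpha = unname(cur["alpha"]),
                     k = unname(cur["k"]), measure = m, score = cur_score)
    }
  }
  trace <- do.call(rbind, trace)
  rownames(trace) <- NULL
  evals <- do.call(rbind, lapply(ls(cache), function(key) {
    p <- strsplit(key, "|", fixed = TRUE)[[1L]]
    data.frame(w = as.integer(p[1L]), alpha = as.integer(p[2L]),
               k = as.integer(p[3L]), measure = p[4L],
               score = cache[[key]])
  }))
  structure(list(best_params = best[c("w", "alpha", "k", "measure")],
                 inner_score = best$score, trace = trace,
                 evaluations = evals),
            class = "kmotif_search")
}

#' @export
print.kmotif_search <- function(x, ...) {
  b <- x$best_params
  cat(sprintf(
    "hill-climb: best w = %d, alpha = %d, k = %d, measure = %s (score %.3f",
    b$w, b$alpha, b$k, b$measure, x$inner_score))
  if (!is.null(x$holdout_score))
    cat(sprintf(", holdout %.3f", x$holdout_score))
  cat(sprintf("); %d evaluations\n", nrow(x$evaluations)))
  invisible(x)
}

#' Tune k-motif hyperparameters on a cohort
#'
#' Full protocol: the cohort is split 90/10 into a development and a
#' holdout set (per subject, [split_holdout()]); [hill_climb()] searches
#' `(w, alpha, k)` with exhaustive search over the interestingness
#' measures, the objective being the mean cross-validated weighted F1 of
#' [kmotif_cv()] on the development set; finally the holdout segments are
#' scored exactly once with the frozen best parameters (model fitted on the
#' development set only).
#'
#' @inheritParams kmotif_cv
#' @param space Search space, as in [hill_climb()].
#' @param restarts Random restarts per measure.
#' @param holdout_fraction Fraction held out for the final evaluation.
#' @return A `"kmotif_search"` object with an additional `holdout_score`.
#' @export
tune_kmotif <- function(data, arena = arena_spec(),
                        space = list(w = c(5L, 50L), alpha = c(2L, 15L),
                                     k = c(1L, 10L),
                                     measures = c("I1", "I2", "I3", "I4")),
                        relations = c("absolute_position",
                                      "relative_position",
                                      "nearest_object", "nearest_boundary"),
                        binning = c("normal_quantile", "equal_width"),
                        classifier = "k_nearest_neighbours", folds = 10L,
                        seed = 1L, restarts = 5L, holdout_fraction = 0.10,
                        reselect = TRUE) {
  binning <- match.arg(binning)
  relations <- match.arg(relations, several.ok = TRUE)
  split <- split_holdout(data, fraction = holdout_fraction, seed = seed)
  # symbol series depend only on (w, alpha): cache pipeline per pair
  preps <- new.env(parent = emptyenv())
  objective <- function(w, alpha, k, measure) {
    key <- paste(w, alpha, sep = "|")
    if (is.null(preps[[key]]))
      preps[[key]] <- .km_prepare(split$dev, arena, w, alpha, relations,
                                  binning)
    .km_cv_prepared(preps[[key]], k, measure, classifier, folds, seed,
                    reselect)$mean
  }
  res <- hill_climb(objective, space = space, seed = seed,
                    restarts = restarts)
  b <- res$best_params
  fit <- kmotif(split$dev, arena = arena, w = b$w, alpha = b$alpha,
                k = b$k, measure = b$measure, relations = relations,
                binning = binning)
  clf <- .km_classifier(classifier)
  pred <- with_seed(seed, {
    model <- clf$fit(fit$features, fit$labels)
    hx <- predict(fit, split$holdout)
    clf$predict(model, as.matrix(hx[, -(1:2), drop = FALSE]))
  })
  res$holdout_score <- weighted_f1(class_labels(split$holdout), pred)
  res$fit <- fit
  res
}
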