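#' Fit a k-motif behaviour quantification model
#'
#' The central fitting function of the package. Each trajectory segment is
#' reparameterised into spatial relations, discretized with SAX (bins
#' fitted on data pooled across *all* segments so that every subject shares
#' one alphabet), and compressed with Sequitur grammar induction. The
#' expansions of grammar rules are candidate motifs; per class and per
#' relation, the `k` candidates with the highest interestingness are
#' selected, giving `k * n * r` motifs in total for `n` classes and `r`
#' relations. A fitted model turns any segment into a fixed-length feature
#' vector of motif occurrence counts via [predict.kmotif()].
#'
#' @param data A [trajectory_set()] of cleaned, segmented trajectories with
#'   class labels (at least two classes).
#' @param arena An [arena_spec()] describing the open field.
#' @param w SAX window size in frames (piecewise-aggregate segment length).
#' @param alpha Number of SAX bins per dimension.
#' @param k Number of motifs selected per class and relation.
#' @param measure Interestingness measure, `"I1"`..`"I4"` (default `"I2"`,
#'   the frequency-focused measure; see [interestingness()]).
#' @param relations Spatial relations to mine (see [spatial_relations()]).
#' @param binning `"normal_quantile"` for the classic SAX equiprobable bins
#'   or `"equal_width"` for a regular zone grid (see [fit_bins()]).
#' @param overlap Count overlapping motif occurrences? Default `FALSE`.
#' @return An object of class `"kmotif"` with elements `motifs` (the ranked
#'   motif table), `bins`, `params`, `classes`, `features` (training motif
#'   counts) and `labels`.
#' @seealso [predict.kmotif()], [kmotif_cv()], [tune_kmotif()]
#' @examples
#' set.seed(1)
#' cohort <- generate_cohort(cohort_spec(n_per_class = 2, session_s = 120,
#'                                       seed = 1))
#' segs <- segment_set(cohort, duration = 60)
#' fit <- kmotif(segs, w = 15, alpha = 5, k = 3)
#' fit
#' head(predict(fit, segs))
#' @export
kmotif <- function(data, arena = arena_spec(), w = 15, alpha = 10, k = 10,
                   measure = c("I2", "I1", "I3", "I4"),
                   relations = c("absolute_position", "relative_position",
                                 "nearest_object", "nearest_boundary"),
                   binning = c("normal_quantile", "equal_width"),
                   overlap = FALSE) {
  measure <- match.arg(measure)
  binning <- match.arg(binning)
  relations <- match.arg(relations, several.ok = TRUE)
  prep <- .km_prepare(data, arena, w, alpha, relations, binning)
  motifs <- .km_select_motifs(prep, seq_along(prep$labels), k, measure)
  feats <- .km_features(prep, seq_along(prep$labels), motifs, overlap)
  structure(
    list(motifs = motifs,
         bins = prep$bins,
         params = list(w = as.integer(w), alpha = as.integer(alpha),
                       k = as.integer(k), measure = measure,
                       relations = relations, binning = binning,
                       overlap = overlap),
         arena = arena,
         classes = prep$classes,
         features = feats,
         labels = prep$labels,
         segment_ids = prep$ids,
         call = match.call()),
    class = "kmotif")
}

# Shared pipeline cache: relation series, bins, symbol series, grammars and
# per-segment candidate tables. Everything downstream (motif selection,
# feature counting, cross-validation) reuses this.
.km_prepare <- function(data, arena, w, alpha, relations, binning) {
  stopifnot(inherits(data, "trajectory_set"))
  labels <- class_labels(data)
  if (anyNA(labels)) stop("all trajectories need a class label")
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("classification needs at least 2 classes")
  rel <- lapply(data$trajectories, spatial_relations, arena = arena,
                relations = relations)
  # fit bins per relation and dimension on pooled values
  bins <- lapply(relations, function(r) {
    dims <- rel[[1L]][[r]]$dims
    lapply(seq_len(dims), function(d) {
      fit_bins(unlist(lapply(rel, function(rs) rs[[r]]$values[, d]),
                      use.names = FALSE), alpha, binning)
    })
  })
  names(bins) <- relations
  segments <- lapply(rel, function(rs) {
    series <- .km_symbolize_rel(rs, bins, w)
    cand <- lapply(series, function(s) {
      g <- induce_grammar(s)
      nts <- setdiff(names(g$rules), "S")
      if (length(nts) == 0L)
        return(data.frame(key = character(0), frequency = integer(0),
                          stringsAsFactors = FALSE))
      counts <- occurrence_counts(g)
      data.frame(key = vapply(nts, function(nm)
                   paste(expand_rule(g, nm), collapse = " "), character(1)),
                 frequency = as.integer(counts[nts]),
                 stringsAsFactors = FALSE)
    })
    list(series = series, candidates = cand)
  })
  ids <- vapply(data$trajectories, function(t) t$session_id, character(1))
  list(bins = bins, segments = segments, labels = labels,
       classes = classes, ids = ids, relations = relations,
       w = as.integer(w))
}

# SAX-transform one segment's relation series against fitted bins.
.km_symbolize_rel <- function(rs, bins, w) {
  out <- lapply(names(bins), function(r) {
    v <- rs[[r]]$values
    per_dim <- lapply(seq_len(ncol(v)), function(d)
      sax_transform(v[, d], w, bins[[r]][[d]]))
    if (length(per_dim) == 2L)
      pair_dimensions(per_dim[[1L]], per_dim[[2L]])
    else per_dim[[1L]]
  })
  names(out) <- names(bins)
  out
}

# Aggregate per-segment candidates over `idx` and select top k per
# class/relation. Motif order: relation-major, then class, then rank.
.km_select_motifs <- function(prep, idx, k, measure) {
  out <- list()
  for (r in prep$relations) {
    for (cl in prep$classes) {
      sel <- idx[prep$labels[idx] == cl]
      tabs <- lapply(prep$segments[sel], function(sg) sg$candidates[[r]])
      all <- do.call(rbind, tabs)
      if (is.null(all) || nrow(all) == 0L) {
        warning(sprintf("no candidate motifs for class %s, relation %s",
                        cl, r))
        next
      }
      freq <- tapply(all$frequency, all$key, sum)
      seqs <- strsplit(names(freq), " ", fixed = TRUE)
      cand <- data.frame(key = names(freq), frequency = as.integer(freq),
                         length = lengths(seqs),
                         diversity = vapply(seqs, function(s)
                           length(unique(s)), integer(1)),
                         relation = r, source_class = cl,
                         stringsAsFactors = FALSE)
      cand$sequence <- I(seqs)
      out[[paste(r, cl, sep = ".")]] <-
        suppressWarnings(select_top_k(cand, k, measure))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Count motif occurrences for the segments in `idx`; rows follow idx.
.km_features <- function(prep, idx, motifs, overlap = FALSE) {
  m <- t(vapply(prep$segments[idx], function(sg)
    build_feature_vector(sg$series, motifs, overlap = overlap),
    integer(nrow(motifs))))
  colnames(m) <- paste(motifs$relation, motifs$source_class,
                       stats::ave(seq_len(nrow(motifs)),
                                  paste(motifs$relation, motifs$source_class),
                                  FUN = seq_along),
                       sep = ".")
  rownames(m) <- prep$ids[idx]
  m
}

#' @export
print.kmotif <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "k-motif model: w = %d, alpha = %d, k = %d, measure = %s (%s bins)\n",
    p$w, p$alpha, p$k, p$measure, p$binning))
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  relations: %s\n", paste(p$relations, collapse = ", ")))
  cat(sprintf("  %d motifs selected (feature vector length %d) from %d segments\n",
              nrow(x$motifs), nrow(x$motifs), length(x$labels)))
  invisible(x)
}

#' @export
summary.kmotif <- function(object, ...) {
  print(object)
  cat("\nTop motifs per class/relation (rank 1):\n")
  first <- object$motifs[!duplicated(paste(object$motifs$relation,
                                           object$motifs$source_class)), ]
  for (i in seq_len(nrow(first)))
    cat(sprintf("  %-18s %-10s f=%-5d |m|=%-3d d=%-3d  %s\n",
                first$relation[i], first$source_class[i],
                first$frequency[i], first$length[i], first$diversity[i],
                paste(utils::head(first$sequence[[i]], 8L), collapse = " ")))
  invisible(object)
}

#' Motif-count features for new segments
#'
#' Transforms trajectories with the bins and motif set of a fitted model
#' (nothing is refitted) and counts each motif's occurrences, yielding one
#' feature vector per segment.
#'
#' @param object A fitted [kmotif()] model.
#' @param newdata A [trajectory_set()].
#' @param ... Unused.
#' @return A data frame: `segment_id`, `class_label`, then one integer
#'   count column per motif.
#' @export
predict.kmotif <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "trajectory_set"))
  p <- object$params
  rel <- lapply(newdata$trajectories, spatial_relations,
                arena = object$arena, relations = p$relations)
  counts <- t(vapply(rel, function(rs) {
    series <- .km_symbolize_rel(rs, object$bins, p$w)
    build_feature_vector(series, object$motifs, overlap = p$overlap)
  }, integer(nrow(object$motifs))))
  colnames(counts) <- colnames(object$features)
  data.frame(segment_id = vapply(newdata$trajectories,
                                 function(t) t$session_id, character(1)),
             class_label = class_labels(newdata),
             counts, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Plot per-class mean motif counts
#'
#' Shows, for each selected motif, the mean occurrence count per class in
#' the training data — a quick visual check of which motifs discriminate.
#'
#' @param x A fitted [kmotif()] model.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.kmotif <- function(x, ...) {
  means <- sapply(x$classes, function(cl)
    colMeans(x$features[x$labels == cl, , drop = FALSE]))
  graphics::barplot(t(means), beside = TRUE, las = 2,
                    cex.names = 0.6, legend.text = x$classes,
                    ylab = "mean occurrence count",
                    main = "Motif counts by class", ...)
  invisible(x)
}
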