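#' Collect candidate motifs from a set of grammars
#'
#' Every non-terminal rule (excluding the start rule, whose expansion is the
#' whole input) of every grammar contributes its terminal expansion as a
#' candidate motif. Candidates with the same expansion are merged and their
#' occurrence counts summed, so the frequency of a motif is aggregated
#' across all segments of a class. Each candidate records its frequency
#' `I_f` (summed occurrence count), length `|m|` (number of symbols, always
#' at least 2) and diversity `I_d` (number of unique symbols).
#'
#' @param grammars A list of [induce_grammar()] results (one per data
#'   segment of one class, for one spatial relation).
#' @param relation Optional relation name stored with the candidates.
#' @param source_class Optional class label stored with the candidates.
#' @return A data frame with columns `key` (space-separated expansion),
#'   `sequence` (list column of character vectors), `frequency`, `length`,
#'   `diversity`, `relation`, `source_class`.
#' @export
collect_candidates <- function(grammars, relation = NA_character_,
                               source_class = NA_character_) {
  if (inherits(grammars, "sequitur_grammar")) grammars <- list(grammars)
  stopifnot(length(grammars) > 0L,
            all(vapply(grammars, inherits, TRUE, "sequitur_grammar")))
  per <- lapply(grammars, function(g) {
    nts <- setdiff(names(g$rules), "S")
    if (length(nts) == 0L)
      return(data.frame(key = character(0), frequency = integer(0)))
    counts <- occurrence_counts(g)
    exps <- lapply(nts, function(nm) expand_rule(g, nm))
    data.frame(key = vapply(exps, paste, character(1), collapse = " "),
               frequency = as.integer(counts[nts]),
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, per)
  if (nrow(all) == 0L) {
    return(data.frame(key = character(0), sequence = I(list()),
                      frequency = integer(0), length = integer(0),
                      diversity = integer(0), relation = character(0),
                      source_class = character(0)))
  }
  freq <- tapply(all$frequency, all$key, sum)
  keys <- names(freq)
  seqs <- strsplit(keys, " ", fixed = TRUE)
  out <- data.frame(key = keys,
                    frequency = as.integer(freq),
                    length = lengths(seqs),
                    diversity = vapply(seqs, function(s)
                      length(unique(s)), integer(1)),
                    relation = relation,
                    source_class = source_class,
                    stringsAsFactors = FALSE)
  out$sequence <- I(seqs)
  rownames(out) <- NULL
  out[, c("key", "sequence", "frequency", "length", "diversity",
          "relation", "source_class")]
}

#' Interestingness of a motif
#'
#' Scalar measures combining a motif's frequency `f`, length `L` and
#' diversity `d` used to rank candidates:
#' \describe{
#'   \item{I1}{`f * L * d` (equal weight);}
#'   \item{I2}{`f * log(L) * log(d)` (focus on frequency);}
#'   \item{I3}{`L * log(f) * log(d)` (focus on length);}
#'   \item{I4}{`d * log(f) * log(L)` (focus on diversity).}
#' }
#' Logarithms are natural; since only the rank order matters for selection,
#' any fixed base gives the same top-k sets.
#'
#' @param frequency,length,diversity Numeric vectors (recycled) of motif
#'   properties; a candidate data frame from [collect_candidates()] may be
#'   passed as `frequency`, in which case its columns are used.
#' @param measure One of `"I1"`, `"I2"`, `"I3"`, `"I4"`.
#' @return Numeric vector of interestingness scores.
#' @export
interestingness <- function(frequency, length = NULL, diversity = NULL,
                            measure = c("I1", "I2", "I3", "I4")) {
  measure <- match.arg(measure)
  if (is.data.frame(frequency)) {
    length <- frequency$length
    diversity <- frequency$diversity
    frequency <- frequency$frequency
  }
  f <- as.numeric(frequency); L <- as.numeric(length)
  d <- as.numeric(diversity)
  switch(measure,
         I1 = f * L * d,
         I2 = f * log(L) * log(d),
         I3 = L * log(f) * log(d),
         I4 = d * log(f) * log(L))
}

#' Select the k most interesting motifs
#'
#' Ranks candidates by an interestingness measure and keeps the top `k`.
#' Ties are broken deterministically: descending interestingness, then
#' descending length, then lexicographically on the symbol sequence. When
#' fewer than `k` candidates exist, all are returned with a warning.
#'
#' @param candidates A candidate data frame from [collect_candidates()].
#' @param k Number of motifs to keep.
#' @param measure Interestingness measure (see [interestingness()]).
#' @return The selected rows, ranked, with a `score` column appended.
#' @export
select_top_k <- function(candidates, k, measure = c("I1", "I2", "I3", "I4")) {
  measure <- match.arg(measure)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  score <- interestingness(candidates, measure = measure)
  ord <- order(-score, -candidates$length,
               candidates$key, method = "radix")
  if (nrow(candidates) < k)
    warning(sprintf("only %d candidate motifs available (k = %d)",
                    nrow(candidates), k))
  sel <- utils::head(ord, k)
  out <- candidates[sel, , drop = FALSE]
  out$score <- score[sel]
  rownames(out) <- NULL
  out
}

#' Count occurrences of a motif in a symbol series
#'
#' Scans left to right; by default matches do not overlap (a match consumes
#' its symbols before scanning resumes), mirroring how grammar-derived
#' occurrence counts arise. Overlapping counting is available as an option.
#'
#' @param m A motif: a character vector of terminal symbols (or a one-row
#'   data frame from [select_top_k()]).
#' @param s A [symbol_series()] or character vector.
#' @param overlap Allow overlapping matches? Default `FALSE`.
#' @return Non-negative integer count.
#' @export
count_motif <- function(m, s, overlap = FALSE) {
  if (is.data.frame(m)) m <- m$sequence[[1L]]
  m <- as.character(m)
  s <- as.character(unclass(s))
  if (length(m) == 0L) stop("empty motif")
  lev <- unique(s)
  pat <- match(m, lev)
  if (anyNA(pat)) return(0L)  # motif uses a symbol absent from the series
  .count_occurrences(match(s, lev), as.integer(pat), isTRUE(overlap))
}

#' Build a motif-count feature vector for one segment
#'
#' Counts every motif of a motif set against the segment's symbol series
#' for that motif's relation, in motif-set order, yielding the fixed-length
#' feature vector used for classification.
#'
#' @param series_by_relation Named list of [symbol_series()], one per
#'   spatial relation appearing in `motifs`.
#' @param motifs A motif data frame (rows ordered as the feature vector),
#'   e.g. the `motifs` element of a fitted [kmotif()] model.
#' @param overlap Passed to [count_motif()].
#' @return Integer vector of counts, one per motif row.
#' @export
build_feature_vector <- function(series_by_relation, motifs,
                                 overlap = FALSE) {
  need <- unique(motifs$relation)
  miss <- setdiff(need, names(series_by_relation))
  if (length(miss) > 0L)
    stop("missing relation series: ", paste(miss, collapse = ", "))
  # precompute integer codings once per relation
  coded <- lapply(series_by_relation[need], function(s) {
    s <- as.character(unclass(s))
    lev <- unique(s)
    list(codes = match(s, lev), lev = lev)
  })
  vapply(seq_len(nrow(motifs)), function(i) {
    cs <- coded[[motifs$relation[i]]]
    pat <- match(motifs$sequence[[i]], cs$lev)
    if (anyNA(pat)) return(0L)
    .count_occurrences(cs$codes, as.integer(pat), isTRUE(overlap))
  }, integer(1))
}
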