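#' Induce a Sequitur grammar from a symbol series
#'
#' Sequitur builds a hierarchical context-free grammar from a sequence by
#' processing symbols one at a time while maintaining two properties:
#' *digram uniqueness* (no pair of adjacent symbols occurs more than once
#' across all rule bodies) and *rule utility* (every rule other than the
#' start rule is referenced at least twice). Repeated subsequences become
#' rules, so the grammar both compresses the input and exposes its
#' recurring structure; expanding the start rule reproduces the input
#' exactly.
#'
#' @param s A [symbol_series()] or plain character vector of symbols.
#' @return An object of class `"sequitur_grammar"`: a list with `rules` (a
#'   named list, `"S"` first then `"1"`, `"2"`, ... in creation order; each
#'   body is a character vector in which non-terminal references are written
#'   `"#k"`) and `terminals` (the input alphabet).
#' @examples
#' g <- induce_grammar(strsplit("a b c a b d a b c a b d", " ")[[1]])
#' g$rules
#' @export
induce_grammar <- function(s) {
  s <- as.character(unclass(s))
  if (length(s) < 1L) stop("empty input sequence")
  if (anyNA(s)) stop("input contains missing symbols")
  terminals <- unique(s)
  codes <- match(s, terminals)
  bodies <- .sequitur_induce(as.integer(codes))
  rules <- lapply(bodies, function(b) {
    out <- character(length(b))
    pos <- b > 0L
    out[pos] <- terminals[b[pos]]
    out[!pos] <- paste0("#", -b[!pos])
    out
  })
  names(rules) <- c("S", as.character(seq_len(length(rules) - 1L)))
  structure(list(rules = rules, terminals = terminals),
            class = "sequitur_grammar")
}

#' @export
print.sequitur_grammar <- function(x, ...) {
  cat(sprintf("<sequitur_grammar> %d rule(s), %d terminal(s)\n",
              length(x$rules), length(x$terminals)))
  for (nm in names(x$rules))
    cat(sprintf("  %s -> %s\n", nm, paste(x$rules[[nm]], collapse = " ")))
  invisible(x)
}

is_nonterminal <- function(tok) startsWith(tok, "#")

#' Expand a grammar symbol to its terminal sequence
#'
#' Repeatedly replaces non-terminal references by their rule bodies until
#' only terminals remain. Expanding `"S"` reproduces the original input.
#'
#' @param g A [induce_grammar()] result.
#' @param s A symbol: a terminal label, `"S"`, a rule name (`"1"`, ...) or a
#'   rule reference (`"#1"`, ...).
#' @return Character vector of terminal symbols.
#' @export
expand_rule <- function(g, s) {
  stopifnot(inherits(g, "sequitur_grammar"))
  key <- if (is_nonterminal(s)) substring(s, 2L) else s
  if (!key %in% names(g$rules)) {
    if (is_nonterminal(s)) stop("unknown non-terminal: ", s)
    return(s)  # a terminal expands to itself
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(k) {
    if (!is.null(memo[[k]])) return(memo[[k]])
    out <- unlist(lapply(g$rules[[k]], function(tok) {
      if (is_nonterminal(tok)) rec(substring(tok, 2L)) else tok
    }), use.names = FALSE)
    memo[[k]] <- out
    out
  }
  rec(key)
}

#' Occurrence count of a grammar symbol
#'
#' The number of times a rule's expansion occurs in the original input, as
#' implied by the grammar: the start rule `S` occurs once, and any other
#' symbol occurs once for each occurrence of every rule body that references
#' it (occurrences within one body each contribute).
#'
#' @inheritParams expand_rule
#' @return A positive integer count (for a terminal, the number of times it
#'   appears in the input).
#' @export
occurrence_count <- function(g, s) {
  stopifnot(inherits(g, "sequitur_grammar"))
  key <- if (is_nonterminal(s)) substring(s, 2L) else s
  if (!key %in% names(g$rules) && !key %in% g$terminals)
    stop("unknown symbol: ", s)
  counts <- occurrence_counts(g)
  if (key %in% names(counts)) return(counts[[key]])
  # terminal: sum over rule bodies referencing it
  tot <- 0L
  for (nm in names(g$rules))
    tot <- tot + sum(g$rules[[nm]] == key) * counts[[nm]]
  tot
}

#' All rule occurrence counts of a grammar
#'
#' @inheritParams expand_rule
#' @return Named integer vector of counts, one per rule (including `"S"`).
#' @export
occurrence_counts <- function(g) {
  stopifnot(inherits(g, "sequitur_grammar"))
  memo <- new.env(parent = emptyenv())
  # reverse index: for each rule, how often is it referenced in each body
  refs <- lapply(names(g$rules), function(nm) {
    body <- g$rules[[nm]]
    nts <- body[is_nonterminal(body)]
    if (length(nts) == 0L) return(integer(0))
    table(substring(nts, 2L))
  })
  names(refs) <- names(g$rules)
  rec <- function(k) {
    if (k == "S") return(1L)
    if (!is.null(memo[[k]])) return(memo[[k]])
    tot <- 0L
    for (nm in names(refs)) {
      mult <- refs[[nm]][k]
      if (!is.na(mult) && mult > 0L) tot <- tot + mult * rec(nm)
    }
    memo[[k]] <- as.integer(tot)
    memo[[k]]
  }
  out <- vapply(names(g$rules), rec, integer(1))
  names(out) <- names(g$rules)
  out
}

#' Structural invariants of an induced grammar
#'
#' Post-hoc checks of the two properties Sequitur maintains, plus the
#' compression bound (total grammar size cannot exceed the input length).
#'
#' @inheritParams expand_rule
#' @return A list with logical `digram_uniqueness` and `rule_utility`, and
#'   integer `size` (sum of rule body lengths).
#' @export
grammar_properties <- function(g) {
  stopifnot(inherits(g, "sequitur_grammar"))
  # Two occurrences of the same digram can overlap only inside a run of
  # identical symbols (e.g. `b b b`); Sequitur leaves such overlaps alone,
  # so only non-overlapping occurrences count (greedy within each run).
  digrams <- unlist(lapply(g$rules, function(body) {
    if (length(body) < 2L) return(character(0))
    d <- paste(body[-length(body)], body[-1L], sep = "\r")
    keep <- logical(length(d))
    for (i in seq_along(d))
      keep[i] <- !(i > 1L && d[i] == d[i - 1L] && keep[i - 1L])
    d[keep]
  }), use.names = FALSE)
  refs <- unlist(lapply(g$rules, function(body)
    body[is_nonterminal(body)]), use.names = FALSE)
  ref_counts <- table(substring(refs, 2L))
  non_start <- setdiff(names(g$rules), "S")
  list(digram_uniqueness = !anyDuplicated(digrams),
       rule_utility = all(non_start %in% names(ref_counts)) &&
         all(ref_counts[non_start] >= 2L),
       size = sum(lengths(g$rules)))
}
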