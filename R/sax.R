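#' Fit SAX discretization bins
#'
#' Bins are fitted once on values pooled across all subjects so that every
#' recording is discretized against the same alphabet. Two modes are
#' supported:
#' \describe{
#'   \item{`normal_quantile`}{breakpoints equiprobable under a normal
#'     distribution with the mean and standard deviation of the pooled data
#'     (the classic SAX breakpoints): the interior limits are
#'     `mean + sd * qnorm(i/alpha)` for `i = 1..alpha-1`, and the bottom bin
#'     extends to `-Inf`;}
#'   \item{`equal_width`}{`alpha` equal-width bins spanning the pooled
#'     `[min, max]` range, reproducing a regular zone grid (e.g. the 5 x 5
#'     zone division used by T-pattern analyses).}
#' }
#' Each bin is represented by the lower limit of its value range.
#'
#' @param pooled_values Numeric vector of pooled raw values.
#' @param alpha Number of bins (the alphabet size per dimension).
#' @param mode `"normal_quantile"` or `"equal_width"`.
#' @return An object of class `"sax_bins"` with fields `mode`,
#'   `lower_limits` (length `alpha`, ascending), `fitted_mean`, `fitted_sd`.
#' @export
fit_bins <- function(pooled_values, alpha,
                     mode = c("normal_quantile", "equal_width")) {
  mode <- match.arg(mode)
  v <- pooled_values[is.finite(pooled_values)]
  if (length(v) < 1L) stop("no finite values to fit bins on")
  alpha <- as.integer(alpha)
  if (is.na(alpha) || alpha < 1L) stop("alpha must be a positive integer")
  m <- mean(v)
  s <- stats::sd(v)
  if (mode == "normal_quantile") {
    if (!is.finite(s) || s == 0)
      stop("degenerate data: pooled standard deviation is zero")
    limits <- c(-Inf, m + s * stats::qnorm(seq_len(alpha - 1L) / alpha))
  } else {
    lo <- min(v); hi <- max(v)
    if (hi == lo) hi <- lo + 1  # constant data: one informative bin
    limits <- seq(lo, hi, length.out = alpha + 1L)[seq_len(alpha)]
  }
  structure(list(mode = mode, lower_limits = limits,
                 fitted_mean = m, fitted_sd = if (is.finite(s)) s else 0),
            class = "sax_bins")
}

#' @export
print.sax_bins <- function(x, ...) {
  cat(sprintf("<sax_bins> %s, alpha = %d, lower limits: %s\n", x$mode,
              length(x$lower_limits),
              paste(signif(x$lower_limits, 4), collapse = " ")))
  invisible(x)
}

#' Piecewise aggregate approximation
#'
#' Slices `x` into windows of `w` consecutive values and replaces each
#' window by its mean. When the length of `x` is not a multiple of `w`, `x`
#' is padded with its last value until it is, so the output always has
#' `ceiling(length(x) / w)` values.
#'
#' @param x Numeric vector.
#' @param w Window size in frames.
#' @return Numeric vector of window means.
#' @export
paa <- function(x, w) {
  if (length(x) < 1L) stop("empty input series")
  w <- as.integer(w)
  if (is.na(w) || w < 1L) stop("w must be a positive integer")
  n_out <- ceiling(length(x) / w)
  pad <- n_out * w - length(x)
  if (pad > 0L) x <- c(x, rep(x[length(x)], pad))
  colMeans(matrix(x, nrow = w))
}

#' Map values to bin labels
#'
#' Each value is replaced by the label (`0` to `alpha - 1`) of the bin it
#' falls into. Bins are half-open `[lower, upper)`; the bottom bin extends
#' to `-Inf` and the top bin to `+Inf`, so every real value maps to a label
#' and the mapping is monotone.
#'
#' @param values Numeric vector.
#' @param bins A [fit_bins()] object.
#' @return A [symbol_series()] of arity 1.
#' @export
discretize <- function(values, bins) {
  stopifnot(inherits(bins, "sax_bins"))
  alpha <- length(bins$lower_limits)
  labels <- findInterval(values, bins$lower_limits[-1L])
  symbol_series(as.character(labels), arity = 1L, alphabet_size = alpha)
}

#' SAX transform of a real-valued series
#'
#' Symbolic Aggregate Approximation: [paa()] windowed averaging followed by
#' [discretize()] against pre-fitted bins.
#'
#' @param x Numeric vector.
#' @param w Window size in frames.
#' @param bins A [fit_bins()] object.
#' @return A [symbol_series()] of length `ceiling(length(x) / w)`.
#' @export
sax_transform <- function(x, w, bins) discretize(paa(x, w), bins)

#' Construct a symbol series
#'
#' The discrete output of SAX: a sequence of bin labels (arity 1) or of
#' paired labels `"i:j"` for two jointly discretized dimensions (arity 2).
#'
#' @param symbols Character vector of labels.
#' @param arity 1 for single labels, 2 for label pairs.
#' @param alphabet_size Number of distinct possible symbols.
#' @return An object of class `"symbol_series"` (a character vector with
#'   attributes `arity` and `alphabet_size`).
#' @export
symbol_series <- function(symbols, arity = 1L, alphabet_size = NA_integer_) {
  structure(as.character(symbols), arity = as.integer(arity),
            alphabet_size = as.integer(alphabet_size),
            class = "symbol_series")
}

#' @export
print.symbol_series <- function(x, ...) {
  cat(sprintf("<symbol_series> %d symbols (arity %d, alphabet %s)\n",
              length(x), attr(x, "arity"), attr(x, "alphabet_size")))
  if (length(x) > 0L)
    cat(" ", paste(utils::head(unclass(x), 20L), collapse = " "),
        if (length(x) > 20L) "..." else "", "\n")
  invisible(x)
}

#' @export
`[.symbol_series` <- function(x, i) {
  symbol_series(unclass(x)[i], arity = attr(x, "arity"),
                alphabet_size = attr(x, "alphabet_size"))
}

#' Pair two per-dimension symbol series
#'
#' A 2-D relation (e.g. absolute position) is discretized per dimension and
#' the two label series are recombined into one series of `"i:j"` pairs,
#' each pair treated downstream as a single symbol over an alphabet of
#' `alpha^2`.
#'
#' @param sx,sy Arity-1 [symbol_series()] of equal length.
#' @return An arity-2 [symbol_series()].
#' @export
pair_dimensions <- function(sx, sy) {
  if (length(sx) != length(sy))
    stop("symbol series lengths differ")
  stopifnot(attr(sx, "arity") == 1L, attr(sy, "arity") == 1L)
  a <- attr(sx, "alphabet_size")
  b <- attr(sy, "alphabet_size")
  symbol_series(if (length(sx)) paste(unclass(sx), unclass(sy), sep = ":")
                else character(0),
                arity = 2L, alphabet_size = a * b)
}

#' Entropy of symbol visit proportions
#'
#' Shannon entropy (base 2) of the empirical symbol-frequency distribution
#' of a series. Higher entropy means visits are spread more uniformly over
#' the bins; a uniform distribution over `alpha` symbols attains
#' `log2(alpha)` bits.
#'
#' @param s A [symbol_series()] (or plain character vector).
#' @return Entropy in bits.
#' @export
visit_entropy <- function(s) {
  if (length(s) < 1L) stop("empty symbol series")
  p <- table(unclass(s)) / length(s)
  p <- p[p > 0]
  -sum(p * log2(p))
}
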