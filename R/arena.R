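#' Specify an open-field arena
#'
#' The arena is a square of side `side` cm with a small number of fixed
#' objects placed on it to encourage exploration. The default reproduces a
#' common open-field layout: a 200 x 200 cm area (a 160 cm physical table
#' plus a 20 cm virtual margin on each side) with four objects arranged
#' symmetrically.
#'
#' @param side Side length of the square arena in cm.
#' @param objects Two-column matrix (or list of `c(x, y)` pairs) of object
#'   centre positions in cm; all must lie strictly inside the arena.
#' @return An object of class `"arena_spec"`.
#' @export
arena_spec <- function(side = 200,
                       objects = rbind(c(60, 60), c(60, 140),
                                       c(140, 60), c(140, 140))) {
  if (!is.numeric(side) || side <= 0) stop("side must be positive")
  if (is.list(objects)) objects <- do.call(rbind, objects)
  objects <- matrix(as.numeric(objects), ncol = 2)
  if (nrow(objects) > 0 &&
      (any(objects <= 0) || any(objects >= side)))
    stop("object centres must lie strictly inside the arena")
  structure(list(side = side, objects = objects), class = "arena_spec")
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf("<arena_spec> %g x %g cm, %d objects\n",
              x$side, x$side, nrow(x$objects)))
  invisible(x)
}

#' Read / write an arena specification as JSON
#'
#' Format: `{"side": 200, "objects": [[x, y], ...]}`.
#'
#' @param path JSON file path.
#' @return [read_arena()] returns an [arena_spec()]; [write_arena()] returns
#'   `path` invisibly.
#' @export
read_arena <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  arena_spec(side = j$side, objects = j$objects)
}

#' @rdname read_arena
#' @param a An [arena_spec()].
#' @export
write_arena <- function(a, path) {
  stopifnot(inherits(a, "arena_spec"))
  jsonlite::write_json(list(side = a$side, objects = a$objects), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

relation_series <- function(name, dims, values) {
  structure(list(name = name, dims = dims,
                 values = matrix(values, ncol = dims)),
            class = "relation_series")
}

#' @export
print.relation_series <- function(x, ...) {
  cat(sprintf("<relation_series> %s: %d frames x %d dim(s)\n",
              x$name, nrow(x$values), x$dims))
  invisible(x)
}

#' Spatial relations of a trajectory
#'
#' Reparameterise a position trajectory with respect to the arena. Four
#' relations are available:
#' \describe{
#'   \item{`absolute_position`}{the Cartesian `(x, y)` location (2-D);}
#'   \item{`relative_position`}{the per-frame displacement
#'     `(x_i - x_{i-1}, y_i - y_{i-1})` (2-D), prepended with `(0, 0)` so
#'     all relations share the trajectory length;}
#'   \item{`nearest_object`}{Euclidean distance to the nearest object
#'     centre (1-D);}
#'   \item{`nearest_boundary`}{distance to the nearest point on the arena
#'     boundary, `min(x, y, side - x, side - y)` (1-D).}
#' }
#'
#' @param t A cleaned [trajectory()].
#' @param arena An [arena_spec()].
#' @param relations Character vector of relation names to compute.
#' @return A named list of relation series.
#' @export
spatial_relations <- function(t, arena = arena_spec(),
                              relations = c("absolute_position",
                                            "relative_position",
                                            "nearest_object",
                                            "nearest_boundary")) {
  relations <- match.arg(relations, several.ok = TRUE)
  out <- list()
  for (r in relations) {
    out[[r]] <- switch(r,
      absolute_position = absolute_position(t),
      relative_position = relative_position(t),
      nearest_object = nearest_object_distance(t, arena),
      nearest_boundary = nearest_boundary_distance(t, arena))
  }
  out
}

#' @rdname spatial_relations
#' @export
absolute_position <- function(t) {
  stopifnot(inherits(t, "trajectory"))
  relation_series("absolute_position", 2L, cbind(t$x, t$y))
}

#' @rdname spatial_relations
#' @export
relative_position <- function(t) {
  stopifnot(inherits(t, "trajectory"))
  if (length(t$x) < 2L) stop("relative position needs at least 2 frames")
  relation_series("relative_position", 2L,
                  cbind(c(0, diff(t$x)), c(0, diff(t$y))))
}

#' @rdname spatial_relations
#' @export
nearest_object_distance <- function(t, arena = arena_spec()) {
  stopifnot(inherits(t, "trajectory"), inherits(arena, "arena_spec"))
  if (nrow(arena$objects) == 0L)
    stop("arena has no objects; nearest_object is undefined")
  d2 <- sapply(seq_len(nrow(arena$objects)), function(i) {
    (t$x - arena$objects[i, 1])^2 + (t$y - arena$objects[i, 2])^2
  })
  d2 <- matrix(d2, nrow = length(t$x))
  relation_series("nearest_object", 1L, sqrt(apply(d2, 1L, min)))
}

#' @rdname spatial_relations
#' @export
nearest_boundary_distance <- function(t, arena = arena_spec()) {
  stopifnot(inherits(t, "trajectory"), inherits(arena, "arena_spec"))
  side <- arena$side
  x <- t$x; y <- t$y
  tol <- 1e-6
  if (any(x < -tol | x > side + tol | y < -tol | y > side + tol))
    stop("positions outside the arena square")
  x <- pmin(pmax(x, 0), side)
  y <- pmin(pmax(y, 0), side)
  relation_series("nearest_boundary", 1L, pmin(x, y, side - x, side - y))
}
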