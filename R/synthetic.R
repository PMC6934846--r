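#' Specify a synthetic open-field cohort
#'
#' Describes a two-class cohort of simulated open-field sessions: a control
#' class that explores the arena (a smoothed correlated random walk with
#' occasional object visits) and a case class that, with probability
#' `repetition_strength` per behavioural bout, performs stereotyped cyclic
#' loops between a fixed pair of objects — the synthetic analogue of
#' repetitive object-checking behaviour. With `repetition_strength = 0` the
#' two classes are generated by the identical process and are statistically
#' indistinguishable.
#'
#' @param n_per_class Subjects per class (one session each).
#' @param session_s Session duration in seconds (default 1800 s = 30 min).
#' @param frame_interval Frame interval in seconds (default 0.040 s).
#' @param arena An [arena_spec()].
#' @param repetition_strength Probability in `[0, 1]` that a case bout is a
#'   stereotyped loop (default 0.8).
#' @param noise_sd Positional jitter of the loop path in cm (default 2).
#' @param seed Integer seed; identical spec and seed give a bit-identical
#'   cohort.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_per_class = 10L, session_s = 1800,
                        frame_interval = 0.040, arena = arena_spec(),
                        repetition_strength = 0.8, noise_sd = 2,
                        seed = 1L) {
  stopifnot(n_per_class >= 1L, session_s > 0, frame_interval > 0,
            inherits(arena, "arena_spec"),
            repetition_strength >= 0, repetition_strength <= 1,
            noise_sd >= 0)
  if (nrow(arena$objects) < 2L)
    stop("the cohort generator needs at least 2 objects in the arena")
  structure(list(n_per_class = as.integer(n_per_class),
                 session_s = session_s, frame_interval = frame_interval,
                 arena = arena, repetition_strength = repetition_strength,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a labelled synthetic cohort
#'
#' Simulates one session per subject according to a [cohort_spec()].
#' Sessions are concatenations of behavioural bouts drawn from a two-state
#' process:
#' \describe{
#'   \item{explore}{a correlated random walk — speed fluctuating around
#'     15 cm/s, heading driven by an AR(1) turning process — folded back
#'     into the arena by reflection;}
#'   \item{object visit}{(30\% of non-loop bouts) straight travel to a
#'     random object followed by a few seconds orbiting it;}
#'   \item{loop}{(case subjects, probability `repetition_strength` per
#'     bout) stereotyped circuit between the first two arena objects —
#'     orbit one object, cross to the other, orbit, return — traversed at
#'     constant speed with `noise_sd` positional jitter.}
#' }
#' All positions lie inside the arena square. Controls are labelled
#' `"control"`, cases `"case"`.
#'
#' @param spec A [cohort_spec()].
#' @return A [trajectory_set()] of `2 * n_per_class` sessions.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_frames <- as.integer(round(spec$session_s / spec$frame_interval))
  with_seed(spec$seed, {
    sessions <- list()
    for (cl in c("control", "case")) {
      p_rep <- if (cl == "case") spec$repetition_strength else 0
      for (i in seq_len(spec$n_per_class)) {
        sid <- sprintf("%s%02d", cl, i)
        xy <- .km_simulate_session(n_frames, spec, p_rep)
        sessions[[length(sessions) + 1L]] <-
          trajectory(xy[, 1L], xy[, 2L],
                     frame_interval = spec$frame_interval,
                     subject_id = sid, session_id = paste0(sid, "_d1"),
                     class_label = cl)
      }
    }
    trajectory_set(sessions)
  })
}

# One session: draw bouts until n_frames positions exist.
.km_simulate_session <- function(n_frames, spec, p_rep) {
  dt <- spec$frame_interval
  side <- spec$arena$side
  loop_path <- .km_loop_path(spec$arena, dt)
  pos <- stats::runif(2L, 0.3 * side, 0.7 * side)
  heading <- stats::runif(1L, 0, 2 * pi)
  out <- matrix(NA_real_, n_frames, 2L)
  filled <- 0L
  while (filled < n_frames) {
    u <- stats::runif(1L)
    if (u < p_rep) {
      blk <- .km_bout_loop(pos, loop_path, dt, spec$noise_sd)
    } else if (stats::runif(1L) < 0.3) {
      blk <- .km_bout_visit(pos, spec$arena, dt)
    } else {
      blk <- .km_bout_explore(pos, heading, side, dt)
      heading <- blk$heading
    }
    take <- min(nrow(blk$xy), n_frames - filled)
    out[filled + seq_len(take), ] <- blk$xy[seq_len(take), , drop = FALSE]
    pos <- out[filled + take, ]
    filled <- filled + take
  }
  out[, 1L] <- pmin(pmax(out[, 1L], 0), side)
  out[, 2L] <- pmin(pmax(out[, 2L], 0), side)
  out
}

# Fold an unconstrained coordinate into [0, side] by reflection.
.km_fold <- function(p, side) {
  m <- p %% (2 * side)
  ifelse(m > side, 2 * side - m, m)
}

# Correlated random walk: AR(1) turning increments, fluctuating speed.
.km_bout_explore <- function(pos, heading, side, dt,
                             mean_s = 20, phi = 0.97) {
  nf <- max(25L, as.integer(round(stats::rexp(1L, 1 / mean_s) / dt)))
  turn <- as.numeric(stats::filter(stats::rnorm(nf, 0, 0.25), phi,
                                   method = "recursive"))
  h <- heading + cumsum(turn)
  v <- pmax(0, stats::rnorm(nf, 15, 5)) * dt
  x <- .km_fold(pos[1L] + cumsum(v * cos(h)), side)
  y <- .km_fold(pos[2L] + cumsum(v * sin(h)), side)
  list(xy = cbind(x, y), heading = h[nf])
}

# Straight travel to a random object, then a short orbit around it.
.km_bout_visit <- function(pos, arena, dt, speed = 20, radius = 8) {
  j <- sample.int(nrow(arena$objects), 1L)
  obj <- arena$objects[j, ]
  ang <- stats::runif(1L, 0, 2 * pi)
  target <- obj + radius * c(cos(ang), sin(ang))
  d <- sqrt(sum((target - pos)^2))
  nt <- max(2L, as.integer(ceiling(d / (speed * dt))))
  frac <- seq_len(nt) / nt
  travel <- cbind(pos[1L] + frac * (target[1L] - pos[1L]),
                  pos[2L] + frac * (target[2L] - pos[2L]))
  dwell <- max(25L, as.integer(round(stats::rexp(1L, 1 / 5) / dt)))
  omega <- speed / radius * dt
  th <- ang + seq_len(dwell) * omega
  orbit <- cbind(obj[1L] + radius * cos(th), obj[2L] + radius * sin(th))
  xy <- rbind(travel, orbit)
  xy <- xy + stats::rnorm(length(xy), 0, 0.3)
  list(xy = xy)
}

# Fixed stereotyped circuit between the first two objects: orbit object A,
# cross to object B, orbit, cross back. Returns evenly spaced waypoints.
.km_loop_path <- function(arena, dt, speed = 25, radius = 12) {
  a <- arena$objects[1L, ]
  b <- arena$objects[2L, ]
  arc <- function(ctr, from, len) {
    th <- from + seq(0, len, by = 0.05)
    cbind(ctr[1L] + radius * cos(th), ctr[2L] + radius * sin(th))
  }
  base <- atan2(b[2L] - a[2L], b[1L] - a[1L])
  path <- rbind(arc(a, base + pi / 2, 1.5 * pi),
                arc(b, base - pi / 2, 1.5 * pi))
  # resample to constant speed
  seg <- sqrt(rowSums(diff(path)^2))
  s <- c(0, cumsum(seg))
  step <- speed * dt
  at <- seq(0, s[length(s)], by = step)
  cbind(stats::approx(s, path[, 1L], xout = at)$y,
        stats::approx(s, path[, 2L], xout = at)$y)
}

# One loop bout: travel to the path, then follow it cyclically with jitter.
.km_bout_loop <- function(pos, loop_path, dt, noise_sd,
                          speed = 25, mean_s = 15) {
  d0 <- sqrt(rowSums((loop_path - matrix(pos, nrow(loop_path), 2L,
                                         byrow = TRUE))^2))
  entry <- which.min(d0)
  nt <- max(2L, as.integer(ceiling(d0[entry] / (speed * dt))))
  frac <- seq_len(nt) / nt
  travel <- cbind(pos[1L] + frac * (loop_path[entry, 1L] - pos[1L]),
                  pos[2L] + frac * (loop_path[entry, 2L] - pos[2L]))
  nf <- max(50L, as.integer(round(stats::rexp(1L, 1 / mean_s) / dt)))
  idx <- (entry - 1L + seq_len(nf) - 1L) %% nrow(loop_path) + 1L
  xy <- rbind(travel, loop_path[idx, , drop = FALSE])
  xy <- xy + stats::rnorm(length(xy), 0, noise_sd)
  list(xy = xy)
}

#' Worked 12-symbol example sequence
#'
#' The classic grammar-induction demonstration input
#' `a b c a b d a b c a b d`: inducing a grammar on it yields a rule for
#' the digram `a b` (occurring 4 times) and a rule for the 6-symbol
#' sequence `a b c a b d` (occurring twice).
#'
#' @return A [symbol_series()] of length 12 over the alphabet
#'   `a, b, c, d`.
#' @export
make_table1_sequence <- function() {
  symbol_series(rep(c("a", "b", "c", "a", "b", "d"), 2L),
                arity = 1L, alphabet_size = 4L)
}
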