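#' Construct a trajectory
#'
#' A trajectory holds the per-frame position of one subject during one
#' recording session (or one segment of it): a regularly sampled series of
#' `(x, y)` coordinates in centimetres, in an arena-local frame with the
#' origin at the lower-left corner of the arena, x rightward and y upward.
#'
#' @param x,y Numeric vectors of positions in cm (may contain `NA`/non-finite
#'   markers before cleaning).
#' @param frame_interval Sampling interval in seconds (default 0.040 s, the
#'   frame rate of typical overhead video tracking).
#' @param times Optional vector of frame times in seconds; defaults to
#'   `0, frame_interval, 2*frame_interval, ...`.
#' @param subject_id,session_id,class_label Identifier strings; `class_label`
#'   names the experimental group the subject belongs to.
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(x, y, frame_interval = 0.040, times = NULL,
                       subject_id = "subject", session_id = "session",
                       class_label = NA_character_) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 1L) stop("empty trajectory")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be a positive number of seconds")
  if (is.null(times)) {
    times <- (seq_along(x) - 1L) * frame_interval
  } else {
    times <- as.numeric(times)
    if (length(times) != length(x)) stop("times must match x/y in length")
  }
  structure(
    list(subject_id = as.character(subject_id),
         session_id = as.character(session_id),
         class_label = as.character(class_label),
         frame_interval = frame_interval,
         times = times, x = x, y = y),
    class = "trajectory")
}

#' @export
length.trajectory <- function(x) length(x$x)

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s / %s (%s): %d frames @ %.3f s (%.1f s)\n",
              x$subject_id, x$session_id, x$class_label, length(x$x),
              x$frame_interval, length(x$x) * x$frame_interval))
  invisible(x)
}

#' Read a trajectory from CSV
#'
#' Expects one row per video frame with columns for time (seconds) and the
#' x/y position (cm). Column names are configurable through `dialect` so
#' that exports from tracking software with different headers can be read.
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect Named list mapping the roles `time`, `x`, `y` to column
#'   names in the file.
#' @param frame_interval Frame interval in seconds; if `NULL`, inferred from
#'   the median spacing of the time column.
#' @inheritParams trajectory
#' @return A [trajectory()] with raw (possibly still missing) positions.
#' @export
read_trajectory <- function(path,
                            dialect = list(time = "time_s", x = "x_cm",
                                           y = "y_cm"),
                            frame_interval = NULL,
                            subject_id = "subject", session_id = NULL,
                            class_label = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (role in c("time", "x", "y")) {
    col <- dialect[[role]]
    if (is.null(col) || !col %in% names(raw))
      stop(sprintf("format error: column for '%s' (%s) not found in %s",
                   role, if (is.null(col)) "<unset>" else col, path))
  }
  if (nrow(raw) == 0L) stop("empty trajectory: ", path)
  num <- function(role) {
    v <- raw[[dialect[[role]]]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !is.na(v) & !(trimws(as.character(v)) %in%
                                              c("", "NA", "NaN", "nan")))
    if (length(bad) > 0L)
      stop(sprintf("parse error: non-numeric value '%s' in column %s, row %d",
                   v[bad[1L]], dialect[[role]], bad[1L]))
    out
  }
  times <- num("time")
  if (is.null(frame_interval)) {
    frame_interval <- if (length(times) > 1L)
      stats::median(diff(times)) else 0.040
  }
  if (is.null(session_id))
    session_id <- sub("\\.[^.]*$", "", basename(path))
  trajectory(num("x"), num("y"), frame_interval = frame_interval,
             times = times, subject_id = subject_id,
             session_id = session_id, class_label = class_label)
}

#' Write a trajectory to CSV
#'
#' Inverse of [read_trajectory()] for the default dialect: writes columns
#' `time_s,x_cm,y_cm` with full precision, so a read/write round trip
#' reproduces finite values exactly.
#'
#' @param t A [trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(t, path) {
  stopifnot(inherits(t, "trajectory"))
  df <- data.frame(time_s = format(t$times, digits = 17, trim = TRUE,
                                   scientific = FALSE),
                   x_cm = format(t$x, digits = 17, trim = TRUE),
                   y_cm = format(t$y, digits = 17, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Clean a trajectory by interpolating short tracking gaps
#'
#' Video tracking occasionally loses the subject for a few frames. Runs of
#' non-finite positions of at most `max_gap` consecutive frames are filled
#' by linear interpolation between the neighbouring valid frames; a longer
#' gap makes the recording unusable and the trajectory is rejected with an
#' error of class `"kmotif_gap_error"` carrying the gap location. Leading or
#' trailing invalid runs cannot be interpolated and are trimmed when they
#' are at most `max_gap` frames long (rejected otherwise). Cleaning is
#' idempotent.
#'
#' @param t A [trajectory()].
#' @param max_gap Largest interpolatable gap, in frames (default 25 frames,
#'   i.e. one second at a 0.040 s frame interval).
#' @return A cleaned [trajectory()] with all positions finite.
#' @export
clean_trajectory <- function(t, max_gap = 25L) {
  stopifnot(inherits(t, "trajectory"))
  ok <- is.finite(t$x) & is.finite(t$y)
  if (sum(ok) < 2L) stop("fewer than 2 valid frames")
  if (all(ok)) return(t)

  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  bad <- which(!runs$values)
  for (b in bad) {
    if (runs$lengths[b] > max_gap) {
      cond <- structure(
        class = c("kmotif_gap_error", "error", "condition"),
        list(message = sprintf(
               "gap of %d frames (> max_gap = %d) at frames %d-%d",
               runs$lengths[b], max_gap, starts[b], ends[b]),
             call = sys.call(-1L),
             gap_start = starts[b], gap_end = ends[b],
             gap_length = runs$lengths[b]))
      stop(cond)
    }
  }

  keep <- rep(TRUE, length(ok))
  if (!runs$values[1L]) keep[starts[1L]:ends[1L]] <- FALSE
  if (!runs$values[length(runs$values)]) {
    b <- length(runs$values)
    keep[starts[b]:ends[b]] <- FALSE
  }
  idx <- which(keep)
  x <- t$x[idx]; y <- t$y[idx]; times <- t$times[idx]
  ok2 <- is.finite(x) & is.finite(y)
  if (!all(ok2)) {
    x <- stats::approx(which(ok2), x[ok2], xout = seq_along(x))$y
    y <- stats::approx(which(ok2), y[ok2], xout = seq_along(y))$y
  }
  trajectory(x, y, frame_interval = t$frame_interval, times = times,
             subject_id = t$subject_id, session_id = t$session_id,
             class_label = t$class_label)
}

#' Section a session into fixed-duration segments
#'
#' Splits a trajectory into consecutive non-overlapping segments of exactly
#' `duration` seconds; a trailing remainder shorter than `duration` is
#' dropped. This is used to augment a cohort: a 30-minute session with
#' 10-minute segments yields three data points instead of one.
#'
#' @param t A cleaned [trajectory()].
#' @param duration Segment duration in seconds (default 600 s = 10 min).
#' @return A list of [trajectory()] segments; segment ids are
#'   `<session_id>_seg<i>`.
#' @export
segment_trajectory <- function(t, duration = 600) {
  stopifnot(inherits(t, "trajectory"))
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive")
  if (duration < t$frame_interval)
    stop("duration shorter than one frame interval")
  seg_len <- as.integer(round(duration / t$frame_interval))
  n_seg <- length(t$x) %/% seg_len
  if (n_seg == 0L) return(list())
  lapply(seq_len(n_seg), function(i) {
    idx <- ((i - 1L) * seg_len + 1L):(i * seg_len)
    trajectory(t$x[idx], t$y[idx], frame_interval = t$frame_interval,
               times = t$times[idx], subject_id = t$subject_id,
               session_id = paste0(t$session_id, "_seg", i),
               class_label = t$class_label)
  })
}

#' Bundle trajectories into a labelled data set
#'
#' @param trajectories A list of [trajectory()] objects, each carrying a
#'   class label.
#' @return An object of class `"trajectory_set"` with elements
#'   `trajectories` and `classes` (sorted unique class labels).
#' @export
trajectory_set <- function(trajectories) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  stopifnot(all(vapply(trajectories, inherits, TRUE, "trajectory")))
  labels <- vapply(trajectories, function(t) t$class_label, character(1))
  structure(list(trajectories = trajectories,
                 classes = sort(unique(labels[!is.na(labels)]))),
            class = "trajectory_set")
}

#' @export
length.trajectory_set <- function(x) length(x$trajectories)

#' @export
print.trajectory_set <- function(x, ...) {
  lab <- class_labels(x)
  cat(sprintf("<trajectory_set> %d trajectories, classes: %s\n",
              length(lab), paste(sprintf("%s (%d)", names(table(lab)),
                                         table(lab)), collapse = ", ")))
  invisible(x)
}

#' Class labels of a trajectory set
#' @param data A [trajectory_set()].
#' @return Character vector of per-trajectory class labels.
#' @export
class_labels <- function(data) {
  vapply(data$trajectories, function(t) t$class_label, character(1))
}

#' Segment every session in a set
#'
#' Applies [segment_trajectory()] to each trajectory and returns the pooled
#' segments as a new set.
#'
#' @param data A [trajectory_set()].
#' @inheritParams segment_trajectory
#' @return A [trajectory_set()] of segments.
#' @export
segment_set <- function(data, duration = 600) {
  stopifnot(inherits(data, "trajectory_set"))
  segs <- unlist(lapply(data$trajectories, segment_trajectory,
                        duration = duration), recursive = FALSE)
  trajectory_set(segs)
}
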