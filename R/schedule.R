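#' Frame schedule of a dynamic PET acquisition
#'
#' A frame schedule is the temporal sampling grid of a dynamic scan: frame
#' start times and durations in seconds from injection. Frames must be
#' contiguous (each frame starts where the previous one ends) and
#' non-overlapping, with strictly positive durations.
#'
#' @param start_s numeric vector of frame start times, seconds.
#' @param duration_s numeric vector of frame durations, seconds.
#' @return An object of class `frame_schedule` with fields `start_s`,
#'   `duration_s` and `count`.
#' @examples
#' sched <- frame_schedule(c(0, 6, 12), c(6, 6, 6))
#' sched$count
#' @export
frame_schedule <- function(start_s, duration_s) {
  if (!is.numeric(start_s) || !is.numeric(duration_s))
    stop("frame starts and durations must be numeric", call. = FALSE)
  if (length(start_s) != length(duration_s) || length(start_s) < 1L)
    stop("start_s and duration_s must have equal, positive length", call. = FALSE)
  if (any(!is.finite(start_s)) || any(!is.finite(duration_s)))
    stop("frame times must be finite", call. = FALSE)
  if (any(duration_s <= 0))
    stop("all frame durations must be > 0", call. = FALSE)
  if (start_s[1L] < 0)
    stop("first frame must not start before injection", call. = FALSE)
  n <- length(start_s)
  if (n > 1L) {
    gap <- start_s[-1L] - (start_s[-n] + duration_s[-n])
    if (any(abs(gap) > 1e-9 * max(1, start_s[n])))
      stop("frames must be contiguous and non-overlapping", call. = FALSE)
  }
  structure(list(start_s = as.numeric(start_s),
                 duration_s = as.numeric(duration_s),
                 count = n),
            class = "frame_schedule")
}

#' Default 33-frame, 90-minute schedule
#'
#' The default temporal sampling used throughout the package: 10 x 6 s,
#' 8 x 30 s, 5 x 60 s, 4 x 300 s, 6 x 600 s = 33 frames spanning 5400 s,
#' dense over the bolus and coarse over the washout tail.
#'
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  dur <- c(rep(6, 10), rep(30, 8), rep(60, 5), rep(300, 4), rep(600, 6))
  frame_schedule(cumsum(c(0, dur[-length(dur)])), dur)
}

#' Uniform frame schedule
#'
#' Convenience constructor for evenly spaced frames, mainly used for densely
#' sampled input functions and numerical oracles.
#'
#' @param duration_s frame duration, seconds.
#' @param total_s total span, seconds (must be a multiple of `duration_s`).
#' @return A [frame_schedule()].
#' @export
uniform_frame_schedule <- function(duration_s, total_s) {
  .assert_scalar_num(duration_s, "duration_s", 0, strict = TRUE)
  .assert_scalar_num(total_s, "total_s", 0, strict = TRUE)
  n <- round(total_s / duration_s)
  if (abs(n * duration_s - total_s) > 1e-9)
    stop("total_s must be a multiple of duration_s", call. = FALSE)
  frame_schedule(seq(0, by = duration_s, length.out = n), rep(duration_s, n))
}

# frame end times in seconds
frame_ends <- function(schedule) schedule$start_s + schedule$duration_s

#' Frame midpoints in minutes
#' @param schedule a [frame_schedule()].
#' @return numeric vector of frame midpoints, minutes.
#' @export
frame_midpoints_min <- function(schedule) {
  (schedule$start_s + schedule$duration_s / 2) / 60
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Frame schedule: %d frames, %.1f-%.1f s (%.1f min)\n",
              x$count, x$start_s[1L], frame_ends(x)[x$count],
              frame_ends(x)[x$count] / 60))
  cat("Durations (s):", paste(rle(x$duration_s)$lengths, "x",
                              rle(x$duration_s)$values, collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a frame schedule as delimited text
#'
#' Plain CSV with columns `frame_start_s`, `frame_duration_s`.
#'
#' @param path file path.
#' @param schedule a [frame_schedule()].
#' @return `read_frame_schedule` returns a [frame_schedule()];
#'   `write_frame_schedule` returns `path` invisibly.
#' @export
read_frame_schedule <- function(path) {
  d <- utils::read.csv(path)
  frame_schedule(d$frame_start_s, d$frame_duration_s)
}

#' @rdname read_frame_schedule
#' @export
write_frame_schedule <- function(schedule, path) {
  utils::write.csv(data.frame(frame_start_s = schedule$start_s,
                              frame_duration_s = schedule$duration_s),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

schedules_equal <- function(a, b) {
  a$count == b$count &&
    all(abs(a$start_s - b$start_s) < 1e-9) &&
    all(abs(a$duration_s - b$duration_s) < 1e-9)
}
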