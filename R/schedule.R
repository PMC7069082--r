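#' Dynamic PET frame schedule
#'
#' A contiguous, non-overlapping sequence of acquisition frames following an
#' initial excluded interval (the pre-arrival segment dropped from
#' reconstruction).
#'
#' @param durations_s per-frame durations in seconds (all > 0).
#' @param exclusion_s initial excluded interval in seconds (>= 0).
#' @return object of class `frame_schedule` with elements `frames`
#'   (data.frame with `start_s`, `duration_s`), `exclusion_s`.
#' @export
frame_schedule <- function(durations_s, exclusion_s = 0) {
  durations_s <- as.numeric(durations_s)
  stopifnot(exclusion_s >= 0)
  if (length(durations_s) && any(durations_s <= 0))
    stop("frame durations must be > 0")
  start_s <- if (length(durations_s))
    exclusion_s + cumsum(c(0, utils::head(durations_s, -1))) else numeric(0)
  structure(list(
    frames = data.frame(start_s = start_s, duration_s = durations_s),
    exclusion_s = exclusion_s
  ), class = "frame_schedule")
}

#' Validate an explicit frame table as a schedule
#'
#' Frames given as (start, duration) pairs must tile the axis contiguously
#' after the exclusion interval; overlaps or gaps are errors.
#'
#' @param frames two-column matrix or data.frame of (start_s, duration_s).
#' @param exclusion_s initial excluded interval (s).
#' @export
frame_schedule_from_frames <- function(frames, exclusion_s = 0) {
  frames <- as.data.frame(frames)
  names(frames) <- c("start_s", "duration_s")
  o <- order(frames$start_s)
  frames <- frames[o, , drop = FALSE]
  expected <- exclusion_s + cumsum(c(0, utils::head(frames$duration_s, -1)))
  if (any(abs(frames$start_s - expected) > 1e-9))
    stop("frames overlap or leave gaps: schedule must be contiguous")
  frame_schedule(frames$duration_s, exclusion_s)
}

#' The 31-frame dynamic FDG protocol
#'
#' 20 s exclusion; 10 frames of 5 s, 5 of 10 s, 2 of 15 s, 3 of 60 s,
#' 5 of 120 s, 3 of 5 min, 3 of 10 min — a 60.5 min acquisition.
#' @export
petrus_schedule <- function() {
  frame_schedule(
    c(rep(5, 10), rep(10, 5), rep(15, 2), rep(60, 3), rep(120, 5),
      rep(300, 3), rep(600, 3)),
    exclusion_s = 20
  )
}

#' Total scheduled acquisition time in minutes
#'
#' Exclusion interval plus the sum of frame durations.
#' @param schedule a [frame_schedule()].
#' @export
total_schedule_duration <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  (schedule$exclusion_s + sum(schedule$frames$duration_s)) / 60
}

#' Frame midpoints in seconds
#' @param schedule a [frame_schedule()].
#' @export
frame_midpoints <- function(schedule) {
  schedule$frames$start_s + schedule$frames$duration_s / 2
}

#' Frame end time of the schedule (seconds)
#' @keywords internal
schedule_end_s <- function(schedule) {
  n <- nrow(schedule$frames)
  if (n == 0) return(schedule$exclusion_s)
  schedule$frames$start_s[n] + schedule$frames$duration_s[n]
}

#' Average a finely sampled curve over each frame window
#'
#' The curve is treated as piecewise linear between samples; each frame value
#' is the time average over [start, start + duration].
#'
#' @param times_s sample times (strictly increasing, covering the schedule).
#' @param values curve samples.
#' @param schedule a [frame_schedule()].
#' @return numeric vector, one value per frame.
#' @export
frame_average <- function(times_s, values, schedule) {
  stopifnot(length(times_s) == length(values))
  fr <- schedule$frames
  if (!nrow(fr)) return(numeric(0))
  # cumulative trapezoid integral of the piecewise-linear curve; exact at the
  # sample points (frame boundaries normally coincide with them)
  I <- c(0, cumsum(diff(times_s) *
                     (utils::head(values, -1) + utils::tail(values, -1)) / 2))
  a <- fr$start_s
  b <- a + fr$duration_s
  Ia <- stats::approx(times_s, I, xout = a, rule = 2)$y
  Ib <- stats::approx(times_s, I, xout = b, rule = 2)$y
  (Ib - Ia) / fr$duration_s
}
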