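#' Frame schedules
#'
#' A frame schedule is the time binning of a dynamic PET acquisition: one row
#' per frame with half-open intervals `[frame_start, frame_end)` in seconds.
#' Frames must be strictly ordered with positive durations; gaps between
#' consecutive frames are permitted (they arise naturally in split-session
#' "coffee-break" acquisitions) but overlaps are not.
#'
#' @param frame_start,frame_end Numeric vectors of frame boundaries, seconds.
#' @return A tibble of class `frame_schedule` with columns `frame_start` and
#'   `frame_end` (seconds).
#' @export
#' @examples
#' frame_schedule(c(0, 15, 30), c(15, 30, 60))
frame_schedule <- function(frame_start, frame_end) {
  if (length(frame_start) != length(frame_end)) {
    abort("frame_start and frame_end must have the same length")
  }
  frame_start <- as.numeric(frame_start)
  frame_end <- as.numeric(frame_end)
  if (length(frame_start)) {
    if (any(!is.finite(frame_start)) || any(!is.finite(frame_end))) {
      abort("frame boundaries must be finite")
    }
    if (any(frame_end <= frame_start)) {
      abort("all frame durations must be > 0")
    }
    if (length(frame_start) > 1) {
      if (any(diff(frame_start) <= 0)) {
        abort("frame_start must be strictly increasing")
      }
      if (any(frame_start[-1] < frame_end[-length(frame_end)] - 1e-9)) {
        abort("frames must not overlap")
      }
    }
  }
  out <- tibble::tibble(frame_start = frame_start, frame_end = frame_end)
  class(out) <- c("frame_schedule", class(out))
  out
}

#' Parse a compact frame-schedule specification
#'
#' Parses strings such as `"6x15s,3x30s,3x60s,2x90s,2x180s,9x300s,6x600s"`
#' (the 31-frame, 120-min schedule used for dynamic brain acquisitions) into a
#' [frame_schedule()]. Each comma-separated token is `<count>x<duration><unit>`
#' with unit `s`, `m` or `min`; frames are laid out contiguously from 0.
#'
#' @param spec Character scalar schedule specification.
#' @return A [frame_schedule()].
#' @export
#' @examples
#' sched <- parse_frame_schedule("6x15s,3x30s,3x60s,2x90s,2x180s,9x300s,6x600s")
#' nrow(sched)                     # 31 frames
#' max(sched$frame_end) / 60       # 120 minutes
parse_frame_schedule <- function(spec) {
  if (!is.character(spec) || length(spec) != 1L || is.na(spec) || !nzchar(spec)) {
    abort("schedule specification must be a non-empty string")
  }
  tokens <- strsplit(gsub("\\s", "", spec), ",", fixed = TRUE)[[1]]
  durations <- unlist(lapply(tokens, function(tok) {
    m <- regmatches(tok, regexec("^([0-9]+)x([0-9.]+)(s|min|m)$", tok))[[1]]
    if (length(m) != 4L) {
      abort(paste0("malformed frame-schedule token: '", tok, "'"))
    }
    count <- as.integer(m[2])
    dur <- as.numeric(m[3]) * switch(m[4], s = 1, m = 60, min = 60)
    if (is.na(count) || count < 1L || !is.finite(dur) || dur <= 0) {
      abort(paste0("malformed frame-schedule token: '", tok, "'"))
    }
    rep(dur, count)
  }))
  ends <- cumsum(durations)
  frame_schedule(c(0, head(ends, -1)), ends)
}

#' Frame midpoints and durations
#'
#' All numerical routines in the package evaluate frame-binned data at the
#' frame midpoint `(start + end) / 2`.
#'
#' @param schedule A [frame_schedule()] (or any object carrying one, such as a
#'   [tac()]).
#' @return Numeric vector of midpoints (respectively durations), seconds.
#' @export
frame_midpoints <- function(schedule) {
  schedule <- as_schedule(schedule)
  (schedule$frame_start + schedule$frame_end) / 2
}

#' @rdname frame_midpoints
#' @export
frame_durations <- function(schedule) {
  schedule <- as_schedule(schedule)
  schedule$frame_end - schedule$frame_start
}

as_schedule <- function(x) {
  if (inherits(x, "frame_schedule")) return(x)
  if (inherits(x, "tac")) {
    return(frame_schedule(x$frame_start, x$frame_end))
  }
  if (is.data.frame(x) && all(c("frame_start", "frame_end") %in% names(x))) {
    return(frame_schedule(x$frame_start, x$frame_end))
  }
  abort("cannot interpret object as a frame schedule")
}
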