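#' Time-activity curves
#'
#' A time-activity curve (TAC) pairs a [frame_schedule()] with one activity
#' concentration per frame. Brain TACs are conventionally decay-corrected to
#' injection time and expressed in kBq/mL; whole-body organ curves for
#' dosimetry are *not* decay-corrected and are expressed as fraction of
#' injected activity (see the dosimetry functions, which work on plain
#' time/value tables for that reason). Negative frame values are allowed —
#' they occur in low-count reconstructed frames — and are recorded in the
#' `has_negative` attribute.
#'
#' @param schedule A [frame_schedule()].
#' @param activity Numeric vector, one value per frame (kBq/mL).
#' @param label Optional region/organ name.
#' @param decay_corrected Logical; is the curve decay-corrected to the
#'   reference time? Default `TRUE` (the brain-TAC convention).
#' @param reference_time Time (s) activities are decay-corrected to; 0 =
#'   injection.
#' @return A tibble of class `tac` with columns `frame_start`, `frame_end`
#'   (s) and `activity`.
#' @export
#' @examples
#' sched <- parse_frame_schedule("2x15s,1x30s")
#' tac(sched, c(1, 2, 3), label = "cerebellum")
tac <- function(schedule, activity, label = NULL, decay_corrected = TRUE,
                reference_time = 0) {
  schedule <- as_schedule(schedule)
  activity <- as.numeric(activity)
  if (length(activity) != nrow(schedule)) {
    abort("activity length must equal the number of frames")
  }
  if (any(!is.finite(activity))) {
    abort("activity values must be finite")
  }
  out <- tibble::tibble(
    frame_start = schedule$frame_start,
    frame_end = schedule$frame_end,
    activity = activity
  )
  structure(
    out,
    class = c("tac", class(tibble::tibble())),
    label = label,
    decay_corrected = isTRUE(decay_corrected),
    reference_time = reference_time,
    has_negative = any(activity < 0)
  )
}

is_decay_corrected <- function(x) isTRUE(attr(x, "decay_corrected"))

tac_label <- function(x) attr(x, "label")

#' Decay-correct or un-correct a time-activity curve
#'
#' Multiplies (or, with `reverse = TRUE`, divides) each frame value by
#' `2^(t_mid / half_life)` where `t_mid` is the frame midpoint relative to the
#' reference time. Correcting an already-corrected curve (or un-correcting a
#' physical one) is a state error. The operation is an exact involution:
#' correcting then un-correcting returns the input to machine precision.
#'
#' @param x A [tac()].
#' @param half_life_min Radionuclide half-life in minutes (default F-18).
#' @param reverse If `TRUE`, reintroduce physical decay instead of removing it.
#' @return A [tac()] with the `decay_corrected` flag toggled.
#' @export
#' @examples
#' sched <- frame_schedule(0, 2 * 109.771 * 60)  # one frame, midpoint = T1/2
#' physical <- tac(sched, 50, decay_corrected = FALSE)
#' decay_correct(physical)$activity              # 100
decay_correct <- function(x, half_life_min = f18_half_life_min(),
                          reverse = FALSE) {
  stopifnot(inherits(x, "tac"))
  if (!is.numeric(half_life_min) || half_life_min <= 0) {
    abort("half_life_min must be > 0")
  }
  if (!reverse && is_decay_corrected(x)) {
    abort("curve is already decay-corrected (double correction)")
  }
  if (reverse && !is_decay_corrected(x)) {
    abort("curve is not decay-corrected; nothing to reverse")
  }
  t_mid <- frame_midpoints(x) - attr(x, "reference_time")
  factor <- 2^(t_mid / (half_life_min * 60))
  act <- if (reverse) x$activity / factor else x$activity * factor
  tac(as_schedule(x), act,
    label = tac_label(x),
    decay_corrected = !reverse,
    reference_time = attr(x, "reference_time")
  )
}

#' Cumulative integral of a time-activity curve
#'
#' Trapezoid integral of the curve from injection (t = 0) to `t`, treating the
#' frame values as samples at the frame midpoints with an anchored value of 0
#' at t = 0 (no activity pre-injection) and linear interpolation between
#' nodes. Beyond the last midpoint the curve is extended as a constant up to
#' the last frame end. This is the integral used on both Logan axes and by
#' the trapezoid dosimetry routines; it is exact for piecewise-linear data.
#'
#' @param x A [tac()].
#' @param t Time(s) (s) at which to evaluate the running integral; vectorised.
#' @return Numeric vector of integrals, in activity x seconds.
#' @export
#' @examples
#' sched <- parse_frame_schedule("10x60s")
#' cumulative_integral(tac(sched, rep(1, 10)), 600)   # ~ 600
cumulative_integral <- function(x, t) {
  stopifnot(inherits(x, "tac"))
  if (any(t < 0)) abort("integration time must be non-negative")
  mids <- frame_midpoints(x)
  nodes <- c(0, mids)
  vals <- c(0, x$activity)
  t_end <- max(x$frame_end)
  if (t_end > nodes[length(nodes)]) {
    nodes <- c(nodes, t_end)
    vals <- c(vals, vals[length(vals)])
  }
  if (any(t > t_end + 1e-9)) {
    abort("integration time beyond the end of the last frame")
  }
  cums <- cumsum(c(0, diff(nodes) * (head(vals, -1) + tail(vals, -1)) / 2))
  vapply(t, function(ti) {
    i <- findInterval(ti, nodes)
    i <- min(i, length(nodes) - 1L)
    # partial trapezoid within panel i
    v_at_t <- vals[i] + (vals[i + 1] - vals[i]) *
      (ti - nodes[i]) / (nodes[i + 1] - nodes[i])
    cums[i] + (vals[i] + v_at_t) / 2 * (ti - nodes[i])
  }, numeric(1))
}
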