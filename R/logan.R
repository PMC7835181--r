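#' Acquisition windows
#'
#' An acquisition window is an ordered set of disjoint scan segments in
#' minutes, e.g. the full dynamic acquisition `"0-120"`, a truncated session
#' `"0-90"`, or the split-session coffee-break protocol `"0-60,90-120"` (a
#' 60-min session from injection plus a 30-min session starting at 90 min).
#'
#' @param spec Either a string like `"0-60,90-120"` or a 2-column numeric
#'   matrix of (start, end) minutes.
#' @return A 2-column matrix of class `acquisition_window`, minutes.
#' @export
#' @examples
#' acquisition_window("0-60,90-120")
acquisition_window <- function(spec) {
  if (is.character(spec)) {
    segs <- strsplit(spec, ",", fixed = TRUE)[[1]]
    m <- t(vapply(segs, function(s) {
      p <- as.numeric(strsplit(s, "-", fixed = TRUE)[[1]])
      if (length(p) != 2L || any(is.na(p))) {
        abort(paste0("malformed window segment: '", s, "'"))
      }
      p
    }, numeric(2)))
  } else {
    m <- matrix(as.numeric(spec), ncol = 2)
  }
  if (any(m[, 2] <= m[, 1])) abort("window segments must have end > start")
  if (nrow(m) > 1 && any(m[-1, 1] < m[-nrow(m), 2])) {
    abort("window segments must be disjoint and ordered")
  }
  dimnames(m) <- list(NULL, c("start_min", "end_min"))
  structure(m, class = c("acquisition_window", "matrix"))
}

#' Restrict a TAC to an acquisition window
#'
#' Keeps the frames wholly contained in one of the window segments; the
#' resulting schedule may contain a gap (coffee-break). Downstream integrals
#' bridge gaps by linear interpolation between the last retained midpoint
#' before the gap and the first after it (see [cumulative_integral()]).
#'
#' @param x A [tac()].
#' @param window An [acquisition_window()] or a spec accepted by it.
#' @return A [tac()] with the reduced schedule.
#' @export
#' @examples
#' sched <- parse_frame_schedule("6x15s,3x30s,3x60s,2x90s,2x180s,9x300s,6x600s")
#' full <- tac(sched, seq_len(31))
#' nrow(apply_window(full, "0-60,90-120")) # 28 frames
apply_window <- function(x, window) {
  stopifnot(inherits(x, "tac"))
  if (!inherits(window, "acquisition_window")) {
    window <- acquisition_window(window)
  }
  w <- window * 60 # seconds
  keep <- rep(FALSE, nrow(x))
  for (i in seq_len(nrow(w))) {
    keep <- keep | (x$frame_start >= w[i, 1] - 1e-9 &
      x$frame_end <= w[i, 2] + 1e-9)
  }
  if (!any(keep)) abort("window retains no frames")
  tac(
    frame_schedule(x$frame_start[keep], x$frame_end[keep]),
    x$activity[keep],
    label = tac_label(x),
    decay_corrected = is_decay_corrected(x),
    reference_time = attr(x, "reference_time")
  )
}

#' Logan graphical transform
#'
#' Maps a tissue TAC and its plasma input to the Logan coordinates
#' `x_i = int_0^{t_i} C_p dtau / C_t(t_i)` and
#' `y_i = int_0^{t_i} C_t dtau / C_t(t_i)` at the frame midpoints `t_i`.
#' The tissue integral is the anchored trapezoid of [cumulative_integral()];
#' the input integral is the closed form of [integral_input()]. Midpoints
#' with non-positive tissue activity are dropped (count recorded in the
#' `n_dropped` attribute). No blood-volume term is applied (standard Logan
#' formulation).
#'
#' @param x A [tac()].
#' @param input An [input_function()].
#' @return A tibble with `t_min`, `x`, `y` (both axes in minutes).
#' @export
logan_transform <- function(x, input) {
  stopifnot(inherits(x, "tac"), inherits(input, "input_function"))
  mids <- frame_midpoints(x)
  ct <- x$activity
  ok <- ct > 0
  if (!any(ok)) abort("no usable Logan points: tissue activity never positive")
  int_ct <- cumulative_integral(x, mids[ok])
  int_cp <- integral_input(input, mids[ok], "parent_plasma")
  out <- tibble::tibble(
    t_min = mids[ok] / 60,
    x = int_cp / ct[ok] / 60,
    y = int_ct / ct[ok] / 60
  )
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Fit the Logan plot
#'
#' Ordinary least squares on the Logan points with midpoint time at or after
#' `t_star`; the slope is reported as VT. `t_star = 40` min is the default
#' used throughout for this tracer.
#'
#' @param points A tibble from [logan_transform()].
#' @param t_star_min Start time of the linear segment, minutes.
#' @return An object of class `logan_fit` with `vt`, `intercept` (minutes),
#'   `t_star`, `n_points`, `r_squared` and the included points. Methods:
#'   [tidy()], [glance()], [autoplot()].
#' @export
fit_logan <- function(points, t_star_min = 40) {
  keep <- points$t_min >= t_star_min
  if (sum(keep) < 3L) {
    abort("need at least 3 Logan points at or after t_star")
  }
  pts <- points[keep, , drop = FALSE]
  f <- lm(y ~ x, data = pts)
  ss_tot <- sum((pts$y - mean(pts$y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(f)^2) / ss_tot else 1
  structure(
    list(
      vt = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
      t_star = t_star_min, n_points = nrow(pts),
      r_squared = r2, points = pts,
      all_points = points
    ),
    class = "logan_fit"
  )
}

#' Regional Logan VT in one call
#'
#' Convenience pipeline: optional acquisition window, Logan transform, fit.
#'
#' @inheritParams logan_transform
#' @inheritParams fit_logan
#' @param window Optional [acquisition_window()] spec.
#' @return A `logan_fit`.
#' @export
logan_vt <- function(x, input, t_star_min = 40, window = NULL) {
  if (!is.null(window)) x <- apply_window(x, window)
  fit_logan(logan_transform(x, input), t_star_min = t_star_min)
}

#' @export
tidy.logan_fit <- function(x, ...) {
  tibble::tibble(
    term = c("vt", "intercept"),
    estimate = c(x$vt, x$intercept)
  )
}

#' @export
glance.logan_fit <- function(x, ...) {
  tibble::tibble(
    vt = x$vt, intercept = x$intercept, t_star = x$t_star,
    n_points = x$n_points, r_squared = x$r_squared
  )
}

#' @export
print.logan_fit <- function(x, ...) {
  cat(
    "<logan_fit> VT =", format(x$vt, digits = 4),
    " t* =", x$t_star, "min,",
    x$n_points, "points, r^2 =", format(x$r_squared, digits = 4), "\n"
  )
  invisible(x)
}

#' Voxel-wise Logan VT map
#'
#' Applies the Logan transform and OLS fit to every voxel TAC of a dynamic
#' volume (compiled inner loop). Voxels with non-positive activity at any
#' included midpoint, or with fewer than 3 usable points, become `NaN`.
#'
#' @param volume A [dynamic_volume()].
#' @param input An [input_function()].
#' @param t_star_min Logan start time, minutes.
#' @return A list with `vt` (3D array), `r_squared` (3D array) and
#'   `nan_fraction`.
#' @export
voxelwise_logan <- function(volume, input, t_star_min = 40) {
  stopifnot(inherits(volume, "dynamic_volume"))
  mids <- frame_midpoints(volume$schedule)
  keep <- mids >= t_star_min * 60
  if (sum(keep) < 3L) abort("fewer than 3 frames at or after t_star")
  nf <- length(mids)
  ct <- matrix(volume$data, ncol = nf)
  intcp <- integral_input(input, mids, "parent_plasma")
  res <- logan_slopes(ct, mids, intcp, keep)
  d3 <- dim(volume$data)[1:3]
  vt <- array(res[, 1], dim = d3)
  r2 <- array(res[, 3], dim = d3)
  list(vt = vt, r_squared = r2, nan_fraction = mean(!is.finite(vt)))
}

default_windows <- function() {
  w <- c(
    "0-60/90-120" = "0-60,90-120",
    "0-60" = "0-60", "0-70" = "0-70", "0-80" = "0-80", "0-90" = "0-90",
    "0-100" = "0-100", "0-110" = "0-110", "0-120" = "0-120"
  )
  lapply(w, acquisition_window)
}

#' Time stability of Logan VT under reduced acquisitions
#'
#' For each acquisition window, computes (i) the test-retest variability of
#' windowed Logan VT across the paired scans and (ii) the bias of windowed
#' VT relative to the full 0-120-min value for every cohort scan, then
#' summarises both across regions and subjects as mean, SD and range. The
#' full-window row has no bias by construction.
#'
#' @param trt Tibble of test-retest scans: columns `subject`, `region`,
#'   `scan` (`"test"`/`"retest"`), `tac` (list of [tac()]), `input` (list of
#'   [input_function()]).
#' @param cohort Tibble of single scans: columns `subject`, `region`, `tac`,
#'   `input`.
#' @param windows Named list of [acquisition_window()]s; the default is the
#'   full protocol ladder (coffee-break, truncations 60-110 min, full). The
#'   reference window is the one spanning the full schedule and is detected
#'   as the last window.
#' @param t_star_min Logan start time, minutes.
#' @return A tibble, one row per window: TRV and bias summaries (percent).
#' @export
time_stability_table <- function(trt, cohort, windows = default_windows(),
                                 t_star_min = 40) {
  vt_of <- function(tt, inp, win) {
    logan_vt(tt, inp, t_star_min = t_star_min, window = win)$vt
  }
  ref_name <- names(windows)[length(windows)]
  summarise_vec <- function(v, prefix) {
    out <- tibble::tibble(
      mean = mean(v), sd = sd(v),
      min = min(v), max = max(v)
    )
    names(out) <- paste0(prefix, "_", names(out))
    out
  }
  rows <- purrr::map_dfr(names(windows), function(wn) {
    win <- windows[[wn]]
    # TRV between paired scans under this window
    wide <- tidyr::pivot_wider(
      dplyr::mutate(trt,
        vt = purrr::map2_dbl(.data$tac, .data$input, vt_of, win = win)
      )[, c("subject", "region", "scan", "vt")],
      names_from = "scan", values_from = "vt"
    )
    trv_vals <- trv(wide$test, wide$retest)
    row <- dplyr::bind_cols(
      tibble::tibble(window = wn),
      summarise_vec(trv_vals, "trv")
    )
    if (wn != ref_name) {
      co <- dplyr::mutate(cohort,
        vt_win = purrr::map2_dbl(.data$tac, .data$input, vt_of, win = win),
        vt_full = purrr::map2_dbl(.data$tac, .data$input, vt_of,
          win = windows[[ref_name]]
        )
      )
      bias_vals <- 100 * (co$vt_win - co$vt_full) / co$vt_full
      row <- dplyr::bind_cols(row, summarise_vec(bias_vals, "bias"))
    } else {
      row <- dplyr::bind_cols(row, tibble::tibble(
        bias_mean = NA_real_, bias_sd = NA_real_,
        bias_min = NA_real_, bias_max = NA_real_
      ))
    }
    row
  })
  rows
}
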