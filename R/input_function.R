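#' Fit a tri-exponential curve to arterial blood or plasma samples
#'
#' Arterial whole-blood and total-plasma concentration curves from manual
#' sampling are modelled as a linear rise from 0 at injection to the peak,
#' followed by a tri-exponential decay. The fit applies to the post-peak
#' samples only (the manual early samples are too sparse to constrain an
#' ascending exponential); continuity at the peak is built in because the
#' rise ends at the fitted curve value.
#'
#' The decay is fitted by constrained least squares: rates are optimised in
#' log space while, for each candidate rate set, amplitudes are solved by
#' linear least squares with non-negativity imposed through a small active-set
#' step; a final joint quasi-Newton polish refines all six parameters.
#' Amplitudes are returned sorted by descending rate.
#'
#' @param time_s Sample times, seconds, strictly increasing.
#' @param conc Concentrations, kBq/mL, non-negative.
#' @return An object of class `triexp_curve`: a list with `peak_time`,
#'   `peak_value` (curve value at the peak, = sum of amplitudes),
#'   `amplitudes`, `rates` (1/s, descending) and `rss`.
#' @export
fit_triexponential <- function(time_s, conc) {
  stopifnot(length(time_s) == length(conc))
  if (any(diff(time_s) <= 0)) abort("sample times must be strictly increasing")
  if (any(conc < 0)) abort("concentrations must be non-negative")
  if (all(conc <= 0)) abort("degenerate input: all concentrations are zero")
  ipk <- which.max(conc)
  tp <- time_s[ipk]
  post <- time_s >= tp
  tt <- time_s[post] - tp
  yy <- conc[post]
  if (length(tt) < 8L) abort("need at least 8 post-peak samples")

  span <- max(tt[tt > 0])
  # amplitudes for fixed rates: linear LS with non-negativity (active set)
  amps_for <- function(lam) {
    X <- exp(-outer(tt, lam))
    active <- rep(TRUE, length(lam))
    a <- rep(0, length(lam))
    for (it in 1:4) {
      sol <- tryCatch(
        qr.solve(X[, active, drop = FALSE], yy),
        error = function(e) NULL
      )
      if (is.null(sol)) return(NULL)
      if (all(sol >= 0)) {
        a[active] <- sol
        return(a)
      }
      drop <- which(active)[which.min(sol)]
      active[drop] <- FALSE
      if (!any(active)) return(rep(0, length(lam)))
    }
    a
  }
  obj_rates <- function(loglam) {
    a <- amps_for(exp(loglam))
    if (is.null(a)) return(1e30)
    sum((exp(-outer(tt, exp(loglam))) %*% a - yy)^2)
  }
  # dispersed deterministic starts spanning the sampled time scale
  starts <- list(
    log(c(10, 1, 0.1) / span),
    log(c(30, 3, 0.3) / span),
    log(c(100, 10, 1) / span),
    log(c(5, 1, 0.2) / span),
    log(c(50, 5, 0.05) / span)
  )
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      nlminb(s, obj_rates, control = list(iter.max = 500, rel.tol = 1e-14)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective)) {
      best <- fit
    }
  }
  if (is.null(best)) abort("tri-exponential fit failed to converge")
  lam <- exp(best$par)
  a <- amps_for(lam)
  # joint polish on log(amplitude + eps), log(rate)
  eps <- 1e-12 * max(yy)
  obj_all <- function(p) {
    av <- exp(p[1:3]) - eps
    lv <- exp(p[4:6])
    sum((exp(-outer(tt, lv)) %*% pmax(av, 0) - yy)^2)
  }
  p0 <- c(log(pmax(a, 0) + eps), log(lam))
  pol <- nlminb(p0, obj_all, control = list(iter.max = 1000, rel.tol = 1e-15))
  if (pol$objective <= best$objective + 1e-30) {
    a <- pmax(exp(pol$par[1:3]) - eps, 0)
    lam <- exp(pol$par[4:6])
    rss <- pol$objective
  } else {
    rss <- best$objective
  }
  ord <- order(lam, decreasing = TRUE)
  structure(
    list(
      peak_time = tp, peak_value = sum(a),
      amplitudes = a[ord], rates = lam[ord], rss = rss
    ),
    class = "triexp_curve"
  )
}

# evaluate a triexp_curve (linear rise to peak, tri-exp decay after)
eval_triexp <- function(curve, t) {
  P <- sum(curve$amplitudes)
  tp <- curve$peak_time
  out <- numeric(length(t))
  pre <- t < tp & t >= 0
  post <- t >= tp
  if (tp > 0) out[pre] <- P * t[pre] / tp else out[pre] <- P
  if (any(post)) {
    tt <- t[post] - tp
    out[post] <- drop(exp(-outer(tt, curve$rates)) %*% curve$amplitudes)
  }
  out
}

# closed-form \int_0^t of curve(s) * exp(-k s) ds (k = 0 for uncorrected)
integral_triexp <- function(curve, t, k = 0) {
  P <- sum(curve$amplitudes)
  tp <- curve$peak_time
  rise_int <- function(tt) {
    # \int_0^tt (P s / tp) e^{-k s} ds
    if (tp <= 0) {
      return(if (k > 0) P * (1 - exp(-k * tt)) / k else P * tt)
    }
    if (k > 0) {
      (P / tp) * (1 - exp(-k * tt) * (1 + k * tt)) / k^2
    } else {
      (P / tp) * tt^2 / 2
    }
  }
  vapply(t, function(ti) {
    if (ti <= 0) return(0)
    if (ti <= tp) return(rise_int(ti))
    decay <- sum(curve$amplitudes * exp(-k * tp) *
      (1 - exp(-(curve$rates + k) * (ti - tp))) / (curve$rates + k))
    rise_int(tp) + decay
  }, numeric(1))
}

#' Fit a mono-exponential parent fraction
#'
#' The fraction of plasma radioactivity attributable to intact (parent)
#' tracer is modelled as `f(t) = exp(-k_m t)`, anchored at 1 at injection
#' (no radiometabolites exist at t = 0). The single rate is found by least
#' squares on the measured fractions.
#'
#' @param time_s Measurement times, seconds.
#' @param fraction Measured parent fractions, in \[0, 1\].
#' @return An object of class `parent_fraction`: list with `k_m` (1/s) and
#'   `rss`.
#' @export
#' @examples
#' pf <- fit_parent_fraction(c(300, 1200, 3600), exp(-0.01 / 60 * c(300, 1200, 3600)))
#' pf$k_m * 60  # ~ 0.01 per minute
fit_parent_fraction <- function(time_s, fraction) {
  stopifnot(length(time_s) == length(fraction))
  if (length(fraction) < 3L) abort("need at least 3 parent-fraction measurements")
  if (any(fraction < 0 | fraction > 1)) {
    abort("parent fractions must lie in [0, 1]")
  }
  if (all(fraction >= 1 - 1e-12)) {
    return(structure(list(k_m = 0, rss = 0), class = "parent_fraction"))
  }
  t_min <- time_s / 60 # optimise on the per-minute scale (k ~ 1e-2)
  obj <- function(k) sum((exp(-k * t_min) - fraction)^2)
  # the objective is flat for large k, which defeats plain golden-section
  # search; bracket the minimum on a log grid first, then refine locally
  grid <- c(0, 10^seq(-5, log10(50), length.out = 120))
  vals <- vapply(grid, obj, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- optimize(obj, interval = c(lo, hi), tol = 1e-13)
  if (obj(0) <= opt$objective) opt <- list(minimum = 0, objective = obj(0))
  structure(
    list(k_m = opt$minimum / 60, rss = opt$objective),
    class = "parent_fraction"
  )
}

#' Assemble an arterial input function
#'
#' Bundles the fitted whole-blood and total-plasma curves with the
#' radiometabolite parent-fraction model, a blood-to-tissue delay and an
#' optional plasma free fraction (PFF) record. The metabolite-corrected
#' parent-plasma input driving the tissue models is
#' `plasma(t) * exp(-k_m t)`, so parent plasma never exceeds total plasma.
#' PFF is bookkeeping only; it never rescales VT.
#'
#' @param whole_blood,plasma `triexp_curve` objects from
#'   [fit_triexponential()].
#' @param parent_fraction A `parent_fraction` from [fit_parent_fraction()].
#' @param delay Time shift (s) applied to all components; positive values
#'   delay the input relative to the scanner clock.
#' @param pff Optional plasma free fraction (unitless), stored as metadata.
#' @return An object of class `input_function`.
#' @export
input_function <- function(whole_blood, plasma, parent_fraction,
                           delay = 0, pff = NA_real_) {
  stopifnot(
    inherits(whole_blood, "triexp_curve"),
    inherits(plasma, "triexp_curve"),
    inherits(parent_fraction, "parent_fraction"),
    is.finite(delay)
  )
  structure(
    list(
      whole_blood = whole_blood, plasma = plasma,
      parent_fraction = parent_fraction, delay = delay, pff = pff
    ),
    class = "input_function"
  )
}

#' Evaluate an input function
#'
#' @param input An [input_function()].
#' @param t Times (s), scanner clock; vectorised.
#' @param component One of `"parent_plasma"` (metabolite-corrected, the
#'   default tissue-model input), `"total_plasma"` or `"whole_blood"`.
#' @return Concentrations, kBq/mL; 0 before the delayed injection.
#' @export
evaluate_input <- function(input, t,
                           component = c(
                             "parent_plasma", "total_plasma", "whole_blood"
                           )) {
  component <- match.arg(component)
  ts <- t - input$delay
  out <- numeric(length(ts))
  ok <- ts > 0
  if (!any(ok)) return(out)
  v <- switch(component,
    whole_blood = eval_triexp(input$whole_blood, ts[ok]),
    total_plasma = eval_triexp(input$plasma, ts[ok]),
    parent_plasma = eval_triexp(input$plasma, ts[ok]) *
      exp(-input$parent_fraction$k_m * ts[ok])
  )
  out[ok] <- v
  out
}

#' Closed-form running integral of an input function
#'
#' Integrates the input from injection to `t` using the closed forms of the
#' linear-rise and (metabolite-attenuated) tri-exponential segments: the
#' parent-plasma component is the plasma model with every decay rate shifted
#' by the metabolite rate, so no quadrature is involved. This is the Logan
#' x-axis numerator.
#'
#' @inheritParams evaluate_input
#' @return Integrals in kBq*s/mL; monotone non-decreasing in `t`.
#' @export
integral_input <- function(input, t,
                           component = c(
                             "parent_plasma", "total_plasma", "whole_blood"
                           )) {
  component <- match.arg(component)
  ts <- pmax(t - input$delay, 0)
  switch(component,
    whole_blood = integral_triexp(input$whole_blood, ts, k = 0),
    total_plasma = integral_triexp(input$plasma, ts, k = 0),
    parent_plasma = integral_triexp(input$plasma, ts,
      k = input$parent_fraction$k_m
    )
  )
}

#' Estimate the blood-to-scanner delay from a composite cortical TAC
#'
#' Searches candidate delays between -30 and +30 s ("small time shifts"),
#' refitting a compartment model to the early part of the composite cortical
#' TAC (first 5 min, which the 15-s frames sample densely) for each
#' candidate and minimising the residual sum of squares. A coarse 2-s pass
#' with the cheap one-tissue model brackets the optimum; a fine 0.5-s pass
#' with the two-tissue model (whose extra flexibility removes the early-time
#' model-mismatch bias of the 1TCM) refines it. The delay is estimated once
#' per scan and then held fixed for all regions.
#'
#' @param input An [input_function()] (its current delay is ignored).
#' @param composite_tac A [tac()] averaging the cortical regions.
#' @param range Search bounds, s.
#' @param step Fine grid step, s.
#' @param early_s Early window used for the fits, s.
#' @return The estimated delay (s). A flat objective (degenerate TAC) yields
#'   a warning and delay 0.
#' @export
estimate_delay <- function(input, composite_tac, range = c(-30, 30),
                           step = 0.5, early_s = 300) {
  stopifnot(inherits(input, "input_function"), inherits(composite_tac, "tac"))
  keep <- frame_midpoints(composite_tac) <= early_s
  if (sum(keep) < 6L) abort("composite TAC must sample the first 5 min densely")
  sub <- tac(
    frame_schedule(
      composite_tac$frame_start[keep],
      composite_tac$frame_end[keep]
    ),
    composite_tac$activity[keep]
  )
  rss_at <- function(d, model) {
    shifted <- input
    shifted$delay <- d
    f <- tryCatch(
      fit_compartment(sub, shifted,
        model = model, n_starts = 1,
        vB = 0.05
      ),
      error = function(e) NULL
    )
    if (is.null(f)) Inf else f$rss
  }
  coarse <- seq(range[1], range[2], by = max(step, 2))
  o1 <- vapply(coarse, rss_at, numeric(1), model = "1tcm")
  if (!any(is.finite(o1)) || diff(range(o1[is.finite(o1)])) <=
    1e-12 * max(abs(o1[is.finite(o1)]), 1e-300)) {
    warn("flat delay objective; returning 0")
    return(0)
  }
  c0 <- coarse[which.min(o1)]
  fine <- seq(
    max(range[1], c0 - 2.5), min(range[2], c0 + 2.5),
    by = step
  )
  o2 <- vapply(fine, rss_at, numeric(1), model = "2tcm")
  fine[which.min(o2)]
}

#' @export
tidy.input_function <- function(x, ...) {
  curves <- list(whole_blood = x$whole_blood, total_plasma = x$plasma)
  out <- purrr::map_dfr(names(curves), function(nm) {
    cv <- curves[[nm]]
    tibble::tibble(
      component = nm,
      term = c(paste0("a", 1:3), paste0("lambda", 1:3), "peak_time"),
      estimate = c(cv$amplitudes, cv$rates, cv$peak_time)
    )
  })
  dplyr::bind_rows(out, tibble::tibble(
    component = "parent_fraction", term = "k_m",
    estimate = x$parent_fraction$k_m
  ))
}

#' @export
glance.input_function <- function(x, ...) {
  tibble::tibble(
    delay_s = x$delay, pff = x$pff,
    k_m_per_min = x$parent_fraction$k_m * 60,
    blood_rss = x$whole_blood$rss, plasma_rss = x$plasma$rss
  )
}

#' Read arterial blood and metabolite sample tables
#'
#' Blood files are delimited text with columns `time_s`,
#' `whole_blood_kBq_ml`, `plasma_kBq_ml`; metabolite files have `time_s`,
#' `parent_fraction`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_blood_table <- function(path) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  tbl <- readr::read_delim(path,
    delim = delim, show_col_types = FALSE,
    progress = FALSE, trim_ws = TRUE
  )
  need <- c("time_s", "whole_blood_kBq_ml", "plasma_kBq_ml")
  if (!all(need %in% names(tbl))) {
    need <- c("time_s", "parent_fraction")
    if (!all(need %in% names(tbl))) {
      abort("unrecognised blood/metabolite table columns")
    }
  }
  tbl
}

#' Fit a complete input function from sample tables
#'
#' Convenience wrapper: tri-exponential fits to whole blood and plasma, a
#' mono-exponential parent-fraction fit, and (optionally) delay estimation
#' against a composite cortical TAC.
#'
#' @param blood Tibble with `time_s`, `whole_blood_kBq_ml`, `plasma_kBq_ml`.
#' @param metabolites Tibble with `time_s`, `parent_fraction`.
#' @param composite_tac Optional [tac()] for delay estimation.
#' @param pff Optional plasma free fraction record.
#' @return An [input_function()].
#' @export
fit_input_function <- function(blood, metabolites, composite_tac = NULL,
                               pff = NA_real_) {
  wb <- fit_triexponential(blood$time_s, blood$whole_blood_kBq_ml)
  pl <- fit_triexponential(blood$time_s, blood$plasma_kBq_ml)
  pf <- fit_parent_fraction(metabolites$time_s, metabolites$parent_fraction)
  inp <- input_function(wb, pl, pf, delay = 0, pff = pff)
  if (!is.null(composite_tac)) {
    inp$delay <- estimate_delay(inp, composite_tac)
  }
  inp
}
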