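#' Plot a time-activity curve
#'
#' @param object A [tac()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tac <- function(object, ...) {
  df <- tibble::tibble(
    t_min = frame_midpoints(object) / 60,
    activity = object$activity
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_min, y = .data$activity)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(
      x = "Time (min)", y = "Activity (kBq/mL)",
      title = tac_label(object)
    )
}

#' Plot an input function with its components
#'
#' @param object An [input_function()].
#' @param t_max_s Right edge of the time axis, s.
#' @param ... Unused.
#' @return A ggplot with whole-blood, total-plasma and parent-plasma curves.
#' @export
autoplot.input_function <- function(object, t_max_s = 7200, ...) {
  tt <- seq(0, t_max_s, length.out = 400)
  df <- dplyr::bind_rows(lapply(
    c("whole_blood", "total_plasma", "parent_plasma"),
    function(cm) {
      tibble::tibble(
        t_min = tt / 60, component = cm,
        conc = evaluate_input(object, tt, cm)
      )
    }
  ))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$t_min, y = .data$conc,
    colour = .data$component
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (min)", y = "Concentration (kBq/mL)")
}

#' Plot a compartment fit over its data
#'
#' @param object A `compartment_fit`.
#' @param ... Unused.
#' @return A ggplot of measured frames and the fitted model curve.
#' @export
autoplot.compartment_fit <- function(object, ...) {
  df <- tibble::tibble(
    t_min = frame_midpoints(object$tac) / 60,
    measured = object$tac$activity,
    fitted = object$fitted
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_min)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$measured)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(
      x = "Time (min)", y = "Activity (kBq/mL)",
      title = paste0(
        toupper(object$model), " fit, VT = ",
        signif(object$vt, 4)
      )
    )
}

#' Logan plot
#'
#' @param object A `logan_fit`.
#' @param ... Unused.
#' @return A ggplot of all Logan points with the fitted late-time line;
#'   points before t* are hollow.
#' @export
autoplot.logan_fit <- function(object, ...) {
  all_pts <- object$all_points
  all_pts$included <- all_pts$t_min >= object$t_star
  ggplot2::ggplot(all_pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$included)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = object$vt,
      colour = "red"
    ) +
    ggplot2::labs(
      x = "Int Cp / Ct (min)", y = "Int Ct / Ct (min)",
      title = paste0("Logan plot, VT = ", signif(object$vt, 4))
    )
}

#' Bland-Altman plot of two VT estimates
#'
#' @param a,b Paired estimates (e.g. 2TCM and Logan VT).
#' @param labels Optional point labels.
#' @return A ggplot with bias and 95% limits of agreement.
#' @export
plot_bland_altman <- function(a, b, labels = NULL) {
  ba <- bland_altman(a, b)
  df <- tibble::tibble(
    mean = (a + b) / 2, diff = a - b,
    label = labels %||% ""
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$bias, colour = "blue") +
    ggplot2::geom_hline(
      yintercept = c(ba$loa_low, ba$loa_high),
      linetype = "dashed"
    ) +
    ggplot2::labs(x = "Mean of methods", y = "Difference")
}

#' Plot a time-stability table
#'
#' @param stability A tibble from [time_stability_table()].
#' @return A ggplot of TRV and bias (mean with SD ribbons) per window.
#' @export
plot_time_stability <- function(stability) {
  df <- tidyr::pivot_longer(
    stability,
    cols = c("trv_mean", "bias_mean"),
    names_to = "metric", values_to = "mean"
  )
  df$sd <- ifelse(df$metric == "trv_mean", stability$trv_sd[
    match(df$window, stability$window)
  ], stability$bias_sd[match(df$window, stability$window)])
  df$window <- factor(df$window, levels = stability$window)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$window, y = .data$mean,
    group = .data$metric, colour = .data$metric
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean - .data$sd,
        ymax = .data$mean + .data$sd
      ),
      width = 0.2
    ) +
    ggplot2::labs(x = "Acquisition window", y = "Percent") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
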