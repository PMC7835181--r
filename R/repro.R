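#' Test-retest variability
#'
#' Signed test-retest variability of a paired quantity, in percent:
#' `TRV = 2 (test - retest) / (test + retest) * 100`. `atrv()` is its
#' absolute value. Both are dimensionless and invariant to common scaling of
#' the pair; swapping test and retest flips the TRV sign.
#'
#' @param test,retest Paired measurements (e.g. VT); vectorised.
#' @return Percentages.
#' @export
#' @examples
#' trv(40, 36) # +10.526
trv <- function(test, retest) {
  stopifnot(length(test) == length(retest))
  s <- test + retest
  if (any(s <= 0)) abort("test + retest must be > 0")
  200 * (test - retest) / s
}

#' @rdname trv
#' @export
atrv <- function(test, retest) abs(trv(test, retest))

#' Intra-class correlation coefficient (one-way mean squares)
#'
#' `ICC = (BSMSS - WSMSS) / (BSMSS + WSMSS)`, where BSMSS is the
#' between-subject mean sum of squares (subject means around the grand mean,
#' `n - 1` degrees of freedom, scaled by the k = 2 repeated measurements)
#' and WSMSS the within-subject mean sum of squares (`n (k - 1)` degrees of
#' freedom). Ranges from -1 (all variance within subjects) to 1 (perfect
#' reliability).
#'
#' @param test,retest Per-subject paired measurements.
#' @return The ICC in \[-1, 1\].
#' @export
#' @examples
#' icc(c(10, 20), c(12, 18)) # 62/66
icc <- function(test, retest) {
  stopifnot(length(test) == length(retest))
  n <- length(test)
  if (n < 2L) abort("need at least 2 subjects")
  m <- cbind(test, retest)
  k <- 2
  subj_means <- rowMeans(m)
  grand <- mean(m)
  bsmss <- k * sum((subj_means - grand)^2) / (n - 1)
  wsmss <- sum((m - subj_means)^2) / (n * (k - 1))
  if (bsmss + wsmss <= 0) abort("zero total variance; ICC undefined")
  (bsmss - wsmss) / (bsmss + wsmss)
}

#' Inter-subject coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) over the mean, in percent.
#'
#' @param values Numeric vector, n >= 2, positive mean.
#' @return Percent COV.
#' @export
#' @examples
#' cov_percent(c(9, 10, 11)) # 10
cov_percent <- function(values) {
  if (length(values) < 2L) abort("need at least 2 values")
  m <- mean(values)
  if (m <= 0) abort("mean must be > 0")
  100 * sd(values) / m
}

#' Bland-Altman agreement
#'
#' Differences `a - b`: bias is their mean, `sd` the sample standard
#' deviation and the 95% limits of agreement are `bias +/- 1.96 sd`.
#'
#' @param a,b Paired measurements of the same quantity by two methods.
#' @return A one-row tibble with `bias`, `sd`, `loa_low`, `loa_high`, `n`.
#' @export
#' @examples
#' bland_altman(c(1, 2, 3), c(1, 2, 3))
bland_altman <- function(a, b) {
  if (length(a) != length(b)) abort("paired vectors must have equal length")
  if (length(a) < 2L) abort("need at least 2 pairs")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  tibble::tibble(
    bias = bias, sd = s,
    loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    n = length(d)
  )
}

#' Per-region test-retest summary
#'
#' Reproducibility statistics for a table of paired VT estimates: signed and
#' absolute TRV averaged over the pairs, and the ICC across subjects, per
#' region.
#'
#' @param pairs Tibble with columns `subject`, `region`, `vt_test`,
#'   `vt_retest` (both positive).
#' @return A tibble, one row per region: `trv_mean`, `atrv_mean`, `icc`, `n`.
#' @export
repro_summary <- function(pairs) {
  need <- c("subject", "region", "vt_test", "vt_retest")
  if (!all(need %in% names(pairs))) {
    abort("pairs must have subject, region, vt_test, vt_retest columns")
  }
  if (any(pairs$vt_test <= 0 | pairs$vt_retest <= 0)) {
    abort("VT values must be > 0")
  }
  pairs |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      trv_mean = mean(trv(.data$vt_test, .data$vt_retest)),
      atrv_mean = mean(atrv(.data$vt_test, .data$vt_retest)),
      icc = icc(.data$vt_test, .data$vt_retest),
      n = dplyr::n(),
      .groups = "drop"
    )
}
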