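test_that("Logan transform satisfies the equilibrium identity", {
  # constant Cp = 1 and Ct = 5: y = 5 x exactly (slope 5, intercept 0)
  sched <- parse_frame_schedule("12x600s")
  x <- tac(sched, rep(5, 12))
  pts <- logan_transform(x, const_input(1))
  fit <- fit_logan(pts, t_star_min = 40)
  expect_rel(fit$vt, 5, 1e-4)
  # the (0, 0) tissue-integral anchor shifts the line down by half the
  # first midpoint (2.5 min) without touching the slope
  expect_lt(abs(fit$intercept + 2.5), 0.01)
  expect_gt(fit$r_squared, 1 - 1e-9)
})

test_that("an exact line is reproduced verbatim", {
  pts <- tibble::tibble(t_min = seq(40, 115, length.out = 8))
  pts$x <- seq(1, 8)
  pts$y <- 40 * pts$x - 5
  fit <- fit_logan(pts, 40)
  expect_equal(fit$vt, 40)
  expect_equal(fit$intercept, -5)
  expect_equal(fit$r_squared, 1)
  expect_error(fit_logan(pts, 130), "at least 3")
})

test_that("Logan slope approaches the compartmental VT on noiseless data", {
  # 1TCM: VT = 3
  p1 <- compartment_params("1tcm", K1 = 0.3, k2 = 0.1, vB = 0)
  x1 <- simulate_tissue(p1, fx_input(), fx_schedule())
  expect_rel(logan_vt(x1, fx_input(), 40)$vt, 3, 0.01)
  # 2TCM: VT = 7, within 2% at t* = 40
  p2 <- compartment_params("2tcm", K1 = 0.3, k2 = 0.15, k3 = 0.05,
    k4 = 0.02, vB = 0
  )
  x2 <- simulate_tissue(p2, fx_input(), fx_schedule())
  expect_rel(logan_vt(x2, fx_input(), 40)$vt, 7, 0.02)
  # all-negative TAC: no usable points
  neg <- tac(fx_schedule(), rep(-1, 31))
  expect_error(logan_transform(neg, fx_input()), "usable")
})

test_that("Logan slope is invariant to simultaneous curve scaling", {
  x <- fx_clean_tac_novb()
  fit <- logan_vt(x, fx_input(), 40)
  scaled_tac <- tac(fx_schedule(), x$activity * 3)
  scaled_input <- true_input_function(amplitudes = 3 * c(300, 80, 20))
  fit_s <- logan_vt(scaled_tac, scaled_input, 40)
  expect_rel(fit_s$vt, fit$vt, 1e-9)
})

test_that("acquisition windows select the expected frames", {
  full <- tac(fx_schedule(), seq_len(31))
  expect_equal(nrow(apply_window(full, "0-120")), 31L)
  cb <- apply_window(full, "0-60,90-120")
  # schedule arithmetic: 25 frames end at or before 60 min
  # (6+3+3+2+2+9) and 3 of the 10-min frames lie within 90-120 min
  expect_equal(nrow(cb), 28L)
  expect_equal(sum(cb$frame_end <= 3600), 25L)
  expect_equal(sum(cb$frame_start >= 5400), 3L)
  expect_error(apply_window(full, "130-140"), "no frames")
  expect_error(acquisition_window("60-50"), "end > start")
})

test_that("coffee-break Logan VT agrees with the full window on clean data", {
  x <- fx_clean_tac_novb()
  inp <- fx_input()
  full <- logan_vt(x, inp, 40)$vt
  cb <- logan_vt(x, inp, 40, window = "0-60,90-120")$vt
  expect_lt(abs(cb / full - 1), 0.01)
  # a 0-60 truncation underestimates relative to the full window
  t60 <- logan_vt(x, inp, 40, window = "0-60")$vt
  expect_lt(t60, full)
})

test_that("voxel-wise Logan reproduces regional values and flags failures", {
  ph <- generate_phantom(
    region_vt = c(high = 42, low = 27), dim = c(8, 8, 8),
    noise_sd = 0, seed = 7
  )
  vw <- voxelwise_logan(ph$volume, fx_input(), 40)
  expect_equal(vw$nan_fraction, 0)
  for (i in seq_along(ph$region_map)) {
    truth <- ph$truth$vt[i]
    vox <- vw$vt[ph$labels == i]
    expect_rel(mean(vox), truth, 0.02)
    # regional mean of the map equals the regional-TAC Logan VT within 1%
    reg <- tacs_from_table(
      extract_regional_tacs(ph$volume, ph$labels, ph$region_map)
    )[[ph$truth$region[i]]]
    expect_rel(mean(vox), logan_vt(reg, fx_input(), 40)$vt, 0.01)
  }
  zero <- dynamic_volume(
    array(0, dim = c(4, 4, 4, 31)),
    fx_schedule()
  )
  vz <- voxelwise_logan(zero, fx_input(), 40)
  expect_equal(vz$nan_fraction, 1)
})

test_that("time-stability table has zero TRV for identical scans and no bias row", {
  x <- fx_clean_tac()
  inp <- fx_input()
  trt <- tibble::tibble(
    subject = rep(c("S1", "S2"), each = 2),
    region = "cortex",
    scan = rep(c("test", "retest"), 2),
    tac = list(x, x, x, x),
    input = list(inp, inp, inp, inp)
  )
  cohort <- tibble::tibble(
    subject = c("S1", "S2"), region = "cortex",
    tac = list(x, x), input = list(inp, inp)
  )
  wins <- lapply(c(cb = "0-60,90-120", full = "0-120"), acquisition_window)
  ts <- time_stability_table(trt, cohort, wins)
  expect_equal(ts$trv_mean, c(0, 0))
  expect_true(is.na(ts$bias_mean[ts$window == "full"]))
  expect_false(is.na(ts$bias_mean[ts$window == "cb"]))
})
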