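test_that("VT follows the closed forms", {
  p2 <- compartment_params("2tcm", K1 = 0.3, k2 = 0.15, k3 = 0.05, k4 = 0.02)
  expect_equal(vt_from_params(p2), 2 * (1 + 2.5)) # 7
  p1 <- compartment_params("1tcm", K1 = 0.3, k2 = 0.1)
  expect_equal(vt_from_params(p1), 3)
  p0 <- compartment_params("2tcm", K1 = 0.3, k2 = 0.1, k3 = 0, k4 = 0.02)
  expect_equal(vt_from_params(p0), 3) # k3 = 0 collapses to the 1TCM value
  expect_error(
    compartment_params("2tcm", K1 = 0.3, k2 = 0.1, k3 = 0.1, k4 = 0),
    "irreversible"
  )
})

test_that("the simulator matches closed-form limits", {
  sched <- parse_frame_schedule("6x1200s") # long frames out to 120 min
  # constant input, k2 ~ 0: linear accumulation at K1 * t
  slow <- compartment_params("1tcm", K1 = 0.1, k2 = 1e-7, vB = 0)
  lin <- simulate_tissue(slow, const_input(1), sched)
  expect_rel(lin$activity, 0.1 * frame_midpoints(sched) / 60, 1e-3)
  # constant input, late times: plateau at K1/k2
  eq <- compartment_params("1tcm", K1 = 0.1, k2 = 0.1, vB = 0)
  plat <- simulate_tissue(eq, const_input(1), sched)
  expect_rel(tail(plat$activity, 1), 1, 1e-3)
  # 2TCM with k3 = 0 equals the 1TCM output
  p1 <- compartment_params("1tcm", K1 = 0.3, k2 = 0.12)
  p2 <- compartment_params("2tcm", K1 = 0.3, k2 = 0.12, k3 = 0, k4 = 0.05)
  a <- simulate_tissue(p1, fx_input(), fx_schedule())$activity
  b <- simulate_tissue(p2, fx_input(), fx_schedule())$activity
  expect_lt(max(abs(a - b)), 1e-10)
})

test_that("the simulator is linear in the input when vB = 0", {
  p <- compartment_params("2tcm", K1 = 0.3, k2 = 0.15, k3 = 0.05, k4 = 0.02,
    vB = 0
  )
  base <- simulate_tissue(p, fx_input(), fx_schedule())$activity
  doubled_input <- true_input_function(amplitudes = 2 * c(300, 80, 20))
  doubled <- simulate_tissue(p, doubled_input, fx_schedule())$activity
  expect_rel(doubled, 2 * base, 1e-9)
})

test_that("compartment fits recover noiseless generating parameters", {
  p2 <- compartment_params("2tcm", K1 = 0.3, k2 = 0.15, k3 = 0.05, k4 = 0.02)
  x <- simulate_tissue(p2, fx_input(), fx_schedule())
  fit <- fit_compartment(x, fx_input(), "2tcm")
  expect_rel(
    c(fit$params$K1, fit$params$k2, fit$params$k3, fit$params$k4),
    c(0.3, 0.15, 0.05, 0.02), 0.005
  )
  expect_rel(fit$vt, 7, 0.001)

  p1 <- compartment_params("1tcm", K1 = 0.3, k2 = 0.1)
  x1 <- simulate_tissue(p1, fx_input(), fx_schedule())
  fit1 <- fit_compartment(x1, fx_input(), "1tcm")
  expect_rel(c(fit1$params$K1, fit1$params$k2), c(0.3, 0.1), 0.001)

  expect_error(
    fit_compartment(tac(fx_schedule(), rep(0, 31)), fx_input(), "2tcm"),
    "degenerate"
  )
})

test_that("AIC formula, tie rule and rss behaviour", {
  expect_equal(aic_from_rss(3.1, 31, 4), 31 * log(0.1) + 8)
  # equal rss: 1TCM (k = 2) lower by exactly 4
  expect_equal(aic_from_rss(5, 31, 4) - aic_from_rss(5, 31, 2), 4)
  # doubling rss at fixed n, k adds n log 2
  expect_equal(
    aic_from_rss(10, 31, 4) - aic_from_rss(5, 31, 4),
    31 * log(2)
  )
  expect_warning(v <- aic_from_rss(0, 31, 4), "zero")
  expect_identical(v, -Inf)
  expect_error(aic_from_rss(1, 4, 4), "exceed")
})

test_that("model selection prefers the lower AIC with ties to the 1TCM", {
  x <- fx_clean_tac()
  f1 <- fit_compartment(x, fx_input(), "1tcm")
  f2 <- fit_compartment(x, fx_input(), "2tcm")
  sel <- select_model(f1, f2)
  expect_equal(sel$selected, "2tcm")
  expect_lt(sel$delta_aic, 0)
  # tie -> parsimony
  tie1 <- f1
  tie2 <- f2
  tie2$aic <- tie1$aic
  expect_equal(select_model(tie1, tie2)$selected, "1tcm")
})

test_that("2TCM residual never exceeds the 1TCM residual (nesting)", {
  for (s in 1:3) {
    g <- generate_tissue_tac(default_kinetics(), fx_input(), fx_schedule(),
      noise_level = 0.03, seed = 600 + s
    )
    f1 <- fit_compartment(g$tac, fx_input(), "1tcm")
    f2 <- fit_compartment(g$tac, fx_input(), "2tcm")
    expect_lte(f2$rss, f1$rss * (1 + 1e-8))
  }
})

test_that("tidy and glance expose the fit in broom style", {
  fit <- fit_compartment(fx_clean_tac(), fx_input(), "2tcm")
  td <- tidy(fit)
  expect_equal(td$term, c("K1", "k2", "k3", "k4"))
  gl <- glance(fit)
  expect_equal(gl$model, "2tcm")
  expect_equal(gl$vt, fit$vt)
})
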