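test_that("tri-exponential fit recovers generating parameters on noiseless data", {
  gen <- generate_input_function() # noiseless samples from the true input
  fit <- fit_triexponential(gen$samples$time_s, gen$samples$plasma_kBq_ml)
  expect_rel(fit$amplitudes, c(300, 80, 20), 1e-6)
  expect_rel(fit$rates, c(0.01, 0.002, 0.0002), 1e-6)
  expect_equal(fit$peak_time, 45)
  # scale equivariance: concentrations x c scale amplitudes, not rates
  fit2 <- fit_triexponential(gen$samples$time_s, 2 * gen$samples$plasma_kBq_ml)
  expect_rel(fit2$amplitudes, 2 * fit$amplitudes, 1e-5)
  expect_rel(fit2$rates, fit$rates, 1e-5)
})

test_that("tri-exponential fit degenerates gracefully on nested data", {
  tt <- seq(0, 6000, length.out = 20)
  y <- 100 * exp(-0.003 * tt)
  fit <- fit_triexponential(tt, y)
  expect_rel(eval_fit <- petkin:::eval_triexp(fit, tt[-1]), y[-1], 1e-6)
  expect_error(fit_triexponential(tt, rep(0, 20)), "degenerate")
  expect_error(fit_triexponential(c(0, 10, 20), c(0, 5, 1)), "8 post-peak")
})

test_that("parent-fraction fit is anchored at 1 and recovers the rate", {
  tt <- c(0, 300, 900, 1800, 3600, 6000)
  f <- exp(-0.01 / 60 * tt)
  fit <- fit_parent_fraction(tt, f)
  expect_rel(fit$k_m, 0.01 / 60, 1e-8)
  # all fractions 1 -> no metabolism
  expect_equal(fit_parent_fraction(tt, rep(1, 6))$k_m, 0)
  # closed form at 60 min with k_m = 0.01/min
  pf <- structure(list(k_m = 0.01 / 60, rss = 0), class = "parent_fraction")
  expect_equal(exp(-pf$k_m * 3600), exp(-0.6), tolerance = 1e-12)
  expect_error(fit_parent_fraction(tt, f * 1.5), "\\[0, 1\\]")
  expect_error(fit_parent_fraction(c(0, 10), c(1, 0.9)), "at least 3")
})

test_that("evaluate_input applies delay and metabolite correction", {
  inp <- fx_input()
  t <- c(100, 1800, 5000)
  pp <- evaluate_input(inp, t, "parent_plasma")
  tp <- evaluate_input(inp, t, "total_plasma")
  expect_equal(pp, tp * exp(-inp$parent_fraction$k_m * t))
  expect_true(all(pp <= tp))

  # hand formula at t = 1800 s: tri-exp decay from the 45-s peak
  hand <- sum(c(300, 80, 20) * exp(-c(0.01, 0.002, 0.0002) * (1800 - 45))) *
    exp(-0.01 / 60 * 1800)
  expect_rel(evaluate_input(inp, 1800, "parent_plasma"), hand, 1e-12)

  delayed <- inp
  delayed$delay <- 30
  expect_equal(evaluate_input(delayed, c(0, 10, 29.9), "parent_plasma"),
    rep(0, 3))
  # with no metabolism, parent equals total plasma everywhere
  nomet <- inp
  nomet$parent_fraction$k_m <- 0
  expect_equal(
    evaluate_input(nomet, t, "parent_plasma"),
    evaluate_input(nomet, t, "total_plasma")
  )
})

test_that("closed-form input integral matches adaptive quadrature", {
  inp <- fx_input()
  for (tt in c(30, 45, 300, 1800, 7200)) {
    q <- integrate(function(s) evaluate_input(inp, s, "parent_plasma"),
      0, tt,
      subdivisions = 4000, rel.tol = 1e-12
    )$value
    expect_rel(integral_input(inp, tt, "parent_plasma"), q, 1e-8)
  }
  expect_equal(integral_input(inp, 0), 0)
  # constant plasma with parent fraction 1 integrates to c * t
  expect_rel(integral_input(const_input(2), 600, "parent_plasma"), 1200, 1e-4)
  # monotone non-decreasing
  grid <- integral_input(inp, seq(0, 7200, by = 60))
  expect_true(all(diff(grid) >= 0))
})

test_that("delay estimation recovers known input shifts to the grid step", {
  sched <- fx_schedule()
  for (d in c(10, 0, -8)) {
    shifted <- true_input_function(delay = d)
    comp <- simulate_tissue(default_kinetics(), shifted, sched)
    est <- estimate_delay(true_input_function(), comp)
    expect_lte(abs(est - d), 0.5)
  }
  flat <- tac(sched, rep(0, 31))
  expect_warning(d0 <- estimate_delay(fx_input(), flat), "flat")
  expect_equal(d0, 0)
})

test_that("fit_input_function assembles a usable input from sample tables", {
  gen <- generate_input_function()
  inp <- fit_input_function(gen$samples, gen$metabolites, pff = 0.01)
  expect_s3_class(inp, "input_function")
  expect_rel(
    evaluate_input(inp, 1800, "parent_plasma"),
    evaluate_input(gen$truth, 1800, "parent_plasma"), 1e-4
  )
  expect_equal(glance(inp)$pff, 0.01)
  expect_equal(nrow(tidy(inp)), 15L)
})
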