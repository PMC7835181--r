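test_that("all generators are deterministic under a fixed seed", {
  a <- generate_input_function(noise_cv = 0.03, seed = 5)
  b <- generate_input_function(noise_cv = 0.03, seed = 5)
  expect_identical(a$samples, b$samples)

  g1 <- generate_tissue_tac(default_kinetics(), fx_input(), seed = 5)
  g2 <- generate_tissue_tac(default_kinetics(), fx_input(), seed = 5)
  expect_identical(g1$tac$activity, g2$tac$activity)

  t1 <- generate_test_retest(seed = 5)
  t2 <- generate_test_retest(seed = 5)
  expect_identical(t1, t2)

  w1 <- generate_wb_study(noise_cv = 0.05, seed = 5)
  w2 <- generate_wb_study(noise_cv = 0.05, seed = 5)
  expect_identical(w1$table, w2$table)

  p1 <- generate_phantom(noise_sd = 1, seed = 5)
  p2 <- generate_phantom(noise_sd = 1, seed = 5)
  expect_identical(p1$volume$data, p2$volume$data)
})

test_that("noiseless tissue generation equals the forward simulation", {
  g <- generate_tissue_tac(default_kinetics(), fx_input(), noise_level = 0)
  expect_equal(
    g$tac$activity,
    simulate_tissue(default_kinetics(), fx_input(), fx_schedule())$activity
  )
  expect_equal(g$truth$vt, 42, tolerance = 1e-9)
})

test_that("the empirical last-frame COV matches the requested noise level", {
  set.seed(77)
  n_rep <- 2500
  last <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    last[r] <- tail(generate_tissue_tac(default_kinetics(), fx_input(),
      noise_level = 0.05
    )$tac$activity, 1)
  }
  expect_rel(sd(last) / mean(last), 0.05, 0.05)
})

test_that("the parent fraction of generated metabolite data starts at 1", {
  gen <- generate_input_function(noise_cv = 0.1, seed = 9)
  expect_equal(gen$metabolites$parent_fraction[gen$metabolites$time_s == 0], 1)
  expect_true(all(gen$metabolites$parent_fraction <= 1))
})

test_that("test-retest generation respects its noise dials", {
  quiet <- generate_test_retest(
    cohort_spec(within_subject_noise = 0),
    seed = 21
  )
  expect_equal(atrv(quiet$vt_test, quiet$vt_retest), rep(0, nrow(quiet)))

  trt <- generate_test_retest(seed = 22)
  expect_true(mean(atrv(trt$vt_test, trt$vt_retest)) > 1) # percent scale
  expect_true(all(trt$vt_true > 0))
})

test_that("tac-level test-retest pairs run through the Logan pipeline", {
  trt <- generate_test_retest(
    cohort_spec(n_male = 1, n_female = 1),
    seed = 23, level = "tac", regions = c("hippocampus", "brainstem")
  )
  expect_equal(nrow(trt), 8) # 2 subjects x 2 regions x 2 scans
  vt <- purrr::map2_dbl(trt$tac, trt$input, ~ logan_vt(.x, .y, 40)$vt)
  truth <- attr(trt, "truth")
  merged <- dplyr::left_join(
    dplyr::mutate(trt[c("subject", "region", "scan")], vt = vt),
    truth,
    by = c("subject", "region")
  )
  # measured VT lands near its subject/region truth (noise + Logan bias)
  expect_true(all(abs(merged$vt / merged$vt_true - 1) < 0.25))
})

test_that("cohort generation carries the sex effect and region ordering", {
  reps <- 200
  set.seed(31)
  diffs <- numeric(reps)
  order_ok <- logical(reps)
  for (r in seq_len(reps)) {
    co <- generate_cohort(regions = c("hippocampus", "brainstem"))
    m <- tapply(co$vt, co$sex, mean)
    diffs[r] <- m[["M"]] / m[["F"]] - 1
    rmeans <- tapply(co$vt, co$region, mean)
    order_ok[r] <- rmeans[["hippocampus"]] > rmeans[["brainstem"]]
  }
  expect_lt(abs(mean(diffs) - 0.15), 0.03) # sampling error of the ratio
  expect_gte(mean(order_ok), 0.99)

  # no sex effect -> means agree within sampling error
  set.seed(32)
  d0 <- replicate(100, {
    co <- generate_cohort(cohort_spec(sex_effect = 0),
      regions = "hippocampus"
    )
    m <- tapply(co$vt, co$sex, mean)
    m[["M"]] / m[["F"]] - 1
  })
  expect_lt(abs(mean(d0)), 0.02)
})

test_that("sex-pooled regional COV exceeds within-sex COV on average", {
  set.seed(33)
  res <- replicate(60, {
    co <- generate_cohort(regions = "frontal_cortex")
    pooled <- cov_percent(co$vt)
    within <- mean(c(
      cov_percent(co$vt[co$sex == "M"]),
      cov_percent(co$vt[co$sex == "F"])
    ))
    pooled - within
  })
  expect_gt(mean(res), 0)
})

test_that("whole-body generation conserves activity and round-trips NCAs", {
  wb <- generate_wb_study()
  tbl <- wb$table
  organs <- setdiff(names(tbl), c("time_h", "total_body", "remainder"))
  expect_equal(
    rowSums(tbl[c(organs, "remainder")]), tbl$total_body,
    tolerance = 1e-12
  )
  # fit each organ on decay-corrected data, integrate analytically
  lam <- petkin:::lambda_phys_per_h()
  fmap <- organ_form_map()
  for (org in organs) {
    corrected <- tbl[[org]] * exp(lam * tbl$time_h)
    fit <- fit_organ_curve(tbl$time_h, corrected, fmap[[org]],
      decay_corrected = TRUE, organ = org
    )
    truth <- wb$truth$nca$nca[wb$truth$nca$organ == org]
    expect_rel(nca_analytic(fit)$nca, truth, 0.01)
  }
  expect_error(
    generate_wb_study(organ_spec = list(huge = list(
      form = "uptake_plateau", A = c(0.9, 0.4),
      tau = c(tau_u1 = 0.01, tau_e2 = 50)
    ))),
    "more than 1"
  )
})

test_that("phantom labels tile the grid and zero noise gives identical voxels", {
  ph <- generate_phantom(
    region_vt = c(only = 42), dim = c(8, 8, 8),
    noise_sd = 0
  )
  expect_true(all(ph$labels == 1L))
  nf <- nrow(default_schedule())
  flat <- matrix(ph$volume$data, ncol = nf)
  expect_equal(max(apply(flat, 2, sd)), 0)
  ph2 <- generate_phantom()
  expect_true(all(ph2$labels %in% c(1L, 2L)))
})

test_that("the full pipeline recovers true VT from noiseless generated data", {
  gen <- generate_input_function() # noiseless arterial samples
  inp <- fit_input_function(gen$samples, gen$metabolites)
  x <- simulate_tissue(default_kinetics(), gen$truth, fx_schedule())
  fit <- fit_compartment(x, inp, "2tcm")
  expect_rel(fit$vt, 42, 0.005)
})
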