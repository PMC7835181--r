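wb_times_h <- c(4, 12, 20, 28, 36, 44, 52, 60, 68, 76, 88, 150, 270) / 60

test_that("organ curve fits recover noiseless generating parameters", {
  v <- 0.05 * exp(-log(2) * wb_times_h / 0.5) +
    0.02 * exp(-log(2) * wb_times_h / 3)
  fit <- fit_organ_curve(wb_times_h, v, "biexp")
  expect_rel(unname(fit$A), c(0.05, 0.02), 1e-6)
  expect_rel(unname(fit$tau), c(0.5, 3), 1e-6)

  # uptake_washout with a vanishing uptake half-time reduces to the biexp
  uw <- structure(
    list(
      form = "uptake_washout", A = c(A1 = 0.05, A2 = 0.02),
      tau = c(tau_u1 = 1e-9, tau_e1 = 0.5, tau_e2 = 3),
      c_const = log(2), rss = 0, decay_corrected = FALSE,
      organ = NA_character_, time_h = wb_times_h, value = v
    ),
    class = "organ_curve"
  )
  expect_rel(eval_organ_curve(uw, wb_times_h[-1]), v[-1], 1e-6)

  expect_error(fit_organ_curve(wb_times_h, -v, "biexp"), "non-negative")
  expect_error(fit_organ_curve(c(1, 2, 3) / 60, c(1, 2, 3) / 10, "biexp"),
    "5 time points")
})

test_that("analytic NCA matches the closed form and the quadrature oracle", {
  m <- structure(
    list(
      form = "biexp", A = c(A1 = 0.1, A2 = 0),
      tau = c(tau_e1 = 1.82952, tau_e2 = 1), c_const = log(2), rss = 0,
      decay_corrected = FALSE, organ = "x", time_h = 0, value = 0
    ),
    class = "organ_curve"
  )
  expect_equal(nca_analytic(m)$nca, 0.1 * 1.82952 / log(2), tolerance = 1e-9)
  expect_equal(nca_analytic(m)$nca, 0.26395, tolerance = 1e-4)
  m0 <- m
  m0$A[] <- 0
  expect_equal(nca_analytic(m0)$nca, 0)

  # property: analytic vs adaptive quadrature over random valid models
  set.seed(20)
  for (i in 1:12) {
    form <- sample(c("biexp", "uptake_washout", "uptake_plateau"), 1)
    ntau <- length(petkin:::organ_tau_names(form))
    mm <- structure(
      list(
        form = form, A = c(A1 = runif(1, 0.01, 0.2), A2 = runif(1, 0, 0.1)),
        tau = setNames(
          exp(runif(ntau, log(0.05), log(20))),
          petkin:::organ_tau_names(form)
        ),
        c_const = log(2), rss = 0, decay_corrected = TRUE,
        organ = "r", time_h = 0, value = 0
      ),
      class = "organ_curve"
    )
    lam <- petkin:::lambda_phys_per_h()
    q <- integrate(
      function(t) eval_organ_curve(mm, t) * exp(-lam * t),
      0, Inf,
      rel.tol = 1e-10
    )$value
    expect_rel(nca_analytic(mm)$nca, q, 0.005)
  }
})

test_that("the plateau form needs physical decay for a finite integral", {
  m <- structure(
    list(
      form = "uptake_plateau", A = c(A1 = 0.3, A2 = 0.1),
      tau = c(tau_u1 = 0.2, tau_e2 = 2), c_const = log(2), rss = 0,
      decay_corrected = FALSE, organ = "remainder", time_h = 0, value = 0
    ),
    class = "organ_curve"
  )
  expect_error(nca_analytic(m), "diverges")
  m$decay_corrected <- TRUE
  expect_gt(nca_analytic(m)$nca, 0)
})

test_that("trapezoid NCA integrates pure physical decay to T1/2 / ln 2", {
  tt <- seq(0, 4.5, by = 0.05)
  vv <- exp(-petkin:::lambda_phys_per_h() * tt)
  out <- nca_trapezoid(tt, vv)
  expect_rel(out$nca, f18_half_life_min() / 60 / log(2), 0.01)
  expect_equal(nca_trapezoid(tt, rep(0, length(tt)))$nca, 0)
  expect_error(nca_trapezoid(tt, vv, decay_corrected = TRUE), "physical")

  # cross-method: trapezoid vs analytic on a fitted physical biexp organ
  # (physical-domain half-times at or below the physical half-life, as any
  # organ with biological excretion must have)
  v <- 0.04 * exp(-log(2) * wb_times_h / 1.6) +
    0.01 * exp(-log(2) * wb_times_h / 1.83)
  fit <- fit_organ_curve(wb_times_h, v, "biexp")
  expect_rel(
    nca_trapezoid(wb_times_h, v)$nca,
    nca_analytic(fit)$nca, 0.02
  )
})

test_that("every NCA respects the total-decay bound", {
  bound <- f18_half_life_min() / 60 / log(2) # 2.6395 h
  gi <- gi_tract_nca(1)
  expect_true(all(gi$nca <= bound))
  wb <- generate_wb_study()
  expect_true(all(wb$truth$nca$nca <= bound))
  tt <- seq(0, 4.5, by = 0.05)
  expect_lte(nca_trapezoid(tt, exp(-petkin:::lambda_phys_per_h() * tt))$nca,
    bound * 1.01)
})

test_that("the ICRP-30 GI chain reproduces the printed small-intestine values", {
  si <- function(f) gi_tract_nca(f)$nca[1]
  expect_equal(si(0.6175), 0.982, tolerance = 5e-4 / 0.982)
  expect_equal(si(0.49), 0.779, tolerance = 5e-4)
  expect_equal(nrow(gi_tract_nca(0)), 3)
  expect_equal(sum(gi_tract_nca(0)$nca), 0)
  expect_error(gi_tract_nca(1.2), "\\[0, 1\\]")

  # NCAs are linear in f_si: cohort stats transform linearly
  f4 <- c(0.63, 0.49, 0.67, 0.68)
  tab <- gi_tract_nca(f4)
  si4 <- tab$nca[tab$organ == "small_intestine"]
  slope <- si(1)
  expect_equal(mean(si4), slope * mean(f4), tolerance = 1e-12)
  expect_equal(sd(si4), slope * sd(f4), tolerance = 1e-12)
  expect_equal(range(si4), slope * range(f4), tolerance = 1e-12)

  # faster physical decay drives all GI NCAs to zero monotonically
  ncas <- vapply(
    c(109.771, 50, 20, 5),
    function(hl) sum(gi_tract_nca(0.6, half_life_min = hl)$nca),
    numeric(1)
  )
  expect_true(all(diff(ncas) < 0))
})

test_that("remainder is total minus sources, floored at zero with warning", {
  tbl <- tibble::tibble(
    time_h = c(0.1, 0.5, 1), a = c(0.3, 0.2, 0.1), b = c(0.2, 0.1, 0.05),
    total_body = c(1, 0.8, 0.6)
  )
  out <- remainder_tac(tbl)
  expect_equal(out$remainder, c(0.5, 0.5, 0.45))
  bad <- tbl
  bad$a <- c(0.9, 0.9, 0.9)
  expect_warning(out2 <- remainder_tac(bad), "floored")
  expect_true(all(out2$remainder >= 0))
  expect_error(remainder_tac(tbl[-4]), "total-body")
})

test_that("effective dose weights sum to one and combine linearly", {
  w <- icrp60_weights()
  expect_equal(sum(w$weight), 1)
  flat <- setNames(rep(10, nrow(w)), w$tissue)
  expect_equal(effective_dose(flat), 10)
  expect_equal(effective_dose(flat * 0), 0)
  expect_equal(effective_dose(flat * 2), 2 * effective_dose(flat))
  partial <- flat[c("gonads", "liver")]
  expect_error(effective_dose(partial), "missing")
  with_rem <- c(partial, remainder = 5)
  expect_equal(
    effective_dose(with_rem),
    0.20 * 10 + 0.05 * 10 + 0.75 * 5
  )
})

test_that("organ doses contract NCAs against the S matrix", {
  s <- matrix(c(1, 0, 0, 1), 2, 2,
    dimnames = list(c("liver", "lung"), c("liver", "lung"))
  )
  ncas <- tibble::tibble(organ = c("liver", "lung"), nca = c(0.25, 0.04))
  out <- organ_doses_from_nca(ncas, s)
  expect_equal(out$dose, c(0.25, 0.04)) # identity S: doses equal NCAs
  expect_equal(organ_doses_from_nca(dplyr::mutate(ncas, nca = 0), s)$dose,
    c(0, 0))
  # 2-source hand contraction
  s2 <- matrix(c(10, 2, 3, 8), 2, 2,
    dimnames = list(c("t1", "t2"), c("liver", "lung"))
  )
  out2 <- organ_doses_from_nca(ncas, s2)
  expect_equal(out2$dose, c(10 * 0.25 + 3 * 0.04, 2 * 0.25 + 8 * 0.04))
  expect_error(
    organ_doses_from_nca(tibble::tibble(organ = "spleen", nca = 1), s),
    "spleen"
  )

  # delimited S-matrix round trip
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("target,liver,lung", "t1,10,3", "t2,2,8"), path)
  expect_equal(read_s_matrix(path), s2)
})
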