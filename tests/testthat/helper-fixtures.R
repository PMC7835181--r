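# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fx_schedule <- function() fixture("schedule", default_schedule)

fx_input <- function() fixture("input", true_input_function)

# default-kinetics TAC with the 5% blood volume of the acquisition model
fx_clean_tac <- function() {
  fixture("clean_tac", function() {
    simulate_tissue(default_kinetics(), fx_input(), fx_schedule())
  })
}

# blood-free signal: reference for validating the Logan estimator, which has
# no blood-volume term
fx_clean_tac_novb <- function() {
  fixture("clean_tac_novb", function() {
    p <- default_kinetics()
    p$vB <- 0
    simulate_tissue(p, fx_input(), fx_schedule())
  })
}

# constant-concentration input (flat plasma, parent fraction 1): handy for
# closed-form checks
const_input <- function(value = 1) {
  tri <- structure(
    list(
      peak_time = 1e-9, peak_value = value,
      amplitudes = c(value, 0, 0), rates = c(1e-10, 1e-11, 1e-12), rss = 0
    ),
    class = "triexp_curve"
  )
  pf <- structure(list(k_m = 0, rss = 0), class = "parent_fraction")
  input_function(tri, tri, pf)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
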