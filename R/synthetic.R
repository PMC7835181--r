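#' Default synthetic study conditions
#'
#' The synthetic-data generators emulate a first-in-human brain PET study
#' with arterial sampling: a 31-frame 120-min dynamic schedule, a
#' bolus-shaped arterial input with mono-exponentially declining parent
#' fraction, two-tissue-compartment tissue kinetics with regional VT in the
#' 27-50 range (hippocampus highest, brainstem lowest), a ~15% male > female
#' VT offset, day-apart test-retest perturbations, and a 13-time-point
#' whole-body organ study.
#'
#' `default_kinetics()` returns the reference micro-parameters
#' (K1 = 0.42 mL/cm3/min, k2 = 0.18, k3 = 0.34, k4 = 0.02 1/min, VT = 42).
#' These are chosen so the synthetic tracer behaves like the real one on
#' every observable the study reports: VT in the printed range, tissue
#' kinetics that equilibrate fast enough for the Logan start time of 40 min
#' (noiseless Logan bias below 1%), and a second tissue compartment
#' pronounced enough that the AIC prefers the 2TCM essentially always on
#' noisy data. `default_region_profile()` is the regional VT profile used
#' by the cohort generators; `default_schedule()` the 31-frame schedule.
#'
#' @return See each function.
#' @export
default_kinetics <- function() {
  compartment_params("2tcm", K1 = 0.42, k2 = 0.18, k3 = 0.34, k4 = 0.02,
    vB = 0.05
  )
}

#' @rdname default_kinetics
#' @export
default_schedule <- function() {
  parse_frame_schedule("6x15s,3x30s,3x60s,2x90s,2x180s,9x300s,6x600s")
}

#' @rdname default_kinetics
#' @export
default_region_profile <- function() {
  c(
    orbitofrontal_cortex = 36.6, frontal_cortex = 36.3, motor_cortex = 32.7,
    temporal_cortex = 41.7, parietal_cortex = 35.4, occipital_cortex = 33.9,
    insula = 43.8, anterior_cingulate = 44.1, posterior_cingulate = 39.2,
    cerebellum = 43.5, caudate_nucleus = 37.5, putamen = 43.0,
    thalamus = 34.0, entorhinal_cortex = 46.4, hippocampus = 50.4,
    brainstem = 26.9
  )
}

#' Cohort specification for the synthetic generators
#'
#' @param n_male,n_female Subjects per sex.
#' @param sex_effect Fractional male > female VT offset (default 0.15).
#' @param between_subject_cov Between-subject coefficient of variation of the
#'   global VT scaling factor (default 0.13).
#' @param within_subject_noise SD of the fractional day-to-day (retest)
#'   perturbation of K1 and input amplitudes (default 0.05).
#' @param noise_level Target last-frame coefficient of variation of the TAC
#'   measurement noise (default 0.03, typical of a large gray-matter VOI on
#'   a 10-min late frame).
#' @param region_profile Named vector of reference regional VT means.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_male = 6, n_female = 6, sex_effect = 0.15,
                        between_subject_cov = 0.13,
                        within_subject_noise = 0.05, noise_level = 0.03,
                        region_profile = default_region_profile()) {
  stopifnot(
    n_male >= 0, n_female >= 0, n_male + n_female >= 2,
    sex_effect >= 0, sex_effect < 1,
    between_subject_cov >= 0, between_subject_cov < 1,
    within_subject_noise >= 0, within_subject_noise < 1,
    all(region_profile > 0)
  )
  structure(
    list(
      n_male = n_male, n_female = n_female, sex_effect = sex_effect,
      between_subject_cov = between_subject_cov,
      within_subject_noise = within_subject_noise,
      noise_level = noise_level, region_profile = region_profile
    ),
    class = "cohort_spec"
  )
}

# hand-built tri-exponential curve (generator truth)
make_triexp <- function(amplitudes, rates, peak_time) {
  ord <- order(rates, decreasing = TRUE)
  structure(
    list(
      peak_time = peak_time, peak_value = sum(amplitudes),
      amplitudes = amplitudes[ord], rates = rates[ord], rss = 0
    ),
    class = "triexp_curve"
  )
}

#' True (generating) arterial input function
#'
#' Constructs the ground-truth input used by the generators: total plasma as
#' a linear rise to 45 s followed by a tri-exponential decay (amplitudes
#' 300/80/20 kBq/mL, rates 0.01/0.002/0.0002 1/s), whole blood a constant
#' 0.85 of plasma, and a parent fraction declining mono-exponentially at
#' `k_m` = 0.01 1/min.
#'
#' @param peak_time_s Bolus peak time, s.
#' @param amplitudes,rates Plasma tri-exponential parameters (kBq/mL, 1/s).
#' @param blood_ratio Whole-blood-to-plasma concentration ratio.
#' @param k_m_per_min Metabolite (parent-fraction) rate, 1/min.
#' @param delay Input delay, s.
#' @return An [input_function()].
#' @export
true_input_function <- function(peak_time_s = 45,
                                amplitudes = c(300, 80, 20),
                                rates = c(0.01, 0.002, 0.0002),
                                blood_ratio = 0.85,
                                k_m_per_min = 0.01, delay = 0) {
  plasma <- make_triexp(amplitudes, rates, peak_time_s)
  blood <- make_triexp(amplitudes * blood_ratio, rates, peak_time_s)
  pf <- structure(
    list(k_m = k_m_per_min / 60, rss = 0),
    class = "parent_fraction"
  )
  input_function(blood, plasma, pf, delay = delay)
}

#' Generate arterial samples with known ground truth
#'
#' Emulates manual arterial sampling from injection to 100 min with
#' intervals widening over time (every 5 s through the bolus peak, then
#' progressively sparser), plus parent-fraction measurements at eight late
#' times anchored by the t = 0 fraction of 1. Optional multiplicative
#' Gaussian measurement noise.
#'
#' @param input Generating [input_function()] (default
#'   [true_input_function()]).
#' @param noise_cv Fractional measurement noise SD (0 = noiseless).
#' @param seed Optional seed; the same seed reproduces the samples exactly.
#' @return A list with `samples` (tibble `time_s`, `whole_blood_kBq_ml`,
#'   `plasma_kBq_ml`), `metabolites` (tibble `time_s`, `parent_fraction`)
#'   and `truth` (the generating input function).
#' @export
generate_input_function <- function(input = true_input_function(),
                                    noise_cv = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t_blood <- c(
    seq(5, 60, by = 5), seq(70, 120, by = 10), 150, 180, 240, 300,
    420, 600, 900, 1200, 1800, 2400, 3000, 3600, 4200, 4800, 5400, 6000
  )
  wb <- evaluate_input(input, t_blood, "whole_blood")
  pl <- evaluate_input(input, t_blood, "total_plasma")
  if (noise_cv > 0) {
    wb <- pmax(wb * (1 + rnorm(length(wb), 0, noise_cv)), 0)
    pl <- pmax(pl * (1 + rnorm(length(pl), 0, noise_cv)), 0)
  }
  t_met <- c(0, 300, 600, 1200, 1800, 2400, 3600, 4800, 6000)
  pf <- exp(-input$parent_fraction$k_m * t_met)
  if (noise_cv > 0) {
    pf <- pmin(pmax(pf * (1 + rnorm(length(pf), 0, noise_cv)), 0), 1)
    pf[1] <- 1
  }
  list(
    samples = tibble::tibble(
      time_s = t_blood, whole_blood_kBq_ml = wb, plasma_kBq_ml = pl
    ),
    metabolites = tibble::tibble(time_s = t_met, parent_fraction = pf),
    truth = input
  )
}

#' Generate a noisy tissue TAC with known ground truth
#'
#' Forward-simulates the compartment model and adds Gaussian noise with
#' variance proportional to `C(t) exp(lambda t) / duration` — the standard
#' count-statistics heuristic for reconstructed frames (short early frames
#' and late decayed frames are noisier). The proportionality constant is set
#' so that `noise_level` equals the coefficient of variation of the last
#' frame.
#'
#' @param params [compartment_params()].
#' @param input [input_function()].
#' @param schedule [frame_schedule()].
#' @param noise_level Last-frame %COV target as a fraction (0 = noiseless,
#'   returning exactly [simulate_tissue()]; default 0.03).
#' @param seed Optional seed.
#' @param half_life_min Half-life for the decay scaling of the variance.
#' @return A list with `tac` and `truth` (params, true VT, noise level,
#'   seed).
#' @export
generate_tissue_tac <- function(params, input, schedule = default_schedule(),
                                noise_level = 0.03, seed = NULL,
                                half_life_min = f18_half_life_min()) {
  if (!is.null(seed)) set.seed(seed)
  clean <- simulate_tissue(params, input, schedule)
  act <- clean$activity
  if (noise_level > 0) {
    mid <- frame_midpoints(clean)
    dur <- frame_durations(clean)
    lam <- log(2) / (half_life_min * 60)
    v <- pmax(act, 0) * exp(lam * mid) / dur
    n <- length(act)
    sigma2 <- (noise_level * act[n])^2 / v[n]
    act <- act + rnorm(n, 0, sqrt(sigma2 * v))
  }
  list(
    tac = tac(as_schedule(clean), act,
      label = tac_label(clean),
      decay_corrected = TRUE
    ),
    truth = list(
      params = params, vt = vt_from_params(params),
      noise_level = noise_level, seed = seed
    )
  )
}

# regional params: scale K1 so that VT matches the target
region_params <- function(vt_target, base = default_kinetics()) {
  scale <- vt_target / vt_from_params(base)
  compartment_params(base$model,
    K1 = base$K1 * scale, k2 = base$k2,
    k3 = base$k3, k4 = base$k4, vB = base$vB
  )
}

subject_truth <- function(cohort) {
  n <- cohort$n_male + cohort$n_female
  sex <- c(rep("M", cohort$n_male), rep("F", cohort$n_female))
  sdlog <- sqrt(log(1 + cohort$between_subject_cov^2))
  g <- exp(rnorm(n, -sdlog^2 / 2, sdlog))
  mult <- ifelse(sex == "M", 1 + cohort$sex_effect, 1)
  tibble::tibble(
    subject = paste0("S", seq_len(n)), sex = sex,
    factor = g * mult
  )
}

#' Generate a test-retest cohort with known ground truth
#'
#' Each subject has a true regional VT (region profile scaled by a
#' log-normal between-subject factor and the sex offset) shared by both
#' scans; the retest scan perturbs the physiology — K1 and the input
#' amplitudes — by the fractional `within_subject_noise` (a 1-day interscan
#' interval implies biological and procedural, not purely measurement,
#' variability).
#'
#' Two fidelity levels are available: `"vt"` draws measured VT values
#' directly (fast; test = truth, retest = truth scaled by the perturbation),
#' while `"tac"` generates full noisy TACs and per-scan input functions for
#' end-to-end pipeline studies.
#'
#' @param cohort A [cohort_spec()].
#' @param seed Seed (same seed, same cohort).
#' @param level `"vt"` or `"tac"`.
#' @param regions Optional subset of region names.
#' @param input Base [input_function()] for `level = "tac"`.
#' @param schedule Schedule for `level = "tac"`.
#' @return For `"vt"`: a tibble `subject`, `sex`, `region`, `vt_true`,
#'   `vt_test`, `vt_retest`. For `"tac"`: a tibble `subject`, `sex`,
#'   `region`, `scan`, `tac` (list), `input` (list), with the truth table in
#'   the `truth` attribute.
#' @export
generate_test_retest <- function(cohort = cohort_spec(), seed = NULL,
                                 level = c("vt", "tac"), regions = NULL,
                                 input = true_input_function(),
                                 schedule = default_schedule()) {
  level <- match.arg(level)
  if (!is.null(seed)) set.seed(seed)
  profile <- cohort$region_profile
  if (!is.null(regions)) profile <- profile[regions]
  subj <- subject_truth(cohort)
  n <- nrow(subj)
  delta <- rnorm(n, 0, cohort$within_subject_noise) # retest K1 perturbation
  if (level == "vt") {
    out <- tidyr::expand_grid(subj, region = names(profile)) |>
      dplyr::mutate(
        vt_true = unname(profile[.data$region]) * .data$factor,
        vt_test = .data$vt_true,
        vt_retest = .data$vt_true * (1 + delta[match(
          .data$subject,
          subj$subject
        )])
      ) |>
      dplyr::select(-"factor")
    return(out)
  }
  eps <- rnorm(n, 0, cohort$within_subject_noise) # input amplitude factor
  rows <- purrr::map_dfr(seq_len(n), function(i) {
    inp_test <- input
    inp_retest <- input
    sc <- 1 + eps[i]
    inp_retest$plasma$amplitudes <- inp_retest$plasma$amplitudes * sc
    inp_retest$plasma$peak_value <- inp_retest$plasma$peak_value * sc
    inp_retest$whole_blood$amplitudes <-
      inp_retest$whole_blood$amplitudes * sc
    inp_retest$whole_blood$peak_value <-
      inp_retest$whole_blood$peak_value * sc
    purrr::map_dfr(names(profile), function(rg) {
      vt_true <- profile[[rg]] * subj$factor[i]
      p_test <- region_params(vt_true)
      p_retest <- region_params(vt_true * (1 + delta[i]))
      tibble::tibble(
        subject = subj$subject[i], sex = subj$sex[i], region = rg,
        scan = c("test", "retest"),
        tac = list(
          generate_tissue_tac(p_test, inp_test, schedule,
            noise_level = cohort$noise_level
          )$tac,
          generate_tissue_tac(p_retest, inp_retest, schedule,
            noise_level = cohort$noise_level
          )$tac
        ),
        input = list(inp_test, inp_retest),
        vt_true = vt_true
      )
    })
  })
  truth <- dplyr::distinct(rows[, c("subject", "sex", "region", "vt_true")])
  rows <- rows[setdiff(names(rows), "vt_true")]
  attr(rows, "truth") <- truth
  rows
}

#' Generate a single-scan cohort (sexed) with known ground truth
#'
#' Female VT is drawn around the region profile; male VT is additionally
#' scaled by `1 + sex_effect`. At `level = "vt"` the measured value adds a
#' fractional measurement error of SD `within_subject_noise`; at
#' `level = "tac"` full noisy TACs are generated.
#'
#' @inheritParams generate_test_retest
#' @return For `"vt"`: tibble `subject`, `sex`, `region`, `vt_true`, `vt`.
#'   For `"tac"`: tibble `subject`, `sex`, `region`, `tac`, `input` with a
#'   `truth` attribute.
#' @export
generate_cohort <- function(cohort = cohort_spec(), seed = NULL,
                            level = c("vt", "tac"), regions = NULL,
                            input = true_input_function(),
                            schedule = default_schedule()) {
  level <- match.arg(level)
  if (!is.null(seed)) set.seed(seed)
  profile <- cohort$region_profile
  if (!is.null(regions)) profile <- profile[regions]
  subj <- subject_truth(cohort)
  if (level == "vt") {
    out <- tidyr::expand_grid(subj, region = names(profile)) |>
      dplyr::mutate(
        vt_true = unname(profile[.data$region]) * .data$factor,
        vt = .data$vt_true *
          (1 + rnorm(dplyr::n(), 0, cohort$within_subject_noise))
      ) |>
      dplyr::select(-"factor")
    return(out)
  }
  rows <- purrr::map_dfr(seq_len(nrow(subj)), function(i) {
    purrr::map_dfr(names(profile), function(rg) {
      vt_true <- profile[[rg]] * subj$factor[i]
      tibble::tibble(
        subject = subj$subject[i], sex = subj$sex[i], region = rg,
        tac = list(generate_tissue_tac(region_params(vt_true), input,
          schedule,
          noise_level = cohort$noise_level
        )$tac),
        input = list(input),
        vt_true = vt_true
      )
    })
  })
  truth <- rows[, c("subject", "sex", "region", "vt_true")]
  rows <- rows[setdiff(names(rows), "vt_true")]
  attr(rows, "truth") <- truth
  rows
}

#' Default whole-body organ kinetic specification
#'
#' Organ curve parameters on the decay-corrected fraction-of-injected scale,
#' one entry per fitted source organ, spanning the three curve forms.
#' Magnitudes are chosen to be physiologic for a lipophilic tracer with
#' hepatobiliary excretion: sustained brain and liver uptake, a low-fraction
#' fast-clearing blood pool (heart wall, lungs, kidneys, spleen, thyroid)
#' and a large slowly-equilibrating remainder.
#'
#' @return Named list of lists (`form`, `A`, `tau` in hours).
#' @export
default_organ_spec <- function() {
  list(
    brain = list(
      form = "uptake_washout", A = c(0.06, 0.01),
      tau = c(tau_u1 = 0.05, tau_e1 = 40, tau_e2 = 0.8)
    ),
    liver = list(
      form = "uptake_washout", A = c(0.12, 0.02),
      tau = c(tau_u1 = 0.15, tau_e1 = 15, tau_e2 = 0.5)
    ),
    red_marrow = list(
      form = "uptake_washout", A = c(0.025, 0.005),
      tau = c(tau_u1 = 0.08, tau_e1 = 25, tau_e2 = 0.6)
    ),
    heart_wall = list(
      form = "biexp", A = c(0.008, 0.002),
      tau = c(tau_e1 = 0.4, tau_e2 = 4)
    ),
    kidneys = list(
      form = "biexp", A = c(0.03, 0.01),
      tau = c(tau_e1 = 0.5, tau_e2 = 5)
    ),
    lungs = list(
      form = "biexp", A = c(0.025, 0.006),
      tau = c(tau_e1 = 0.3, tau_e2 = 6)
    ),
    spleen = list(
      form = "biexp", A = c(0.006, 0.002),
      tau = c(tau_e1 = 0.4, tau_e2 = 5)
    ),
    thyroid = list(
      form = "biexp", A = c(0.0008, 0.0002),
      tau = c(tau_e1 = 0.5, tau_e2 = 4)
    )
  )
}

eval_organ_spec <- function(spec, time_h, c_const = log(2)) {
  drop(organ_design(spec$form, time_h, spec$tau[organ_tau_names(spec$form)],
    c_const
  ) %*% spec$A)
}

organ_spec_nca <- function(spec, half_life_min = f18_half_life_min(),
                           c_const = log(2)) {
  m <- structure(
    list(
      form = spec$form, A = c(A1 = spec$A[1], A2 = spec$A[2]),
      tau = spec$tau[organ_tau_names(spec$form)], c_const = c_const,
      rss = 0, decay_corrected = TRUE, organ = NA_character_
    ),
    class = "organ_curve"
  )
  nca_analytic(m, half_life_min)$nca
}

#' Generate a whole-body dosimetry study with known ground truth
#'
#' Draws organ time-activity curves from the three organ curve forms (on the
#' decay-corrected fraction scale), applies physical decay, and samples them
#' at the 13 whole-body scan times (11 passes to 90 min, then 150 and 270
#' min). The total body is conserved (no excretion route is simulated), so
#' the remainder is total minus the sum of sources at every time.
#'
#' @param organ_spec Named list as [default_organ_spec()].
#' @param f_si Fraction of injected activity entering the small intestine
#'   (carried through as ground truth for the GI model).
#' @param noise_cv Fractional measurement noise on the sampled organ values.
#' @param seed Optional seed.
#' @param times_min Whole-body scan times, minutes.
#' @param half_life_min Physical half-life, minutes.
#' @return A list: `table` (tibble `time_h`, organ columns, `total_body`,
#'   `remainder`; physical, not decay-corrected), `truth` (organ spec, true
#'   NCAs, `f_si`).
#' @export
generate_wb_study <- function(organ_spec = default_organ_spec(),
                              f_si = 0.6175, noise_cv = 0, seed = NULL,
                              times_min = c(
                                4, 12, 20, 28, 36, 44, 52, 60, 68, 76, 88,
                                150, 270
                              ),
                              half_life_min = f18_half_life_min()) {
  if (!is.null(seed)) set.seed(seed)
  time_h <- times_min / 60
  decay <- exp(-lambda_phys_per_h(half_life_min) * time_h)
  corrected <- vapply(
    organ_spec, eval_organ_spec, numeric(length(time_h)),
    time_h = time_h
  )
  if (any(rowSums(corrected) > 1)) {
    abort("organ fractions sum to more than 1; reduce the organ spec")
  }
  tbl <- tibble::as_tibble(corrected * decay)
  if (noise_cv > 0) {
    tbl <- dplyr::mutate(tbl, dplyr::across(
      dplyr::everything(),
      ~ pmax(.x * (1 + rnorm(dplyr::n(), 0, noise_cv)), 0)
    ))
  }
  tbl <- dplyr::bind_cols(tibble::tibble(time_h = time_h), tbl)
  tbl$total_body <- decay
  tbl <- remainder_tac(tbl, total_col = "total_body")
  truth_nca <- vapply(organ_spec, organ_spec_nca, numeric(1),
    half_life_min = half_life_min
  )
  list(
    table = tbl,
    truth = list(
      organ_spec = organ_spec,
      nca = tibble::tibble(
        organ = names(truth_nca),
        nca = unname(truth_nca)
      ),
      f_si = f_si
    )
  )
}

#' Generate a block phantom for voxel-wise Logan testing
#'
#' Builds a label volume of contiguous blocks along the x axis (every voxel
#' labelled exactly once), one block per region, fills each block with the
#' region's compartmental TAC and adds iid Gaussian noise.
#'
#' @param region_vt Named vector of true regional VT values.
#' @param dim Grid size, length 3 (>= 8 per side recommended).
#' @param noise_sd Absolute iid noise SD, kBq/mL.
#' @param seed Optional seed.
#' @param input [input_function()].
#' @param schedule [frame_schedule()].
#' @param vB Blood volume fraction of the voxel signal. Default 0: the
#'   phantom exists to validate the Logan estimator, which carries no
#'   blood-volume term, so its reference signal is blood-free.
#' @return A list: `volume` ([dynamic_volume()]), `labels`, `region_map`,
#'   `truth` (tibble `region`, `vt`).
#' @export
generate_phantom <- function(region_vt = c(high = 42, low = 27),
                             dim = c(8, 8, 8), noise_sd = 0, seed = NULL,
                             input = true_input_function(),
                             schedule = default_schedule(), vB = 0) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(dim) == 3, all(dim >= 2))
  nr <- length(region_vt)
  nf <- nrow(schedule)
  labels <- array(0L, dim = dim)
  breaks <- round(seq(0, dim[1], length.out = nr + 1))
  data <- array(0, dim = c(dim, nf))
  for (i in seq_len(nr)) {
    xs <- (breaks[i] + 1):breaks[i + 1]
    labels[xs, , ] <- i
    rp <- region_params(region_vt[[i]])
    rp$vB <- vB
    clean <- simulate_tissue(rp, input, schedule)
    for (f in seq_len(nf)) {
      block <- array(clean$activity[f], dim = c(length(xs), dim[2], dim[3]))
      if (noise_sd > 0) {
        block <- block + rnorm(length(block), 0, noise_sd)
      }
      data[xs, , , f] <- block
    }
  }
  list(
    volume = dynamic_volume(data, schedule),
    labels = labels,
    region_map = setNames(seq_len(nr), names(region_vt)),
    truth = tibble::tibble(region = names(region_vt), vt = unname(region_vt))
  )
}
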