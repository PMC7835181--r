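---
title: "Models and methods in petkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in petkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petkin)
```

petkin quantifies dynamic brain PET studies with arterial sampling and
assembles whole-body internal dosimetry. This vignette is the package's own
account of the science: the models, the conventions behind every numeric
choice, what the synthetic-data generator does and does not emulate, and the
known limitations.

## Data model and conventions

A dynamic acquisition is a **frame schedule**: half-open intervals
`[start, end)` in seconds, strictly ordered, positive durations, gaps
allowed (a split-session acquisition is just a schedule with a gap). The
canonical brain protocol is 31 frames over 120 min
(`"6x15s,3x30s,3x60s,2x90s,2x180s,9x300s,6x600s"`). A **time-activity
curve** (TAC) attaches one activity concentration per frame and is treated
numerically as a sample at the frame midpoint — the standard convention when
the vendor's frame-weighting is unknown. Internal time is always seconds;
user-facing reports use minutes; dosimetry uses hours.

Two decay conventions coexist deliberately. Brain TACs are decay-corrected
to injection, because distribution volumes are defined on corrected
concentrations. Whole-body organ curves for dosimetry are *physical*
(not corrected) fractions of injected activity, because cumulated activity
is an integral of physical decay. `decay_correct()` moves between the two
and refuses to correct twice; the correction is an exact involution.

Running integrals of TACs use the trapezoid rule through the midpoints with
an anchored value of 0 at `t = 0` — activity cannot precede the bolus — and
constant extension from the last midpoint to the last frame end. This makes
the parse → midpoint → integral pipeline exact for piecewise-linear data.
One visible consequence: for a curve that is already non-zero in the first
frame, the anchor shaves half a first-panel area off every cumulative
integral; on the Logan plot this shifts the *intercept* (a diagnostic) and
leaves the *slope* (the estimand) untouched.

## Arterial input function

Whole blood and total plasma are modelled as a linear rise from 0 at
injection to the peak, then a tri-exponential decay,

$$C(t) = \sum_{i=1}^{3} a_i e^{-\lambda_i (t - t_{peak})}, \qquad t \ge t_{peak},$$

with amplitudes $a_i \ge 0$ and rates sorted descending. The rise is linear
rather than a fitted ascending exponential: manually drawn early samples are
too sparse to constrain an ascending limb, and the linear-rise convention
keeps the closed-form integrals simple. Continuity at the peak is built in
because the rise ends at the fitted curve value $\sum a_i$.

Fitting uses variable projection: the three rates are optimised in log
space from five dispersed deterministic starts, the amplitudes are solved
linearly with non-negativity enforced by a small active-set step, and a
joint quasi-Newton polish finishes all six parameters. On noiseless
tri-exponential samples this recovers the generating parameters to better
than 1e-6 relative — the round-trip tolerance the test suite asserts.

The parent (unmetabolized) fraction is mono-exponential, $f_p(t) = e^{-k_m t}$,
anchored at 1 at injection since no radiometabolites exist at `t = 0`. The
rate is found by bracketing the least-squares objective on a log grid before
local refinement — the objective is flat for large rates, which defeats
plain golden-section search. The metabolite-corrected input is
$C_p(t) = C_{plasma}(t)\, f_p(t)$, so the parent-plasma integral is just the
plasma model with every rate shifted by $k_m$: closed form, no quadrature.
The plasma free fraction (PFF) is stored as metadata only and never rescales
VT — reported distribution volumes are `VT`, not `VT/fp`.

The blood-to-scanner **delay** is estimated once per scan on the composite
cortical TAC over its first 5 min (densely covered by the 15-s frames) and
then held fixed for all regions. A coarse 2-s grid over ±30 s using the
cheap one-tissue model brackets the optimum; a fine 0.5-s pass refits the
two-tissue model, whose flexibility removes the early-time mismatch bias
that a 1TCM objective alone exhibits when the true kinetics are strongly
biphasic. On generated data the true shift is recovered exactly at the grid
resolution.

## Compartment models

The reversible 1TCM and 2TCM are fitted with a fixed 5% blood volume:

$$C_{model}(t) = (1 - v_B)\, h(t) \otimes C_p(t) + v_B\, C_{blood}(t),$$

with impulse response $h(t) = K_1 e^{-k_2 t}$ (1TCM) or the standard
two-exponential decomposition from $K_1 \ldots k_4$ (2TCM). $v_B$ multiplies
the fitted *whole-blood* curve — the conventional choice; the acquisition
protocol fixes only its value. The convolution is evaluated by
an exact exponential ⊗ linear-segment recursion (compiled) on a graded
lattice — 0.5 s through the bolus, 2 s to 15 min, 5 s beyond, plus all frame
midpoints and input kink points — so the only approximation is the
piecewise-linear representation of the input itself (relative error a few
1e-6 at the frame midpoints). Irreversible models ($k_4 = 0$) are out of
scope and rejected at construction.

Fits are bounded weighted least squares in log-parameter space
($K_1 \in (0, 2]$ mL/cm³/min, $k_{2..4} \in (0, 1]$ 1/min), uniform weights
by default (the vendor weighting in the original pipeline is unreported;
a duration/decay weighting is available), three dispersed starts plus — for
the 2TCM — a start at the 1TCM solution with a vanishing second compartment.
That extra start guarantees the nesting property (2TCM RSS never exceeds
1TCM RSS beyond optimizer tolerance), which uncorrected multi-start can
violate on noisy data. Model comparison uses
$AIC = n \ln(RSS/n) + 2k$ with $k = 2$ or 4; the fixed $v_B$ and delay are
not counted. AICc was considered — at $n = 31$ the correction is material —
but plain AIC is the criterion named for the protocol being mirrored, so
AIC it is; ties break to the 1TCM by parsimony.

## Logan graphical analysis

For reversible kinetics the transformed coordinates
$x_i = \int_0^{t_i} C_p \,d\tau / C_t(t_i)$ and
$y_i = \int_0^{t_i} C_t \,d\tau / C_t(t_i)$ become linear in the late-time
regime with slope VT. The tissue integral is the anchored trapezoid above;
the input integral is closed-form. `t*` is applied to frame midpoints
(first included midpoint ≥ t\*, default 40 min), an unambiguous and
testable rule; at 40 min the full schedule contributes 10 points. No
blood-volume term enters the transform (standard formulation), with a
consequence worth stating plainly: on a signal that *contains* 5% blood,
the Logan slope estimates $(1-v_B)V_T + v_B V_{blood}$, a few percent below
the tissue VT. The package therefore validates the estimator itself on
blood-free synthetic signal, where the noiseless bias at t\* = 40 is below
1% for the default kinetics, and compares Logan against the 2TCM — not
against truth — whenever the signal carries blood, mirroring how the two
methods are compared on real data. Under noise the Logan slope is biased
low (the noisy denominator correlates with both axes); the test suite
checks the resulting ordering, mean Logan VT ≤ mean 2TCM VT.

Acquisition windows keep the frames wholly inside their segments. For the
coffee-break window (0–60 plus 90–120 min) that retains 28 of 31 frames
(25 before 60 min, 3 after 90 min). The tissue integral bridges the gap by
linear interpolation between the last retained midpoint before it and the
first after it — the minimal assumption, and testable: on noiseless data the
coffee-break VT agrees with the full-window value within 1%, while a plain
0–60 truncation underestimates. The input integral has no gap problem (it
is closed-form). `time_stability_table()` assembles the TRV-per-window and
bias-versus-full-window summaries across a cohort; voxel-wise Logan shares
the regional code path through a compiled per-voxel slope routine and
reports the NaN fraction (voxels with non-positive activity at included
midpoints, or fewer than 3 usable points).

## Reliability statistics

Test-retest variability is the paired relative difference
$TRV = 2(V_T^{test} - V_T^{retest})/(V_T^{test} + V_T^{retest})$, reported
in percent, with aTRV its absolute value; both are scale-invariant and TRV
is antisymmetric under swapping the scans. Reliability is the one-way
mean-squares ICC, $(BSMSS - WSMSS)/(BSMSS + WSMSS)$, with BSMSS over
$n - 1$ degrees of freedom (scaled by the $k = 2$ repeats) and WSMSS over
$n(k-1)$; the df convention beyond the formula itself is not pinned down in
the protocol being mirrored, and the one-way form matches the printed
formula exactly. Inter-subject variability is the sample-SD %COV
(n−1 denominators throughout — the cohorts are small). Bland-Altman
agreement reports bias ± SD with 1.96·SD limits on per-subject regional VT
pairs. All of these are pure tabular functions over paired-VT tibbles, so
they compose with any upstream quantification.

## Whole-body dosimetry

Organ curves on the fraction-of-injected scale use three constrained forms
parameterised by half-times ($c = \ln 2$ by default; settable to the
rounded 0.69 for literal replication of half-time tables):

* bi-exponential washout — heart wall, kidneys, lungs, spleen, thyroid;
* uptake × washout — brain, liver, red marrow;
* uptake to plateau plus washout — the remainder of the body.

Fitting mirrors the input-function strategy (log-space half-times, linear
non-negative amplitudes, joint polish); an unacceptable fit (relative
residual above 25%) raises an error that recommends the trapezoid route,
which is exactly what the gallbladder, testes and urinary bladder need in
practice. Analytic NCAs are closed-form infinite integrals; each
exponential term contributes $A\tau/c$. The plateau form only has a finite
integral when the fit was made on decay-corrected data and physical decay
is reapplied analytically — fitting it to physical data with a non-zero
plateau is rejected rather than silently diverging. The trapezoid NCA
anchors at (0, 0) — organs fill over minutes, so zero activity at injection
is the physical boundary condition — and appends a tail that assumes
physical decay only beyond the last sample: conservative, since any further
biological excretion could only reduce the integral. Every NCA respects the
total-decay bound $T_{1/2}/\ln 2 = 2.6395$ h per unit injected.

The ICRP-30 GI chain takes the fraction `f_si` entering the small intestine
as a bolus at `t = 0` (the stomach compartment is bypassed — the input
fraction is measured at the intestinal level) and propagates it through
SI → ULI → LLI with biological rates 6, 1.8 and 1 day⁻¹ plus physical
decay; the NCAs are the closed-form chain products and are *linear* in
`f_si`, so cohort statistics of the NCAs are the same linear transform of
the fraction statistics. With the four measured fractions (63%, 49%, 67%,
68%) this reproduces the published small-intestine row (0.982 ± 0.139,
minimum 0.779 MBq·h/MBq) and the ULI mean (0.541 vs 0.539) to a fraction of
a percent. The LLI mean lands at 0.0965 against a printed 0.099 — a 2.6%
gap the chain model cannot close and which likely reflects an internal
convention of the original dosimetry software; it is documented rather than
tuned away.

Phantom S-value libraries are not bundled (they are licensed artifacts of
the dosimetry phantoms); `organ_doses_from_nca()` contracts NCAs against
any user-supplied delimited S-matrix, and `effective_dose()` applies the
bundled ICRP-60 tissue weights (which sum to 1, enforced). Consequently the
published effective dose is *not* recomputed here — it requires the phantom
doses — and the dose pipeline is validated on toy matrices instead.

## The synthetic-data generator

The generator emulates the study design end to end with known ground truth:
arterial sampling dense through the bolus and sparse to 100 min; a
tri-exponential plasma curve (amplitudes 300/80/20 kBq/mL, rates
0.01/0.002/0.0002 s⁻¹, peak at 45 s) with whole blood at 0.85 of plasma and
a parent-fraction rate of 0.01 min⁻¹ (roughly 55% parent at 60 min —
mid-range metabolism for a lipophilic tracer); 2TCM tissue kinetics; a
16-region VT profile spanning 26.9 (brainstem) to 50.4 (hippocampus); a
15% male > female VT offset on top of a 13% between-subject log-normal
spread; day-apart retest perturbation of K1 and input amplitudes (5% SD) —
physiological rather than purely measurement variability, as befits a
1-day interscan interval; and a 13-time-point whole-body study (11 passes
to 90 min, then 150 and 270 min) built from the three organ curve forms
with activity conservation (remainder = total − sources at every time).

Two defaults deserve their rationale spelled out, because the observable
behaviour of the whole pipeline hangs on them.

**Reference kinetics** are K1 = 0.42 mL/cm³/min, k2 = 0.18, k3 = 0.34,
k4 = 0.02 min⁻¹ (VT = 42.0). Micro-parameters for this tracer class are
not published, so they were chosen to make the synthetic tracer match the
real one on every *observable* at once: VT in the reported 27–50 range;
late-time equilibration fast enough that Logan at t\* = 40 min is nearly
unbiased on clean data (−0.6% here; slow-binding parameter sets that yield
the same VT, e.g. k4 below 0.01 min⁻¹, push the Logan bias past −20% and
would contradict the reported method agreement); and a second compartment
pronounced enough that the AIC prefers the 2TCM essentially always on noisy
data, as observed in practice. Regional profiles scale K1 at fixed rate
constants, so VT scales linearly per region.

**TAC noise** is Gaussian with variance proportional to
$C(t)\,e^{\lambda t}/\Delta t$ — the count-statistics heuristic (short early
frames and decayed late frames are noisier) — scaled so the last-frame COV
equals `noise_level`, default 3%, typical of a large gray-matter VOI on a
10-min frame two half-lives after injection. At this level the early peak
frames carry roughly 5–6% noise. Noise is Gaussian, not Poisson:
reconstructed frame values are already weighted sums over millions of
counts, and Gaussianity is the standard simulation convention at the
regional level.

What the generator does **not** emulate: reconstruction artifacts and
spatially correlated noise (voxel noise is iid in the phantom), motion,
partial-volume effects, atlas misparcellation, plasma-metabolite model
misspecification (the generated parent fraction *is* mono-exponential), and
inter-subject variation of the micro-parameter *ratios* (only the VT scale
varies between subjects). Passing tests therefore demonstrate correctness
of the estimators under the stated model, not robustness to every artifact
of real data.

Every generator is deterministic under a fixed seed. Test-retest cohorts
can be produced at two fidelity levels: `"vt"` draws measured VT values
directly (used for the 500-replicate reliability bands — each replicate is
a 12-subject cohort) and `"tac"` generates full noisy TACs with per-scan
input functions for end-to-end pipeline studies (used at 4-subject scale
for the window-stability orderings). Problem sizes in the shipped tests —
20 noiseless recovery draws, 50 Logan-vs-2TCM replicates, 200
model-selection replicates, 500 reliability replicates, 8³ phantoms — are
chosen so the whole suite completes in a few minutes on one core while
keeping the Monte-Carlo standard errors well inside the asserted bands.

## Numerical choices and degenerate inputs

* Optimisation is `nlminb` on log-parameters everywhere; bounds become box
  constraints in log space; relative tolerances 1e-13-1e-15 so that
  noiseless round trips recover parameters to ~1e-9.
* All-zero TACs, all-zero blood curves, fractions outside [0, 1], ragged
  or non-monotone TAC tables, label volumes off-grid, windows retaining no
  frames, and Logan transforms with no positive tissue values all raise
  typed errors early, with the offending token, line or label named.
* Coincident 2TCM eigenvalues (a measure-zero configuration) are nudged
  apart by 1e-9 relative rather than special-cased.
* Negative frame values are legal data (low-count noise) and flagged, not
  clipped; the remainder organ curve *is* floored at zero with a warning,
  because a negative remainder is a bookkeeping violation, not noise.

## Known limitations

Voxel-wise Logan inherits the well-known noise-dependent negative bias of
graphical methods; no PCA or multilinear correction is provided.
Dispersion correction and image-derived input functions are out of scope.
The GI model exposes `f_si` as an input rather than estimating it from an
abdominal VOI (the plateau-window convention for that estimate is not
standardised). Organ doses require an external S-matrix, so effective dose
is only computable once phantom data are supplied. The AIC/AICc choice and
the vendor weighting scheme remain open questions of the mirrored protocol;
both options are exposed as arguments.
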