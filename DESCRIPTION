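Package: petkin
Title: Kinetic Modelling, Reliability and Dosimetry for Dynamic PET Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification toolkit for dynamic positron emission tomography
    (PET) brain studies with arterial blood sampling, and for whole-body
    radiation dosimetry. Models arterial input functions (tri-exponential
    blood/plasma curves with mono-exponential radiometabolite correction and
    delay estimation), fits one- and two-tissue compartment models with fixed
    blood volume to regional time-activity curves, estimates total distribution
    volume by Logan graphical analysis (regional and voxel-wise) including
    split-session ("coffee-break") and shortened acquisition windows, computes
    test-retest variability, intra-class correlation and Bland-Altman
    agreement statistics, and assembles internal dosimetry from organ
    time-activity curves (constrained organ curve fits, normalized cumulated
    activities, the ICRP-30 gastrointestinal tract model and ICRP-60 effective
    dose weighting). A synthetic-data generator with known ground truth
    emulates a complete first-in-human study design for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
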