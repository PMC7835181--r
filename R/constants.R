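#' Physical half-life of fluorine-18
#'
#' Standard physical half-life of the positron emitter F-18, in minutes.
#' Used as the default throughout decay correction, dosimetry tails and the
#' ICRP-30 gastrointestinal model.
#'
#' @return Half-life in minutes (109.771).
#' @export
#' @examples
#' f18_half_life_min()
f18_half_life_min <- function() 109.771

# physical decay constant, per hour, for a half-life given in minutes
lambda_phys_per_h <- function(half_life_min = f18_half_life_min()) {
  log(2) / (half_life_min / 60)
}
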