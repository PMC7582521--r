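#' Ground truth for a simulated fibrinolysis time course
#'
#' @param Fmax Plateau fluorescence (AU) released at complete lysis.
#' @param k First-order lysis rate constant (1/min).
#' @param sampling_interval Minutes between samples (default 15 min, the
#'   standard manual sampling interval).
#' @param noise_sd Additive Gaussian noise (AU).
#' @return An object of class `lysis_truth`.
#' @export
lysis_truth <- function(Fmax = 10000, k = 0.01, sampling_interval = 15,
                        noise_sd = 0) {
  if (Fmax < 0) stop("`Fmax` must be >= 0", call. = FALSE)
  if (k < 0) stop("`k` must be >= 0", call. = FALSE)
  stop_if_not_scalar_pos(sampling_interval, "sampling_interval")
  structure(list(Fmax = Fmax, k = k, sampling_interval = sampling_interval,
                 noise_sd = noise_sd), class = "lysis_truth")
}

#' Simulate a fibrinolysis fluorescence-release time course
#'
#' Fluorescence released from a labeled clot follows the saturating curve
#' `F(t) = Fmax * (1 - exp(-k t))`, sampled at multiples of the sampling
#' interval starting at t = 0, with additive Gaussian noise. Fluorescence
#' is truncated at zero (a photon count cannot be negative).
#'
#' @param truth A [lysis_truth()].
#' @param duration Total duration (min); must be at least one sampling
#'   interval.
#' @param seed Optional integer seed.
#' @param dilution_factor Dilution applied to each sample before reading
#'   (recorded on the output; default 12-fold).
#' @return A `lysis_series` object (see [lysis_series()]) with attribute
#'   `truth`.
#' @export
simulate_lysis <- function(truth = lysis_truth(), duration = 180,
                           seed = NULL, dilution_factor = 12) {
  stopifnot(inherits(truth, "lysis_truth"))
  if (duration < truth$sampling_interval)
    stop("`duration` must cover at least one sampling interval",
         call. = FALSE)
  time <- seq(0, duration, by = truth$sampling_interval)
  f <- truth$Fmax * (1 - exp(-truth$k * time))
  if (truth$noise_sd > 0)
    f <- f + with_seed_or_not(seed, rnorm(length(f), 0, truth$noise_sd))
  out <- lysis_series(time, pmax(f, 0), dilution_factor = dilution_factor)
  attr(out, "truth") <- truth
  out
}
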