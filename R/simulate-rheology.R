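#' Ground truth for a simulated strain-stiffening clot
#'
#' Parameters of the piecewise constitutive model used to generate
#' stress-ramp curves: the differential modulus is constant (`K0`) up to the
#' stiffening onset `sigma0`, follows the power law `K0 * (sigma/sigma0)^m`
#' up to the rupture stress `sigmaR`, and drops to
#' `post_rupture_fraction` of its pre-rupture value beyond. The power-law
#' stress dependence with exponent `m = 3/2` is the scaling expected for
#' semiflexible biopolymer networks; real clot data constrain no specific
#' functional form, so this model is a documented stand-in with known
#' ground truth.
#'
#' @param K0 Linear differential modulus (Pa).
#' @param sigma0 Onset stress of strain-stiffening (Pa).
#' @param m Stiffening exponent (dimensionless, >= 0).
#' @param sigmaR Rupture stress (Pa); must exceed `sigma0`.
#' @param post_rupture_fraction Residual modulus fraction after rupture,
#'   in `[0, 1)`.
#' @return An object of class `nonlinear_truth`.
#' @export
nonlinear_truth <- function(K0 = 50, sigma0 = 2, m = 1.5, sigmaR = 500,
                            post_rupture_fraction = 0.01) {
  stop_if_not_scalar_pos(K0, "K0")
  stop_if_not_scalar_pos(sigma0, "sigma0")
  stop_if_not_scalar_pos(sigmaR, "sigmaR")
  if (sigmaR <= sigma0)
    stop("`sigmaR` must exceed `sigma0`", call. = FALSE)
  if (m < 0) stop("`m` must be >= 0", call. = FALSE)
  if (post_rupture_fraction < 0 || post_rupture_fraction >= 1)
    stop("`post_rupture_fraction` must be in [0, 1)", call. = FALSE)
  structure(list(K0 = K0, sigma0 = sigma0, m = m, sigmaR = sigmaR,
                 post_rupture_fraction = post_rupture_fraction),
            class = "nonlinear_truth")
}

# strain from exact integration of d gamma = d sigma / K'(sigma),
# closed form per piece of the constitutive model
piecewise_strain <- function(sigma, truth) {
  K0 <- truth$K0; s0 <- truth$sigma0; m <- truth$m; sR <- truth$sigmaR
  g0 <- s0 / K0
  stiff <- function(s) {
    if (abs(m - 1) < 1e-12) g0 + g0 * log(s / s0)
    else g0 + g0 * ((s / s0)^(1 - m) - 1) / (1 - m)
  }
  gam <- ifelse(sigma <= s0, sigma / K0, NA_real_)
  mid <- sigma > s0 & sigma <= sR
  gam[mid] <- stiff(sigma[mid])
  post <- sigma > sR
  if (any(post)) {
    gR <- stiff(sR)
    K_res <- truth$post_rupture_fraction * K0 * (sR / s0)^m
    gam[post] <- gR + (sigma[post] - sR) / K_res
  }
  gam
}

# differential modulus of the constitutive model (used by tests/oracles)
piecewise_kprime <- function(sigma, truth) {
  K <- ifelse(sigma <= truth$sigma0, truth$K0,
              truth$K0 * (sigma / truth$sigma0)^truth$m)
  K[sigma > truth$sigmaR] <-
    truth$post_rupture_fraction * truth$K0 *
    (truth$sigmaR / truth$sigma0)^truth$m
  K
}

#' Simulate a stress-ramp curve with known ground truth
#'
#' Evaluates the piecewise strain-stiffening model of [nonlinear_truth()] on
#' the log-spaced stress grid of a [ramp_protocol()], obtaining the strain
#' at each applied stress by exact (closed-form) integration of
#' `d gamma = d sigma / K'(sigma)`. Measurement noise is multiplicative
#' log-normal on the strain, reflecting the decade-spanning magnitudes of a
#' logarithmic ramp.
#'
#' @param truth A [nonlinear_truth()].
#' @param protocol A [ramp_protocol()].
#' @param noise_sd_rel Relative (log-scale) standard deviation of the
#'   multiplicative strain noise; 0 gives noiseless curves.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return A `stress_ramp` object (see [stress_ramp()]) with attributes
#'   `truth` (the generator parameters) and `censoring` (flags set when
#'   `sigma0` or `sigmaR` fall outside the applied stress range).
#' @export
simulate_stress_ramp <- function(truth = nonlinear_truth(),
                                 protocol = ramp_protocol(),
                                 noise_sd_rel = 0, seed = NULL) {
  stopifnot(inherits(truth, "nonlinear_truth"))
  sigma <- make_ramp_grid(protocol)
  gamma <- piecewise_strain(sigma, truth)
  if (noise_sd_rel > 0)
    gamma <- with_seed_or_not(seed,
      gamma * exp(rnorm(length(gamma), 0, noise_sd_rel)))
  censoring <- c(onset_censored  = truth$sigma0 > max(sigma) ||
                                   truth$sigma0 < min(sigma),
                 rupture_censored = truth$sigmaR > max(sigma))
  out <- stress_ramp(sigma, gamma)
  attr(out, "truth") <- truth
  attr(out, "censoring") <- censoring
  out
}

#' Ground truth for a simulated polymerization time course
#'
#' @param Gss Steady-state storage modulus G' (Pa).
#' @param Gss2 Steady-state loss modulus G'' (Pa).
#' @param tau Saturation time constant (s).
#' @param noise_sd Additive Gaussian noise (Pa).
#' @return An object of class `polymerization_truth`.
#' @export
polymerization_truth <- function(Gss = 80, Gss2 = 8, tau = 600,
                                 noise_sd = 0) {
  stop_if_not_scalar_pos(Gss, "Gss")
  stop_if_not_scalar_pos(tau, "tau")
  structure(list(Gss = Gss, Gss2 = Gss2, tau = tau, noise_sd = noise_sd),
            class = "polymerization_truth")
}

#' Simulate a clot polymerization time series
#'
#' Storage and loss moduli rise as saturating exponentials
#' `G(t) = Gss * (1 - exp(-t/tau))` with additive Gaussian noise, emulating
#' small-amplitude oscillatory monitoring of clot formation (default: 3 h
#' sampled at 0.5 Hz, the standard protocol).
#'
#' @param truth A [polymerization_truth()].
#' @param duration Total duration (s).
#' @param rate Sampling rate (Hz).
#' @param seed Optional integer seed.
#' @return A `rheology_ts` data frame with columns `time`, `Gp`, `Gpp` and
#'   attribute `truth`.
#' @export
simulate_polymerization <- function(truth = polymerization_truth(),
                                    duration = 3 * 3600, rate = 0.5,
                                    seed = NULL) {
  stopifnot(inherits(truth, "polymerization_truth"))
  stop_if_not_scalar_pos(duration, "duration")
  stop_if_not_scalar_pos(rate, "rate")
  time <- seq(0, duration, by = 1 / rate)
  rise <- 1 - exp(-time / truth$tau)
  n <- length(time)
  noise <- if (truth$noise_sd > 0)
    with_seed_or_not(seed, matrix(rnorm(2 * n, 0, truth$noise_sd), ncol = 2))
  else matrix(0, n, 2)
  out <- data.frame(time = time,
                    Gp  = truth$Gss  * rise + noise[, 1],
                    Gpp = truth$Gss2 * rise + noise[, 2])
  class(out) <- c("rheology_ts", "data.frame")
  attr(out, "truth") <- truth
  out
}
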