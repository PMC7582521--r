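# rheology feature extraction: polymerization fits, differential modulus,
# onset, rupture, full feature set, normalization

test_that("polymerization fit recovers plateau and time constant", {
  # constant series: plateau exact through fit or fallback
  ts <- data.frame(time = seq(0, 900, by = 10), Gp = 50, Gpp = 5)
  f <- fit_polymerization(ts)
  expect_lt(abs(f$Gp_ss - 50), 1e-6)
  # noiseless exponential: (Gss, tau) recovered within 0.1%
  sim <- simulate_polymerization(polymerization_truth(Gss = 80, tau = 600))
  f2 <- fit_polymerization(sim)
  expect_lt(abs(f2$Gp_ss - 80) / 80, 1e-3)
  expect_lt(abs(f2$tau - 600) / 600, 1e-3)
  expect_gt(f2$fit_quality, 0.999)
  # record spanning < 3 time constants is flagged low-confidence
  short <- simulate_polymerization(polymerization_truth(Gss = 80, tau = 600),
                                   duration = 1200)
  expect_true("low_confidence" %in% fit_polymerization(short)$flags)
  expect_error(fit_polymerization(data.frame(time = 1:5, Gp = 1, Gpp = 1)),
               "10 samples")
})

test_that("noisy polymerization replicates recover the plateau", {
  errs <- vapply(1:100, function(s) {
    sim <- simulate_polymerization(
      polymerization_truth(Gss = 80, tau = 600, noise_sd = 2), seed = s)
    abs(fit_polymerization(sim)$Gp_ss - 80) / 80
  }, numeric(1))
  expect_lt(median(errs), 0.02)
})

test_that("differential modulus equals the local stress-strain slope", {
  sigma <- default_grid[1:60]
  hook <- stress_ramp(sigma, sigma / 100)
  kc <- differential_modulus(hook)
  expect_equal(kc$Kp, rep(100, 60), tolerance = 1e-9)
  # power-law regime: within 5% of the closed form for 4*sigma0..sigmaR/2
  tr <- nonlinear_truth(K0 = 50, sigma0 = 2, m = 1.5, sigmaR = 500)
  r <- simulate_stress_ramp(tr)
  kc2 <- differential_modulus(r)
  sel <- kc2$sigma >= 8 & kc2$sigma <= 250
  expect_true(all(abs(kc2$Kp[sel] / (50 * (kc2$sigma[sel] / 2)^1.5) - 1)
                  < 0.05))
  # too-short input is rejected at construction
  expect_error(stress_ramp(1:4, (1:4) / 10), "5 points")
  # repeated strain values are flagged, not propagated
  bad <- stress_ramp(c(1, 2, 3, 4, 5), c(1, 2, 2, 2, 3) / 10)
  kb <- differential_modulus(bad)
  expect_true(any(kb$flagged))
})

test_that("onset detection finds the end of the linear regime", {
  # exact Hookean: no onset, K0 = global slope
  sigma <- default_grid[1:80]
  hook <- stress_ramp(sigma, sigma / 100)
  o <- detect_onset(hook)
  expect_true(o$no_onset)
  expect_equal(o$K0, 100, tolerance = 1e-9)
  # noiseless curve: onset within one grid step of the generator truth
  tr <- nonlinear_truth(K0 = 50, sigma0 = 2, m = 1.5, sigmaR = 500)
  r <- simulate_stress_ramp(tr)
  o2 <- detect_onset(r)
  expect_false(o2$no_onset)
  expect_lte(grid_step(o2$sigma0, 2), 1)
  expect_equal(o2$K0, 50, tolerance = 1e-6)
  expect_equal(o2$gamma0, o2$sigma0 / 50, tolerance = 1e-6)
})

test_that("noisy onset localization stays within two grid steps (median)", {
  errs <- vapply(1:100, function(s) {
    r <- simulate_stress_ramp(
      nonlinear_truth(K0 = 50, sigma0 = 2, m = 1.5, sigmaR = 500),
      noise_sd_rel = 0.02, seed = s)
    o <- detect_onset(r)
    if (is.na(o$sigma0)) return(NA_real_)
    grid_step(o$sigma0, 2)
  }, numeric(1))
  expect_lte(median(errs, na.rm = TRUE), 2)
  expect_lt(mean(is.na(errs)), 0.05)
})

test_that("the expanding-window R2 rule matches its brute-force oracle", {
  r <- simulate_stress_ramp(
    nonlinear_truth(K0 = 50, sigma0 = 2, m = 1.5, sigmaR = 500),
    noise_sd_rel = 0.03, seed = 21)
  o <- detect_onset(r, method = "r2", r2_threshold = 0.8)
  r2s <- oracle_prefix_r2(r$sigma, r$gamma)
  first_fail <- which(r2s < 0.8)[1] + 2L  # windows start at 3 points
  expect_false(o$no_onset)
  expect_equal(o$onset_index, first_fail - 1L)
  expect_equal(o$sigma0, r$sigma[first_fail - 1L])
  # Hookean input never fails the R2 rule
  hook <- stress_ramp(default_grid[1:50], default_grid[1:50] / 10)
  expect_true(detect_onset(hook, method = "r2")$no_onset)
})

test_that("rupture detection finds the sudden modulus drop", {
  sR <- on_grid(500)
  tr <- nonlinear_truth(K0 = 50, sigma0 = 2, m = 1.5, sigmaR = sR)
  kc <- differential_modulus(simulate_stress_ramp(tr))
  rup <- detect_rupture(kc)
  expect_false(rup$no_rupture)
  expect_lte(grid_step(rup$sigmaR, sR), 1)
  # monotone nondecreasing K': no rupture
  hook <- differential_modulus(
    stress_ramp(default_grid[1:60], default_grid[1:60] / 80))
  expect_true(detect_rupture(hook)$no_rupture)
})

test_that("rupture false-positive rate is controlled under 5% noise", {
  fp <- vapply(1:50, function(s) {
    tr <- nonlinear_truth(K0 = 50, sigma0 = 2e4, sigmaR = 5e4)  # Hookean
    r <- simulate_stress_ramp(tr, noise_sd_rel = 0.05, seed = 400 + s)
    !detect_rupture(differential_modulus(r))$no_rupture
  }, logical(1))
  expect_lt(mean(fp), 0.05 + 2 * sqrt(0.05 * 0.95 / 50))
})

test_that("extract_features recovers the generator parameter set", {
  sR <- on_grid(500)
  tr <- nonlinear_truth(K0 = 50, sigma0 = 2, m = 1.5, sigmaR = sR)
  f <- extract_features(simulate_stress_ramp(tr))
  expect_lte(grid_step(f$sigma0, 2), 1)
  expect_lte(grid_step(f$sigmaR, sR), 1)
  expect_equal(f$K0, 50, tolerance = 1e-6)
  expect_lt(abs(f$Kmax / (50 * (sR / 2)^1.5) - 1), 0.05)
  expect_equal(f$sigma_max, f$sigmaR)  # modulus peaks at rupture
  # Hookean curve: K0 = Kmax, onset and rupture flagged
  hook <- stress_ramp(default_grid[1:80], default_grid[1:80] / 100)
  fh <- extract_features(hook)
  expect_true(all(c("no_onset", "no_rupture") %in% fh$flags))
  expect_equal(fh$Kmax, fh$K0, tolerance = 1e-6)
})

test_that("feature orderings hold across a randomized simulation sweep", {
  set.seed(77)
  for (i in 1:150) {
    K0 <- exp(runif(1, log(10), log(300)))
    s0 <- exp(runif(1, log(0.3), log(20)))
    sR <- s0 * 10^runif(1, 1.5, 2.5)
    r <- simulate_stress_ramp(
      nonlinear_truth(K0 = K0, sigma0 = s0, m = runif(1, 1, 2),
                      sigmaR = min(sR, 8000)),
      noise_sd_rel = 0.02, seed = 5000 + i)
    f <- extract_features(r)
    if (length(f$flags) == 0) {
      expect_true(f$sigma0 <= f$sigma_max + 1e-9)
      expect_true(f$sigma_max <= f$sigmaR + 1e-9)
      expect_true(f$gamma0 <= f$gamma_max + 1e-9)
      expect_true(f$gamma_max <= f$gammaR + 1e-9)
      expect_true(f$K0 <= f$Kmax * (1 + 1e-9))
    }
  }
})

test_that("features are scale-equivariant in stress", {
  tr <- nonlinear_truth(K0 = 50, sigma0 = 2, m = 1.5, sigmaR = on_grid(500))
  r <- simulate_stress_ramp(tr)
  f1 <- extract_features(r)
  c_scale <- 7.3
  r2 <- stress_ramp(r$sigma * c_scale, r$gamma)
  f2 <- extract_features(r2)
  expect_equal(f2$sigma0, c_scale * f1$sigma0, tolerance = 1e-9)
  expect_equal(f2$sigmaR, c_scale * f1$sigmaR, tolerance = 1e-9)
  expect_equal(f2$K0, c_scale * f1$K0, tolerance = 1e-9)
  expect_equal(f2$Kmax, c_scale * f1$Kmax, tolerance = 1e-9)
  expect_equal(f2$gamma0, f1$gamma0, tolerance = 1e-9)
})

test_that("normalized curves collapse onto a master curve", {
  tr <- nonlinear_truth(K0 = 50, sigma0 = 2, m = 1.5, sigmaR = on_grid(500))
  r <- simulate_stress_ramp(tr)
  kc <- differential_modulus(r)
  f <- extract_features(r)
  nc <- normalize_curve(kc, f)
  # passes near (1, 1) at the onset
  at_onset <- which.min(abs(nc$sigma_rel - 1))
  expect_lt(abs(nc$Kp_rel[at_onset] - 1), 0.1)
  # identity when K0 = 1 and sigma0 = 1
  fid <- f; fid$K0 <- 1; fid$sigma0 <- 1
  nid <- normalize_curve(kc, fid)
  expect_equal(nid$Kp_rel, kc$Kp)
  expect_equal(nid$sigma_rel, kc$sigma)
  # two noiseless curves differing only in (K0, sigma0) collapse together;
  # shifting sigma0 by half a decade keeps the sampled sigma/sigma0 values
  # aligned with the log grid, so the collapse can be compared pointwise
  shift <- 10^(10 / 20)
  tr2 <- nonlinear_truth(K0 = 180, sigma0 = 2 * shift, m = 1.5,
                         sigmaR = on_grid(500) * shift)
  r2 <- simulate_stress_ramp(tr2)
  f2 <- extract_features(r2)
  n2 <- normalize_curve(differential_modulus(r2), f2)
  key1 <- round(20 * log10(nc$sigma_rel))
  key2 <- round(20 * log10(n2$sigma_rel))
  shared <- intersect(key1[nc$sigma_rel >= 0.1 & nc$sigma_rel <= 50],
                      key2)
  i1 <- match(shared, key1); i2 <- match(shared, key2)
  expect_gt(length(shared), 30)
  expect_lt(max(abs(log(nc$Kp_rel[i1]) - log(n2$Kp_rel[i2]))), 1e-6)
  # missing K0/sigma0 directs the caller to flags
  fh <- extract_features(stress_ramp(default_grid[1:60],
                                     default_grid[1:60] / 100))
  expect_error(normalize_curve(kc, fh), "flags")
})
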