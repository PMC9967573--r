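test_that("composition is linear and zero scenarios give zero spectra", {
  basis <- cached_basis("3T")
  scn0 <- scenario("3T")
  scn0$concentrations[] <- 0
  sp0 <- compose_spectrum(basis, scn0)
  expect_true(all(Mod(sp0$values) == 0))

  scn <- scenario("3T")
  sp1 <- compose_spectrum(basis, scn)
  scn2 <- scn
  scn2$concentrations <- 2 * scn$concentrations
  sp2 <- compose_spectrum(basis, scn2)
  expect_equal(sp2$values, 2 * sp1$values, tolerance = 1e-9)
})

test_that("PCr reaches its target linewidth in the processed spectrum", {
  # measurement function validated on an exact Lorentzian first
  g <- acq_grid("3T")
  ppm <- seq(-40, 40, length.out = 4096)
  exact <- new_spectrum_for_test(ppm, lorentzian_ppm(ppm, 0, 6.3, g$larmor_mhz), g)
  expect_equal(measure_peak_metrics(exact)$fwhm_hz, 6.3, tolerance = 0.05)

  # full chain: decay-rate width is recovered up to truncation ripple (~3%)
  for (field in c("3T", "7T")) {
    scn <- pcr_only_scenario(field)
    sp <- compose_spectrum(cached_basis(field), scn)
    target <- scn$linewidths[["PCr"]]
    expect_equal(measure_peak_metrics(sp)$fwhm_hz, target,
                 tolerance = 0.035 * target)
  }
})

test_that("noise calibration hits the target PCr SNR at both fields", {
  for (field in c("3T", "7T")) {
    basis <- cached_basis(field)
    scn <- scenario(field)
    sp <- compose_spectrum(basis, scn)
    sigma <- calibrate_noise_for_snr(sp, scn$target_snr)
    snrs <- vapply(1:60, function(i) {
      measure_peak_metrics(realize_spectrum(basis, scn, i, sigma = sigma))$snr
    }, 0)
    expect_equal(mean(snrs), scn$target_snr,
                 tolerance = 0.05 * scn$target_snr)
  }
})

test_that("calibrated sigma is proportional to the PCr amplitude", {
  basis <- cached_basis("3T")
  scn <- pcr_only_scenario("3T")
  sp1 <- compose_spectrum(basis, scn)
  scn$concentrations["PCr"] <- 2 * scn$concentrations[["PCr"]]
  sp2 <- compose_spectrum(basis, scn)
  s1 <- calibrate_noise_for_snr(sp1, 82)
  s2 <- calibrate_noise_for_snr(sp2, 82)
  expect_equal(s2 / s1, 2, tolerance = 1e-9)
  zero <- scn; zero$concentrations[] <- 0
  expect_error(calibrate_noise_for_snr(compose_spectrum(basis, zero), 82),
               "no positive peak")
})

test_that("noise is seeded, additive and has the predicted frequency-domain SD", {
  g <- acq_grid("3T")
  fid <- simulate_fid(spin_system("x", 0), g, 6)$fid
  expect_identical(add_noise(fid, 0, 1), fid)
  expect_identical(add_noise(fid, 0.3, 42), add_noise(fid, 0.3, 42))
  expect_false(identical(add_noise(fid, 0.3, 1), add_noise(fid, 0.3, 2)))

  # under no apodization/zeroing, freq-domain SD = sigma * sqrt(n_points)
  proc <- proc_params(k_zero = 0, lb_hz = 0, zf_factor = 1)
  sds <- vapply(1:40, function(i) {
    sp <- process_fid(add_noise(complex(g$n_points), 1, i), g, proc)
    stats::sd(Re(sp$values))
  }, 0)
  expect_equal(mean(sds), sqrt(g$n_points), tolerance = 0.02 * sqrt(g$n_points))
})

test_that("peak metrics flag noiseless and low-SNR spectra", {
  basis <- cached_basis("3T")
  scn <- pcr_only_scenario("3T")
  sp <- compose_spectrum(basis, scn)
  m <- measure_peak_metrics(sp)
  expect_true(is.infinite(m$snr))
  expect_false(m$low_snr_flag)

  # bury the peak in noise -> flag
  scn$concentrations["PCr"] <- 1e-4
  spn <- realize_spectrum(basis, scn, 5, sigma = 1)
  mn <- measure_peak_metrics(spn)
  expect_true(mn$low_snr_flag)
})

test_that("FWHM estimates are stable across noise draws", {
  basis <- cached_basis("3T")
  scn <- scenario("3T")
  sigma <- p31corr:::.scenario_sigma(scn, basis, proc_params())
  fw <- vapply(1:12, function(i) {
    measure_peak_metrics(realize_spectrum(basis, scn, i, sigma = sigma))$fwhm_hz
  }, 0)
  expect_lt(stats::sd(fw) / mean(fw), 0.10)
})

test_that("the default baseline is downfield-dominant and MP-scaled", {
  basis3 <- cached_basis("3T")
  basis7 <- cached_basis("7T")
  s3 <- with_default_baseline(scenario("3T"), basis3)
  s7 <- with_default_baseline(scenario("7T"), basis7)
  ppm <- seq(-20, 10, by = 0.05)
  b3 <- eval_baseline(s3$baseline, ppm)
  b7 <- eval_baseline(s7$baseline, ppm)
  # hump lives downfield (max in 2..8 ppm), and is larger at 3 T
  expect_true(ppm[which.max(b3)] > 2 && ppm[which.max(b3)] < 8)
  expect_gt(max(b3), 3 * max(b7))
  # zero outside the fit window
  expect_true(all(eval_baseline(s3$baseline, c(-25, 11, 40)) == 0))
})

test_that("subject scenarios are reproducibly jittered around the defaults", {
  a <- subject_scenarios("3T", n = 5, base_seed = 7)
  b <- subject_scenarios("3T", n = 5, base_seed = 7)
  expect_equal(a, b)
  c2 <- subject_scenarios("3T", n = 5, base_seed = 8)
  expect_false(identical(a, c2))
  # ATP reference and NAD tie preserved under jitter
  for (scn in a) {
    expect_equal(scn$concentrations[["ATP"]], 9)
    expect_equal(scn$linewidths[["NAD+"]], scn$linewidths[["ATP"]] - 1.5)
  }
  pcr_lw <- vapply(a, function(s) s$linewidths[["PCr"]], 0)
  expect_gt(stats::sd(pcr_lw), 0)
})
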