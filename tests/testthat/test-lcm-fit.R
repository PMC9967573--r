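test_that("noiseless spectra are recovered to high relative accuracy", {
  for (field in c("3T", "7T")) {
    basis <- cached_basis(field)
    scn <- scenario(field)
    sp <- compose_spectrum(basis, scn)
    fit <- fit_lcm(sp, basis, fit_config(baseline_degree = NA))
    expect_true(fit$converged)
    expect_equal(unname(fit$amplitudes[names(scn$concentrations)]),
                 unname(scn$concentrations), tolerance = 1e-3)
  }
})

test_that("the NAD linewidth constraint holds exactly in every fit", {
  basis <- cached_basis("3T")
  scn <- scenario("3T")
  sigma <- p31corr:::.scenario_sigma(scn, basis, proc_params())
  for (seed in 1:3) {
    sp <- realize_spectrum(basis, scn, seed, sigma = sigma)
    fit <- fit_lcm(sp, basis, fit_config(baseline_degree = NA))
    expect_identical(fit$linewidths[["NAD+"]], fit$linewidths[["ATP"]] - 1.5)
    expect_identical(fit$linewidths[["NADH"]], fit$linewidths[["ATP"]] - 1.5)
  }
  # also under nonlinear refinement of the linewidths
  sp <- realize_spectrum(basis, scn, 9, sigma = sigma)
  fit <- fit_lcm(sp, basis,
                 fit_config(baseline_degree = NA, optimize_linewidths = TRUE,
                            max_iter = 5))
  expect_equal(fit$linewidths[["NAD+"]], fit$linewidths[["ATP"]] - 1.5)
})

test_that("a spectrum composed with a polynomial baseline is recovered exactly", {
  basis <- cached_basis("3T")
  scn <- scenario("3T")
  scn$baseline <- baseline_model(c(20, -5, 12, 3, -8), window = c(-20, 10))
  sp <- compose_spectrum(basis, scn)
  fit <- fit_lcm(sp, basis, fit_config(baseline_degree = 6))
  expect_equal(unname(fit$amplitudes[names(scn$concentrations)]),
               unname(scn$concentrations), tolerance = 0.01)
})

test_that("adding baseline degrees never increases the residual", {
  basis <- cached_basis("3T")
  scn <- with_default_baseline(scenario("3T"), basis)
  sp <- realize_spectrum(basis, scn, 3, sigma = 0.05)
  rss <- vapply(2:8, function(d)
    fit_lcm(sp, basis, fit_config(baseline_degree = d))$residual_norm, 0)
  expect_true(all(diff(rss) <= 1e-8))
})

test_that("nonlinear refinement recovers a perturbed linewidth", {
  basis <- cached_basis("3T")
  scn <- pcr_only_scenario("3T")
  scn$linewidths["PCr"] <- 9.5
  sp <- compose_spectrum(basis, scn)
  # start 3 Hz off; only PCr amplitude is nonzero so its width is identified
  start <- list(linewidths = c(PCr = 6.5))
  fit <- fit_lcm(sp, basis,
                 fit_config(baseline_degree = NA, optimize_linewidths = TRUE),
                 start = start)
  expect_equal(fit$linewidths[["PCr"]], 9.5, tolerance = 0.2)
  expect_equal(fit$amplitudes[["PCr"]], scn$concentrations[["PCr"]],
               tolerance = 0.01)
})

test_that("all-zero spectra fit to zero amplitudes with a flag", {
  basis <- cached_basis("3T")
  scn <- scenario("3T")
  scn$concentrations[] <- 0
  sp <- compose_spectrum(basis, scn)
  fit <- fit_lcm(sp, basis, fit_config(baseline_degree = NA))
  expect_true(all(fit$amplitudes == 0))
  expect_false(fit$converged)
  expect_true(any(grepl("all-zero", fit$flags)))
})

test_that("concentration referencing scales total ATP to 9 mM", {
  amps <- c(PCr = 2, ATP = 4, "NAD+" = 0.1)
  conc <- quantify_concentrations(amps)
  expect_equal(conc[["ATP"]], 9)
  expect_equal(conc[["PCr"]], 4.5)
  # scale invariance
  expect_equal(quantify_concentrations(5 * amps), conc)
  expect_error(quantify_concentrations(c(PCr = 1, ATP = 0)), "ATP amplitude")
})

test_that("the analytic oracle handles orthogonal and collinear designs", {
  g <- acq_grid("3T")
  sys <- list(spin_system("A", -15), spin_system("B", 8))
  names(sys) <- c("A", "B")
  basis <- structure(lapply(sys, simulate_fid, grid = g, seed_linewidth_hz = 0),
                     class = "basis_set", field = "3T", grid = g)
  cfg <- fit_config(baseline_degree = NA)
  lw <- c(A = 8, B = 8)
  orc <- analytic_correlation_oracle(basis, cfg, linewidths = lw)
  expect_lt(abs(orc$r["A", "B"]), 0.01)  # far-apart lines: ~orthogonal
  dup <- structure(list(A = basis$A, B = basis$A), class = "basis_set",
                   field = "3T", grid = g)
  names(dup) <- c("A", "B")
  expect_error(analytic_correlation_oracle(dup, cfg, linewidths = lw),
               "rank deficient")
})

test_that("the oracle is invariant to noise level and amplitudes by construction", {
  basis <- cached_basis("3T")
  cfg <- fit_config(baseline_degree = NA)
  o1 <- analytic_correlation_oracle(basis, cfg)
  expect_equal(diag(o1$r), rep(1, 11), ignore_attr = TRUE)
  expect_true(all(abs(o1$r) <= 1 + 1e-12))
  expect_true(isSymmetric(o1$r, tol = 1e-10))
  ev <- eigen(o1$r, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})
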