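# Shared fixtures: basis sets are deterministic and moderately costly, so
# build each field's set once per test session.
.basis_cache <- new.env(parent = emptyenv())

cached_basis <- function(field) {
  if (is.null(.basis_cache[[field]]))
    .basis_cache[[field]] <- build_basis_set(field)
  .basis_cache[[field]]
}

# A PCr-only scenario (everything else zeroed) for lineshape checks.
pcr_only_scenario <- function(field) {
  scn <- scenario(field)
  scn$concentrations[setdiff(names(scn$concentrations), "PCr")] <- 0
  scn
}

# Analytic absorption Lorentzian on a ppm axis (height-normalized).
lorentzian_ppm <- function(ppm, center_ppm, fwhm_hz, larmor_mhz, height = 1) {
  hw <- fwhm_hz / larmor_mhz / 2  # half width in ppm
  height * hw^2 / ((ppm - center_ppm)^2 + hw^2)
}

# Wrap a bare real curve as a spectrum object (for validating the
# measurement functions against exact lineshapes).
new_spectrum_for_test <- function(ppm, re, grid) {
  p31corr:::new_p31_spectrum(complex(real = re, imaginary = numeric(length(re))),
                             ppm, grid, "synthetic test curve")
}

# Merge transitions closer than `tol` Hz (second-order splittings that the
# lineshape cannot resolve) into single lines.
cluster_lines <- function(freq, weight, tol = 0.5) {
  o <- order(freq)
  freq <- freq[o]; weight <- weight[o]
  grp <- cumsum(c(TRUE, diff(freq) > tol))
  out <- data.frame(
    freq = as.numeric(tapply(freq * weight, grp, sum) / tapply(weight, grp, sum)),
    weight = as.numeric(tapply(weight, grp, sum)))
  out[out$weight > 1e-6, ]
}

# First-order (weak-coupling) multiplet line positions/weights for one
# nucleus coupled to the given partners: used as the analytic oracle for
# the density-matrix simulation in its weak-coupling regime.
weak_coupling_lines <- function(center_hz, j_partners_hz) {
  lines <- data.frame(freq = center_hz, weight = 1)
  for (J in j_partners_hz) {
    lines <- do.call(rbind, lapply(c(-J / 2, J / 2), function(d)
      transform(lines, freq = freq + d, weight = weight / 2)))
  }
  aggregate(weight ~ freq, lines, sum)
}
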