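# Density-matrix simulation of pulse-acquire 31P spectra.
#
# The Hamiltonian in the rotating frame at the reference (PCr, 0 ppm) is
#   H = sum_i 2*pi*nu_i Iz_i + sum_{i<j} 2*pi*J_ij (Ix_i Ix_j + Iy_i Iy_j + Iz_i Iz_j)
# with nu_i = shift_ppm_i * larmor_mhz in Hz. Strong coupling is handled
# exactly by full diagonalization (systems here have <= 3 spins, so the
# largest matrix is 8 x 8). After an ideal 90-degree pulse rho0 = Fx; the
# detected signal is Tr[(Fx + i Fy) rho(t)], which places a nucleus with
# positive ppm shift at positive frequency under R's fft() convention.

# Single-spin operators embedded at position i of an n-spin product space.
.spin_ops <- function(n) {
  sx <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  sy <- matrix(c(0, 0.5i, -0.5i, 0), 2, 2)
  sz <- diag(c(0.5, -0.5))
  id <- diag(2)
  embed <- function(op, i) {
    m <- matrix(1, 1, 1)
    for (k in seq_len(n)) m <- kronecker(m, if (k == i) op else id)
    m
  }
  list(Ix = lapply(seq_len(n), function(i) embed(sx, i)),
       Iy = lapply(seq_len(n), function(i) embed(sy, i)),
       Iz = lapply(seq_len(n), function(i) embed(sz, i)))
}

# Exact transition table (frequencies in Hz, complex amplitudes) of a
# pulse-acquire experiment on a coupled spin-1/2 system. Amplitudes are
# scaled so that sum(amplitudes) = number of spins (fid[0] = n).
.transition_table <- function(shifts_hz, j_hz) {
  n <- length(shifts_hz)
  ops <- .spin_ops(n)
  H <- matrix(0, 2^n, 2^n)
  for (i in seq_len(n)) H <- H + 2 * pi * shifts_hz[i] * ops$Iz[[i]]
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (j_hz[i, j] != 0) {
        H <- H + 2 * pi * j_hz[i, j] *
          (ops$Ix[[i]] %*% ops$Ix[[j]] + Re(ops$Iy[[i]] %*% ops$Iy[[j]]) +
             ops$Iz[[i]] %*% ops$Iz[[j]])
      }
    }
  }
  Fx <- Reduce(`+`, ops$Ix)
  Fy <- Reduce(`+`, ops$Iy)
  e <- eigen(H, symmetric = TRUE)
  V <- e$vectors
  lam <- e$values
  rhoE <- t(V) %*% Fx %*% V                 # rho0 = Fx (real symmetric)
  DE <- Conj(t(V)) %*% (Fx + 1i * Fy) %*% V  # detection F+
  # s(t) = sum_ab DE[a,b] rhoE[b,a] exp(-i (lam_b - lam_a) t)
  A <- DE * t(rhoE)
  W <- outer(lam, lam, function(a, b) -(b - a) / (2 * pi))
  keep <- Mod(A) > 1e-9
  amp <- A[keep] * 4 / 2^n
  list(freq_hz = W[keep], amplitude = amp)
}

#' Simulate the basis FID of one spin system
#'
#' Evolves the density operator after an ideal 90-degree excitation under the
#' exact Zeeman + scalar-coupling Hamiltonian in the rotating frame at the
#' reference ppm, samples the transverse magnetization on the acquisition
#' raster, and applies an intrinsic Lorentzian decay `exp(-pi * lw * t)`.
#' Broad components are rendered directly as a decaying single resonance at
#' their intrinsic width; effective 1H multiplets on single-31P systems
#' modulate the FID by `cos(pi J t)^(multiplicity-1)`.
#'
#' The FID is normalized per phosphorus: `fid[1]` equals the number of 31P
#' nuclei, so the spectrum integral is proportional to `n_phosphorus`.
#'
#' @param spec A [spin_system()].
#' @param grid An [acq_grid()].
#' @param seed_linewidth_hz Intrinsic Lorentzian FWHM (Hz) applied to the
#'   ideal FID (for broad components the intrinsic `broad_fwhm_hz` is added).
#' @return Object of class `basis_signal`: list with `name`, `fid` (complex,
#'   `n_points`), `n_phosphorus`, `grid`, `intrinsic_fwhm_hz`,
#'   `normalization`.
#' @export
#' @examples
#' g <- acq_grid("3T")
#' pcr <- simulate_fid(spin_system("PCr", 0), g)
#' Mod(pcr$fid[1])  # = 1 phosphorus
simulate_fid <- function(spec, grid, seed_linewidth_hz = 0) {
  if (!inherits(spec, "spin_system")) stop("`spec` must be a spin_system")
  .assert_grid(grid)
  if (seed_linewidth_hz < 0) stop("seed_linewidth_hz must be >= 0")
  t <- grid_times(grid)
  if (spec$broad) {
    nu <- (spec$shifts_ppm - grid$reference_ppm) * grid$larmor_mhz
    lw <- spec$broad_fwhm_hz + seed_linewidth_hz
    fid <- exp((2i * pi * nu - pi * lw) * t)
  } else {
    shifts_hz <- (spec$shifts_ppm - grid$reference_ppm) * grid$larmor_mhz
    tab <- .transition_table(shifts_hz, spec$j_hz)
    ph <- exp(outer(t, tab$freq_hz, function(tt, f) 2i * pi * f * tt))
    fid <- as.vector(ph %*% tab$amplitude)
    if (!is.null(spec$proton_multiplet)) {
      m <- spec$proton_multiplet[1]
      Jh <- spec$proton_multiplet[2]
      if (m > 1) fid <- fid * cos(pi * Jh * t)^(m - 1)
    }
    if (seed_linewidth_hz > 0) fid <- fid * exp(-pi * seed_linewidth_hz * t)
  }
  structure(
    list(name = spec$name, fid = fid, n_phosphorus = spec$n_phosphorus,
         grid = grid,
         intrinsic_fwhm_hz = seed_linewidth_hz +
           if (spec$broad) spec$broad_fwhm_hz else 0,
         normalization = "per-phosphorus"),
    class = "basis_signal")
}

#' @export
print.basis_signal <- function(x, ...) {
  cat(sprintf("<basis_signal> %s: %d x 31P, %d pts, intrinsic FWHM %g Hz\n",
              x$name, x$n_phosphorus, length(x$fid), x$intrinsic_fwhm_hz))
  invisible(x)
}

#' Build the field-specific basis set
#'
#' Simulates one basis signal per metabolite of the spectral model on the
#' field-appropriate Larmor frequency. The 3 T model holds 11 signals (UDPG
#' is excluded for lack of sensitivity); the 7 T model holds all 12.
#'
#' @param field `"3T"` or `"7T"`.
#' @param systems Named list of [spin_system()]s; defaults to
#'   [default_spin_systems()].
#' @param grid Acquisition grid; defaults to `acq_grid(field)`.
#' @param seed_linewidth_hz Intrinsic Lorentzian FWHM given to every basis
#'   FID (default 0: broadening is applied downstream).
#' @return Named list of `basis_signal` objects (class `basis_set`), in
#'   canonical metabolite order.
#' @export
build_basis_set <- function(field = c("3T", "7T"),
                            systems = default_spin_systems(field),
                            grid = acq_grid(field),
                            seed_linewidth_hz = 0) {
  field <- match.arg(field)
  required <- setdiff(.metabolite_order, if (field == "3T") "UDPG" else character())
  missing <- setdiff(required, names(systems))
  if (length(missing))
    stop("missing spin-system specs for: ", paste(missing, collapse = ", "))
  use <- required[required %in% names(systems)]
  basis <- lapply(systems[use], simulate_fid, grid = grid,
                  seed_linewidth_hz = seed_linewidth_hz)
  structure(basis, class = "basis_set", field = field, grid = grid)
}

#' Export a basis signal as CSV plus JSON sidecar
#'
#' Writes `(index, time_s, real, imag)` rows and a `<path>.json` sidecar
#' carrying the grid metadata, so a basis can be exchanged without vendor
#' formats.
#'
#' @param basis A `basis_signal`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_basis_signal <- function(basis, path) {
  df <- data.frame(index = seq_along(basis$fid) - 1L,
                   time_s = grid_times(basis$grid),
                   real = Re(basis$fid), imag = Im(basis$fid))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- basis$grid[c("field", "b0", "larmor_mhz", "sweep_hz", "n_points",
                       "reference_ppm")]
  meta$name <- basis$name
  meta$n_phosphorus <- basis$n_phosphorus
  meta$intrinsic_fwhm_hz <- basis$intrinsic_fwhm_hz
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a basis signal written by [write_basis_signal()]
#' @param path CSV path (expects `<path>.json` sidecar).
#' @return A `basis_signal`.
#' @export
read_basis_signal <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- acq_grid(meta$field, sweep_hz = meta$sweep_hz,
                   n_points = meta$n_points, reference_ppm = meta$reference_ppm)
  structure(
    list(name = meta$name, fid = complex(real = df$real, imaginary = df$imag),
         n_phosphorus = meta$n_phosphorus, grid = grid,
         intrinsic_fwhm_hz = meta$intrinsic_fwhm_hz,
         normalization = "per-phosphorus"),
    class = "basis_signal")
}
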