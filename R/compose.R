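# Composition of synthetic spectra from basis signals plus ground truth,
# noise calibration against a target PCr SNR, and peak metrics.

# Extra Lorentzian decay needed to take a basis signal to its target total
# FWHM under the processing chain: target = intrinsic + proc lb + extra.
.extra_decay_hz <- function(target_fwhm, intrinsic_fwhm, proc_lb) {
  max(target_fwhm - intrinsic_fwhm - proc_lb, 0)
}

# Noiseless composite *FID* (metabolites only; baseline lives in the
# frequency domain and is added after processing).
.compose_fid <- function(basis, scn, proc) {
  grid <- attr(basis, "grid")
  t <- grid_times(grid)
  fid <- complex(grid$n_points)
  for (nm in names(scn$concentrations)) {
    b <- basis[[nm]]
    if (is.null(b)) stop("basis is missing metabolite: ", nm)
    extra <- .extra_decay_hz(scn$linewidths[[nm]], b$intrinsic_fwhm_hz,
                             proc$lb_hz)
    fid <- fid + scn$concentrations[[nm]] * b$fid * exp(-pi * extra * t)
  }
  if (scn$lb_factor > 0) fid <- fid * exp(-pi * scn$lb_factor * t)
  fid
}

#' Compose the noiseless spectrum of a scenario
#'
#' Sums the amplitude-weighted, broadened basis FIDs, applies the global
#' line-broadening factor, runs the processing chain, and adds the baseline
#' curve (if any) to the real part in the frequency domain. The scenario
#' ground truth is attached to the result.
#'
#' @param basis A [build_basis_set()] matching the scenario field.
#' @param scn A [scenario()].
#' @param proc [proc_params()].
#' @return A `p31_spectrum` with attribute `truth` (the scenario).
#' @export
compose_spectrum <- function(basis, scn, proc = proc_params()) {
  if (!inherits(scn, "scenario")) stop("`scn` must be a scenario")
  if (attr(basis, "field") != scn$field)
    stop("basis field ", attr(basis, "field"),
         " does not match scenario field ", scn$field)
  grid <- attr(basis, "grid")
  sp <- process_fid(.compose_fid(basis, scn, proc), grid, proc)
  if (!is.null(scn$baseline)) {
    sp$values <- sp$values + eval_baseline(scn$baseline, sp$ppm)
    sp$processing <- c(sp$processing, "baseline added (frequency domain)")
  }
  attr(sp, "truth") <- scn
  sp
}

#' Add complex Gaussian noise to an FID
#'
#' i.i.d. complex noise (independent real/imaginary channels, SD `sigma`
#' each) added in the time domain, before any processing. Identical seeds
#' give bit-identical output.
#'
#' @param fid Complex vector.
#' @param sigma Per-channel noise SD (>= 0).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Noisy copy of `fid`.
#' @export
add_noise <- function(fid, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(fid)
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  n <- length(fid)
  fid + complex(real = stats::rnorm(n, 0, sigma),
                imaginary = stats::rnorm(n, 0, sigma))
}

#' Calibrate the time-domain noise SD for a target PCr SNR
#'
#' Under the processing chain, frequency-domain noise on the real part has
#' SD `sigma * g` with the exact gain
#' `g = sqrt(sum_t w_t^2)`, where `w_t` are the apodization weights (zeroed
#' initial points included). The returned sigma therefore satisfies
#' `PCr peak height / frequency-domain noise SD = target_snr` in
#' expectation, deterministically.
#'
#' @param noiseless A noiseless `p31_spectrum` (from [compose_spectrum()]),
#'   composed without baseline or with one (the PCr peak is read from it).
#' @param target_snr Desired PCr peak SNR (> 0).
#' @param proc The [proc_params()] used to produce the spectrum.
#' @param peak_ppm Location of the reference peak (default 0 = PCr).
#' @return Time-domain per-channel noise SD.
#' @export
calibrate_noise_for_snr <- function(noiseless, target_snr,
                                    proc = proc_params(), peak_ppm = 0) {
  stopifnot(target_snr > 0)
  sel <- abs(noiseless$ppm - peak_ppm) <= 0.5
  height <- max(Re(noiseless$values[sel]))
  if (height <= 0) stop("no positive peak found at the reference location")
  height / (target_snr * .noise_gain(noiseless$grid, proc))
}

# Resolve a scenario's noise sigma (explicit or SNR-calibrated).
.scenario_sigma <- function(scn, basis, proc) {
  if (!is.null(scn$noise_sigma)) return(scn$noise_sigma)
  no_bl <- scn
  no_bl$baseline <- NULL
  calibrate_noise_for_snr(compose_spectrum(basis, no_bl, proc),
                          scn$target_snr, proc)
}

#' Generate one noisy realization of a scenario
#'
#' Adds seeded time-domain noise to the composite FID, processes it, and
#' adds the baseline curve. This is the unit of work of the Monte Carlo
#' drivers.
#'
#' @param basis Matching basis set.
#' @param scn A [scenario()].
#' @param seed Integer seed for this realization.
#' @param proc [proc_params()].
#' @param sigma Optional pre-resolved noise SD (avoids re-calibration).
#' @return A `p31_spectrum` with attribute `truth`.
#' @export
realize_spectrum <- function(basis, scn, seed, proc = proc_params(),
                             sigma = NULL) {
  if (is.null(sigma)) sigma <- .scenario_sigma(scn, basis, proc)
  grid <- attr(basis, "grid")
  fid <- add_noise(.compose_fid(basis, scn, proc), sigma, seed)
  sp <- process_fid(fid, grid, proc)
  if (!is.null(scn$baseline))
    sp$values <- sp$values + eval_baseline(scn$baseline, sp$ppm)
  attr(sp, "truth") <- scn
  sp
}

#' Measure FWHM and SNR of a peak
#'
#' FWHM by linear interpolation of the half-maximum crossings of the real
#' part around the peak; SNR as peak height over the noise SD of the real
#' part in a signal-free noise window. The noise window is detrended with a
#' quadratic before taking the SD, so the smooth pedestal left by
#' initial-point zeroing and broad-signal tails does not inflate the noise
#' estimate.
#'
#' @param spectrum A `p31_spectrum`.
#' @param peak_ppm Peak location (searched within +-0.5 ppm).
#' @param noise_window_ppm Two-element ppm range free of signal (default
#'   12..18 ppm, upfield of all modeled resonances at both fields).
#' @return List with `fwhm_hz`, `snr`, `peak_ppm`, `height`, `noise_sd`,
#'   `low_snr_flag` (`TRUE` if the peak is below 3x the noise SD; `snr` is
#'   `Inf` for a noiseless spectrum).
#' @export
measure_peak_metrics <- function(spectrum, peak_ppm = 0,
                                 noise_window_ppm = c(12, 18)) {
  re <- Re(spectrum$values)
  ppm <- spectrum$ppm
  sel <- which(abs(ppm - peak_ppm) <= 0.5)
  if (!length(sel)) stop("peak window outside the spectrum")
  i <- sel[which.max(re[sel])]
  height <- re[i]
  half <- height / 2
  # walk outward to the half-height crossings and interpolate
  lo <- i
  while (lo > 1 && re[lo] > half) lo <- lo - 1
  hi <- i
  while (hi < length(re) && re[hi] > half) hi <- hi + 1
  if (lo == i || hi == i || re[lo] > half || re[hi] > half)
    stop("could not bracket half maximum for FWHM measurement")
  interp <- function(a, b) ppm[a] + (half - re[a]) / (re[b] - re[a]) * (ppm[b] - ppm[a])
  fwhm_ppm <- interp(hi - 1, hi) - interp(lo + 1, lo)
  fwhm_hz <- abs(fwhm_ppm) * spectrum$grid$larmor_mhz
  nw <- ppm >= noise_window_ppm[1] & ppm <= noise_window_ppm[2]
  if (sum(nw) < 10) stop("noise window outside the spectrum (or too narrow)")
  noise_sd <- stats::sd(stats::resid(stats::lm(re[nw] ~ stats::poly(ppm[nw], 2))))
  # beyond ~5e3 the "noise" estimate is dominated by deterministic lineshape
  # residue in the window, so the SNR is unmeasurable and reported infinite
  snr <- if (noise_sd <= 0 || height / noise_sd > 5e3) Inf else height / noise_sd
  list(fwhm_hz = fwhm_hz, snr = snr, peak_ppm = ppm[i], height = height,
       noise_sd = noise_sd, low_snr_flag = is.finite(snr) && snr < 3)
}
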