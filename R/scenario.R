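# Synthetic "participants": scenarios bundle the ground-truth amplitudes,
# linewidths, baseline, and noise level from which Monte Carlo spectra are
# generated.

#' Polynomial baseline model
#'
#' The background spectral baseline is a polynomial over the fit window,
#' evaluated on the normalized coordinate `x in [-1, 1]` spanning the window
#' (default -20..10 ppm). The curve is added to the real part of the
#' spectrum inside the window and is zero outside.
#'
#' @param coefficients Numeric coefficients `c0, c1, ...` of powers of `x`.
#' @param window ppm window the normalization maps onto `[-1, 1]`.
#' @return A `baseline_model`.
#' @export
baseline_model <- function(coefficients, window = c(-20, 10)) {
  stopifnot(length(coefficients) >= 1, all(is.finite(coefficients)),
            length(window) == 2, window[1] < window[2])
  structure(list(coefficients = as.numeric(coefficients),
                 degree = length(coefficients) - 1L,
                 window = as.numeric(window)),
            class = "baseline_model")
}

#' Evaluate a baseline model on a ppm axis
#' @param baseline A [baseline_model()].
#' @param ppm Numeric ppm axis.
#' @return Numeric curve, zero outside the window.
#' @export
eval_baseline <- function(baseline, ppm) {
  x <- (2 * ppm - sum(baseline$window)) / diff(baseline$window)
  inside <- x >= -1 & x <= 1
  y <- numeric(length(ppm))
  if (any(inside)) {
    xx <- x[inside]
    acc <- numeric(sum(inside))
    for (k in seq_along(baseline$coefficients))
      acc <- acc + baseline$coefficients[k] * xx^(k - 1)
    y[inside] <- acc
  }
  y
}

# Least-squares projection of a curve onto polynomials of given degree over
# the normalized window.
.project_polynomial <- function(f, degree, window = c(-20, 10), n_grid = 601) {
  ppm <- seq(window[1], window[2], length.out = n_grid)
  x <- (2 * ppm - sum(window)) / diff(window)
  X <- outer(x, 0:degree, `^`)
  beta <- qr.solve(X, f(ppm))
  baseline_model(beta, window)
}

#' Default downfield-dominant synthetic baseline
#'
#' A degree-6 polynomial obtained by projecting a smooth Gaussian hump
#' centered in the downfield region (5 ppm, FWHM 6 ppm) onto the normalized
#' fit window. Its peak height is set relative to the MP peak height of the
#' scenario it accompanies (equal to it by default), so the baseline is
#' prominent at 3 T and much weaker at 7 T, following the field dependence
#' of the macromolecule signal.
#'
#' @param peak_height Height of the hump (same units as the spectrum it will
#'   be added to).
#' @param center_ppm,fwhm_ppm Location and width of the hump.
#' @param degree Polynomial degree (default 6).
#' @param window Fit window in ppm.
#' @return A [baseline_model()].
#' @export
default_baseline <- function(peak_height, center_ppm = 5, fwhm_ppm = 6,
                             degree = 6, window = c(-20, 10)) {
  s <- fwhm_ppm / (2 * sqrt(2 * log(2)))
  bl <- .project_polynomial(
    function(p) peak_height * exp(-(p - center_ppm)^2 / (2 * s^2)),
    degree, window)
  bl
}

# Default total-FWHM table (Hz) per field; PCr widths are the in vivo values
# (6.3 Hz at 3 T, 9.3 Hz at 7 T). ATP is substantially broader and more so
# at 7 T (chemical-shift-anisotropy relaxation grows with field); NAD
# linewidths are tied to ATP - 1.5 Hz; esters and Pi pools sit between. MP
# carries only its intrinsic broad width.
.default_linewidths <- function(field) {
  if (field == "3T") {
    lw <- c("PCr" = 6.3, "ATP" = 14, "GPC" = 12, "GPE" = 12, "Pi_ex" = 12,
            "Pi_in" = 12, "PC" = 12, "PE" = 12, "MP" = 250)
  } else {
    lw <- c("PCr" = 9.3, "ATP" = 22, "UDPG" = 20.5, "GPC" = 15, "GPE" = 15,
            "Pi_ex" = 15, "Pi_in" = 15, "PC" = 15, "PE" = 15, "MP" = 450)
  }
  lw["NAD+"] <- lw["ATP"] - 1.5
  lw["NADH"] <- lw["ATP"] - 1.5
  lw
}

# Literature-style default concentrations (mM); total ATP 9 mM is the
# internal reference. MP "concentration" is an amplitude knob for the broad
# pool, chosen so the MP hump dominates at 3 T and is small at 7 T.
.default_concentrations <- function(field) {
  conc <- c("PCr" = 4.5, "ATP" = 9.0, "NAD+" = 0.35, "NADH" = 0.1,
            "GPC" = 1.0, "GPE" = 1.0, "Pi_ex" = 0.3, "Pi_in" = 1.0,
            "PC" = 0.6, "PE" = 1.8, "MP" = if (field == "3T") 45 else 10)
  if (field == "7T") conc["UDPG"] <- 0.1
  conc
}

.default_snr <- function(field) if (field == "3T") 82 else 171

#' Define a synthetic scenario (one "participant" condition)
#'
#' A scenario fixes everything needed to generate noisy spectra: the field,
#' per-metabolite ground-truth concentrations (mM), per-metabolite target
#' total Lorentzian FWHM in the processed spectrum (Hz; this includes the
#' 1-Hz processing apodization, so the in vivo PCr values 6.3/9.3 Hz can be
#' entered directly), a global extra line-broadening factor (shim
#' degradation), an optional polynomial baseline, and the noise level (either
#' an explicit time-domain sigma or a target PCr SNR to calibrate against).
#'
#' @param field `"3T"` or `"7T"`.
#' @param concentrations Named vector (mM); defaults to the literature-style
#'   table.
#' @param linewidths Named vector of total FWHM (Hz); defaults per field.
#' @param lb_factor Global additional Lorentzian broadening (Hz) applied to
#'   the composed data (not to the fit basis start values directly).
#' @param baseline A [baseline_model()], `"default"` for the downfield hump
#'   scaled to the MP peak height, or `NULL` for none.
#' @param target_snr PCr peak SNR the noise is calibrated to (default 82 at
#'   3 T, 171 at 7 T). Ignored if `noise_sigma` is given.
#' @param noise_sigma Explicit time-domain complex-noise SD per channel.
#' @param seed Base RNG seed label for this scenario.
#' @param subject_id Optional label for replicated-subject designs.
#' @return Object of class `scenario` (ground truth is carried along).
#' @export
scenario <- function(field = c("3T", "7T"),
                     concentrations = .default_concentrations(field),
                     linewidths = .default_linewidths(field),
                     lb_factor = 0,
                     baseline = NULL,
                     target_snr = .default_snr(field),
                     noise_sigma = NULL,
                     seed = 1L,
                     subject_id = NA_character_) {
  field <- match.arg(field)
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (any(linewidths <= 0)) stop("linewidths must be > 0")
  if (lb_factor < 0) stop("lb_factor must be >= 0")
  if (!is.null(noise_sigma) && noise_sigma < 0) stop("noise_sigma must be >= 0")
  expected <- setdiff(.metabolite_order, if (field == "3T") "UDPG" else character())
  missing <- setdiff(expected, names(concentrations))
  if (length(missing))
    stop("concentrations missing for: ", paste(missing, collapse = ", "))
  if (length(setdiff(expected, names(linewidths))))
    stop("linewidths missing for: ",
         paste(setdiff(expected, names(linewidths)), collapse = ", "))
  structure(
    list(field = field,
         concentrations = concentrations[expected],
         linewidths = linewidths[expected],
         lb_factor = lb_factor, baseline = baseline,
         target_snr = target_snr, noise_sigma = noise_sigma,
         seed = as.integer(seed), subject_id = subject_id),
    class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s%s: %d metabolites, lb %g Hz, baseline %s, %s\n",
              x$field,
              if (is.na(x$subject_id)) "" else paste0(" subject ", x$subject_id),
              length(x$concentrations), x$lb_factor,
              if (is.null(x$baseline)) "off" else "on",
              if (is.null(x$noise_sigma))
                sprintf("target SNR %g", x$target_snr)
              else sprintf("sigma %g", x$noise_sigma)))
  invisible(x)
}

#' Attach the default downfield baseline to a scenario
#'
#' Scales the hump to `scale` times the MP peak height of the scenario's
#' noiseless metabolite spectrum, so the baseline inherits the field
#' dependence of the MP signal.
#'
#' @param scn A [scenario()].
#' @param basis Matching [build_basis_set()].
#' @param proc [proc_params()].
#' @param scale Hump height relative to the MP peak height (default 1).
#' @return The scenario with `$baseline` set.
#' @export
with_default_baseline <- function(scn, basis, proc = proc_params(), scale = 1) {
  mp_only <- scn
  mp_only$concentrations[setdiff(names(mp_only$concentrations), "MP")] <- 0
  mp_only$baseline <- NULL
  sp <- compose_spectrum(basis, mp_only, proc)
  mp_height <- max(Re(sp$values[sp$ppm > -5 & sp$ppm < 8]))
  scn$baseline <- default_baseline(peak_height = scale * mp_height)
  scn
}

#' Generate the jittered subject scenarios of the baseline experiment
#'
#' Emits `n` subject scenarios per field emulating between-participant
#' variability: all linewidths are scaled by a common factor drawn so the
#' PCr width matches the in vivo spread (6.3 +- 0.9 Hz at 3 T, 9.3 +- 2.1 Hz
#' at 7 T), the target SNR is drawn from the in vivo spread (82 +- 21,
#' 171 +- 27), and concentrations receive 10% multiplicative jitter.
#' Draws are seeded and reproducible.
#'
#' @param field `"3T"` or `"7T"`.
#' @param n Number of subjects (default 5).
#' @param base_seed Integer seed for the jitter stream.
#' @param baseline `"none"` leaves `$baseline` NULL (attach later with
#'   [with_default_baseline()] if wanted).
#' @return List of `n` [scenario()] objects.
#' @export
subject_scenarios <- function(field = c("3T", "7T"), n = 5, base_seed = 1L,
                              baseline = "none") {
  field <- match.arg(field)
  lw0 <- .default_linewidths(field)
  conc0 <- .default_concentrations(field)
  pcr_sd <- if (field == "3T") 0.9 else 2.1
  snr0 <- .default_snr(field)
  snr_sd <- if (field == "3T") 21 else 27
  out <- vector("list", n)
  set.seed(base_seed)
  for (j in seq_len(n)) {
    lw_scale <- max(0.5, stats::rnorm(1, 1, pcr_sd / lw0[["PCr"]]))
    snr <- max(20, stats::rnorm(1, snr0, snr_sd))
    jitter <- pmax(0.5, stats::rnorm(length(conc0), 1, 0.10))
    conc <- conc0 * jitter
    conc["ATP"] <- conc0[["ATP"]]  # internal reference stays 9 mM
    lw <- lw0 * lw_scale
    lw["MP"] <- lw0[["MP"]]        # broad pool width is not shim-limited
    lw["NAD+"] <- lw["NADH"] <- max(lw[["ATP"]] - 1.5, 0.5)
    out[[j]] <- scenario(field, concentrations = conc, linewidths = lw,
                         target_snr = snr, seed = base_seed + j,
                         subject_id = sprintf("S%d", j))
  }
  out
}
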