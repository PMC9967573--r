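# Constrained linear-combination-model (LCM) fitting.
#
# The model for the real part of the spectrum over the fit window is
#   y(ppm) = sum_m a_m * Re S_m(ppm; lw_m, d_m) + poly(ppm; b) + noise
# where S_m is the processed basis signal of metabolite m broadened to total
# Lorentzian FWHM lw_m and shifted by d_m ppm, a_m >= 0 are amplitudes, and
# poly is a polynomial baseline over the normalized window. Amplitudes and
# baseline coefficients enter linearly and are solved exactly at each
# nonlinear step (variable projection); lw and d are bounded nonlinear
# parameters. The NAD+ and NADH linewidths are never free: they are tied to
# the ATP linewidth minus 1.5 Hz (floored at 0).

#' Fit configuration
#'
#' @param window ppm fit interval (closed; default `c(-20, 10)`).
#' @param baseline_degree Polynomial baseline degree, or `NA` to disable the
#'   baseline block entirely.
#' @param optimize_linewidths,optimize_shifts If `TRUE`, refine the
#'   per-metabolite nonlinear parameters by bounded optimization; if `FALSE`
#'   (the Monte Carlo default) the fit is linearized at the starting values.
#' @param lw_bounds Allowed total-FWHM range in Hz.
#' @param shift_bound Allowed |shift| in ppm.
#' @param nad_offset_hz NAD linewidth tie: `lw_NAD = lw_ATP - nad_offset_hz`.
#' @param reference_atp_mm Total-ATP concentration assumed for internal
#'   referencing (9 mM).
#' @param nonneg Bound amplitudes at zero (default TRUE).
#' @param max_iter Iteration cap for the nonlinear refinement.
#' @return A `fit_config` list.
#' @export
fit_config <- function(window = c(-20, 10), baseline_degree = 6,
                       optimize_linewidths = FALSE, optimize_shifts = FALSE,
                       lw_bounds = c(1.5, 60), shift_bound = 0.2,
                       nad_offset_hz = 1.5, reference_atp_mm = 9,
                       nonneg = TRUE, max_iter = 100) {
  stopifnot(length(window) == 2, window[1] < window[2],
            is.na(baseline_degree) || baseline_degree >= 0,
            lw_bounds[1] >= 0, lw_bounds[1] < lw_bounds[2], shift_bound >= 0)
  structure(list(window = window, baseline_degree = baseline_degree,
                 optimize_linewidths = isTRUE(optimize_linewidths),
                 optimize_shifts = isTRUE(optimize_shifts),
                 lw_bounds = lw_bounds, shift_bound = shift_bound,
                 nad_offset_hz = nad_offset_hz,
                 reference_atp_mm = reference_atp_mm,
                 nonneg = isTRUE(nonneg), max_iter = max_iter),
            class = "fit_config")
}

# Apply the NAD linewidth tie to a named linewidth vector.
.apply_nad_constraint <- function(lw, offset_hz) {
  if ("ATP" %in% names(lw)) {
    tied <- max(lw[["ATP"]] - offset_hz, 0)
    for (nm in c("NAD+", "NADH")) if (nm %in% names(lw)) lw[[nm]] <- tied
  }
  lw
}

# Default starting values: ground truth when the spectrum carries it,
# otherwise the field defaults.
.start_values <- function(spectrum, basis, config) {
  truth <- attr(spectrum, "truth")
  field <- attr(basis, "field")
  if (!is.null(truth)) {
    lw <- truth$linewidths + truth$lb_factor
  } else {
    lw <- .default_linewidths(field)
  }
  lw <- lw[names(basis)]
  names(lw) <- names(basis)
  lw <- .apply_nad_constraint(lw, config$nad_offset_hz)
  shifts <- stats::setNames(numeric(length(basis)), names(basis))
  list(linewidths = lw, shifts = shifts)
}

# Indices of the fit window on a spectrum's ppm axis.
.window_index <- function(ppm, window) which(ppm >= window[1] & ppm <= window[2])

# Polynomial baseline regressors over the normalized window.
.baseline_columns <- function(ppm_win, window, degree) {
  x <- (2 * ppm_win - sum(window)) / diff(window)
  outer(x, 0:degree, `^`)
}

# Design matrix of metabolite regressors (real part over the window) at
# given nonlinear parameters. Columns follow names(basis).
.metabolite_columns <- function(basis, proc, idx, linewidths, shifts) {
  grid <- attr(basis, "grid")
  t <- grid_times(grid)
  X <- matrix(0, length(idx), length(basis),
              dimnames = list(NULL, names(basis)))
  for (nm in names(basis)) {
    b <- basis[[nm]]
    extra <- .extra_decay_hz(linewidths[[nm]], b$intrinsic_fwhm_hz, proc$lb_hz)
    mod <- exp((2i * pi * shifts[[nm]] * grid$larmor_mhz - pi * extra) * t)
    sp <- process_fid(b$fid * mod, grid, proc)
    X[, nm] <- Re(sp$values[idx])
  }
  X
}

# Solve min ||y - Xa a - Xb b||^2 with a >= 0 (optionally), b free.
# Baseline columns are projected out by QR, the non-negative amplitude
# problem is solved on the projected system, and b is back-substituted.
.solve_linear <- function(Xa, Xb, y, nonneg = TRUE) {
  if (!is.null(Xb)) {
    qb <- qr(Xb)
    Q <- qr.Q(qb)
    ya <- y - Q %*% crossprod(Q, y)
    Xat <- Xa - Q %*% crossprod(Q, Xa)
  } else {
    ya <- y
    Xat <- Xa
  }
  a <- tryCatch(qr.solve(Xat, ya), error = function(e) rep(0, ncol(Xa)))
  a <- as.vector(a)
  if (nonneg && any(a < 0)) a <- pracma::lsqnonneg(Xat, as.vector(ya))$x
  names(a) <- colnames(Xa)
  b <- NULL
  if (!is.null(Xb)) b <- as.vector(qr.coef(qb, y - Xa %*% a))
  fitted <- as.vector(Xa %*% a + if (is.null(Xb)) 0 else Xb %*% b)
  list(amplitudes = a, baseline = b, fitted = fitted,
       rss = sum((y - fitted)^2))
}

# Free nonlinear parameter bookkeeping: linewidths for all metabolites
# except NAD+/NADH (tied to ATP); shifts for all metabolites.
.free_lw_names <- function(basis) setdiff(names(basis), c("NAD+", "NADH"))

#' Fit a spectrum with the constrained linear-combination model
#'
#' Minimizes the squared residual of the real part over the fit window with
#' respect to non-negative per-metabolite amplitudes, a polynomial baseline
#' (both linear, solved exactly by variable projection), and bounded
#' per-metabolite total linewidths and frequency shifts (nonlinear,
#' optionally refined with `L-BFGS-B`). The NAD+/NADH linewidths are
#' constrained to the ATP linewidth minus 1.5 Hz throughout. The fit is
#' deterministic given the spectrum and starting values.
#'
#' @param spectrum A `p31_spectrum` (preprocessed).
#' @param basis A matching [build_basis_set()].
#' @param config A [fit_config()].
#' @param start Optional list with named `linewidths` (Hz) and `shifts`
#'   (ppm); defaults to the spectrum's attached ground truth or the field
#'   defaults.
#' @param proc The [proc_params()] the data went through (the basis
#'   regressors are pushed through the same chain).
#' @return Object of class `fit_result`: `amplitudes` (a.u. = mM under the
#'   generator normalization), `concentrations` (after total-ATP = 9 mM
#'   referencing), `linewidths`, `shifts`, `baseline_coefficients`,
#'   `residual_norm`, `converged`, `flags`.
#' @export
fit_lcm <- function(spectrum, basis, config = fit_config(), start = NULL,
                    proc = proc_params()) {
  if (attr(basis, "field") != spectrum$grid$field)
    stop("basis field does not match spectrum field")
  idx <- .window_index(spectrum$ppm, config$window)
  if (!length(idx)) stop("fit window outside the spectrum")
  y <- Re(spectrum$values[idx])
  flags <- character()
  if (all(y == 0)) flags <- c(flags, "all-zero spectrum")

  sv <- .start_values(spectrum, basis, config)
  if (!is.null(start)) {
    if (!is.null(start$linewidths)) sv$linewidths[names(start$linewidths)] <- start$linewidths
    if (!is.null(start$shifts)) sv$shifts[names(start$shifts)] <- start$shifts
    sv$linewidths <- .apply_nad_constraint(sv$linewidths, config$nad_offset_hz)
  }
  Xb <- if (is.na(config$baseline_degree)) NULL else
    .baseline_columns(spectrum$ppm[idx], config$window, config$baseline_degree)

  build <- function(lw, sh) .metabolite_columns(basis, proc, idx, lw, sh)

  lw <- sv$linewidths
  sh <- sv$shifts
  converged <- TRUE
  if (config$optimize_linewidths || config$optimize_shifts) {
    lw_names <- if (config$optimize_linewidths) .free_lw_names(basis) else character()
    sh_names <- if (config$optimize_shifts) names(basis) else character()
    par0 <- c(lw[lw_names], if (length(sh_names)) stats::setNames(sh[sh_names], paste0("d_", sh_names)))
    lower <- c(rep(config$lw_bounds[1], length(lw_names)),
               rep(-config$shift_bound, length(sh_names)))
    upper <- c(rep(config$lw_bounds[2], length(lw_names)),
               rep(config$shift_bound, length(sh_names)))
    unpack <- function(p) {
      l <- lw; s <- sh
      if (length(lw_names)) l[lw_names] <- p[seq_along(lw_names)]
      l <- .apply_nad_constraint(l, config$nad_offset_hz)
      if (length(sh_names)) s[sh_names] <- p[length(lw_names) + seq_along(sh_names)]
      list(lw = l, sh = s)
    }
    obj <- function(p) {
      th <- unpack(p)
      # unconstrained inner solve keeps the objective smooth for L-BFGS-B
      .solve_linear(build(th$lw, th$sh), Xb, y, nonneg = FALSE)$rss
    }
    opt <- stats::optim(par0, obj, method = "L-BFGS-B", lower = lower,
                        upper = upper,
                        control = list(maxit = config$max_iter))
    converged <- opt$convergence == 0
    if (!converged) flags <- c(flags, sprintf("optim convergence code %d", opt$convergence))
    th <- unpack(opt$par)
    lw <- th$lw
    sh <- th$sh
  }

  sol <- .solve_linear(build(lw, sh), Xb, y, nonneg = config$nonneg)
  if ("ATP" %in% names(sol$amplitudes) && sol$amplitudes[["ATP"]] > 0) {
    conc <- .reference_to_atp(sol$amplitudes, config$reference_atp_mm)
  } else {
    conc <- sol$amplitudes * NA_real_
    flags <- c(flags, "zero ATP amplitude: concentrations undefined")
  }
  structure(
    list(amplitudes = sol$amplitudes, concentrations = conc,
         linewidths = lw, shifts = sh,
         baseline_coefficients = sol$baseline,
         residual_norm = sqrt(sol$rss),
         fitted = sol$fitted, window_ppm = spectrum$ppm[idx],
         converged = converged && !length(flags), flags = flags,
         config = config),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %d metabolites, residual %.4g, %s\n",
              length(x$amplitudes), x$residual_norm,
              if (x$converged) "converged" else
                paste("flagged:", paste(x$flags, collapse = "; "))))
  print(round(x$concentrations, 3))
  invisible(x)
}

.reference_to_atp <- function(amplitudes, atp_mm = 9) {
  if (!"ATP" %in% names(amplitudes)) stop("no ATP amplitude to reference to")
  atp <- amplitudes[["ATP"]]
  if (atp <= 0) stop("ATP amplitude is zero; cannot reference concentrations")
  amplitudes * atp_mm / atp
}

#' Convert fitted amplitudes to concentrations by total-ATP referencing
#'
#' `conc_m = amplitude_m * 9 / amplitude_ATP`: total ATP (the single ATP
#' basis amplitude, covering its three 31P moieties) is assumed to be 9 mM.
#'
#' @param result A `fit_result` (or a named amplitude vector).
#' @param atp_mm Reference total-ATP concentration in mM.
#' @return Named concentration vector (mM).
#' @export
quantify_concentrations <- function(result, atp_mm = 9) {
  amp <- if (inherits(result, "fit_result")) result$amplitudes else result
  .reference_to_atp(amp, atp_mm)
}

#' Analytic correlation oracle for the linearized fit
#'
#' For fixed nonlinear parameters the LCM estimator is linear, with
#' amplitude covariance `sigma^2 * (X'X)^-1` where the columns of `X` are
#' the windowed real-part metabolite regressors plus the baseline
#' polynomial. The normalized amplitude block of the inverse normal matrix
#' predicts the Monte Carlo Pearson correlations, independently of the noise
#' level and the true amplitudes.
#'
#' @param basis A [build_basis_set()].
#' @param config A [fit_config()] (its window/baseline define the design).
#' @param linewidths Named total-FWHM vector (Hz); defaults to field
#'   defaults with the NAD tie applied.
#' @param shifts Named shift vector (ppm); defaults to zero.
#' @param proc [proc_params()].
#' @return A `correlation_matrix` (see [pearson_matrix()]) over the
#'   metabolite amplitudes.
#' @export
analytic_correlation_oracle <- function(basis, config = fit_config(),
                                        linewidths = NULL, shifts = NULL,
                                        proc = proc_params()) {
  grid <- attr(basis, "grid")
  field <- attr(basis, "field")
  if (is.null(linewidths))
    linewidths <- .apply_nad_constraint(.default_linewidths(field)[names(basis)],
                                        config$nad_offset_hz)
  if (is.null(shifts)) shifts <- stats::setNames(numeric(length(basis)), names(basis))
  # any processed axis works; build one from a zero FID
  sp <- process_fid(complex(grid$n_points), grid, proc)
  idx <- .window_index(sp$ppm, config$window)
  Xa <- .metabolite_columns(basis, proc, idx, linewidths, shifts)
  X <- if (is.na(config$baseline_degree)) Xa else
    cbind(Xa, .baseline_columns(sp$ppm[idx], config$window, config$baseline_degree))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(Xa)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
    bad <- bad[!is.na(bad)]
    stop("design is rank deficient; collinear columns involve: ",
         paste(unique(bad), collapse = ", "))
  }
  Cinv <- chol2inv(chol(crossprod(X)))
  k <- ncol(Xa)
  Ca <- Cinv[seq_len(k), seq_len(k), drop = FALSE]
  r <- stats::cov2cor(Ca)
  dimnames(r) <- list(colnames(Xa), colnames(Xa))
  new_correlation_matrix(r, n = NA_integer_,
                         note = "analytic (X'X)^-1 oracle")
}
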