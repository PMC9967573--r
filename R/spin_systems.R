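#' Define a 31P spin system
#'
#' A spin system is either a set of coupled spin-1/2 31P nuclei (chemical
#' shifts in ppm relative to PCr, scalar couplings in Hz) or a single broad
#' Lorentzian component standing in for the macromolecule membrane
#' phospholipid (MP) signal.
#'
#' Spectra are modeled as acquired without 1H decoupling, so single-31P
#' metabolites may carry an effective first-order proton multiplet
#' (`proton_multiplet = c(multiplicity, J_hz)`): the FID is modulated by
#' `cos(pi J t)^(multiplicity - 1)`, i.e. a triplet uses multiplicity 3.
#' Proton multiplets are only supported on single-31P systems; on coupled
#' multi-31P systems they would not factor out of the density-matrix
#' evolution.
#'
#' @param name Metabolite identifier.
#' @param shifts_ppm Chemical shift of each 31P nucleus (ppm, PCr = 0).
#' @param j_hz Symmetric J-coupling matrix in Hz (zero diagonal). May be
#'   omitted for uncoupled systems.
#' @param proton_multiplet Optional `c(multiplicity, J_hz)` effective
#'   1H-31P splitting. `multiplicity >= 1`.
#' @param broad If `TRUE` the system is a single broad Lorentzian
#'   ("macromolecule") component with intrinsic width `broad_fwhm_hz`.
#' @param broad_fwhm_hz Intrinsic FWHM (Hz) of a broad component.
#' @return Object of class `spin_system`.
#' @export
#' @examples
#' atp <- spin_system("ATP", c(-2.53, -7.56, -16.18),
#'                    j_hz = j_matrix(3, "1-3" = 16.3, "2-3" = 16.3))
spin_system <- function(name, shifts_ppm, j_hz = NULL, proton_multiplet = NULL,
                        broad = FALSE, broad_fwhm_hz = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  shifts_ppm <- as.numeric(shifts_ppm)
  n <- length(shifts_ppm)
  if (!all(is.finite(shifts_ppm))) stop("shifts must be finite")
  if (broad) {
    if (n != 1) stop("a broad component has exactly one nucleus")
    if (!is.null(j_hz) && any(j_hz != 0)) stop("a broad component has no couplings")
    if (is.null(broad_fwhm_hz) || broad_fwhm_hz <= 0)
      stop("a broad component needs broad_fwhm_hz > 0")
    j_hz <- matrix(0, 1, 1)
  }
  if (is.null(j_hz)) j_hz <- matrix(0, n, n)
  j_hz <- as.matrix(j_hz)
  if (!identical(dim(j_hz), c(n, n)) || any(abs(j_hz - t(j_hz)) > 1e-12))
    stop(sprintf("'%s': J matrix must be %dx%d symmetric", name, n, n))
  if (any(diag(j_hz) != 0)) stop("J matrix must have zero diagonal")
  if (n > 6) stop("spin systems with more than 6 nuclei are not supported")
  if (!is.null(proton_multiplet)) {
    if (n > 1) stop("proton multiplets are only supported on single-31P systems")
    stopifnot(length(proton_multiplet) == 2, proton_multiplet[1] >= 1,
              proton_multiplet[2] >= 0)
  }
  structure(
    list(name = name, shifts_ppm = shifts_ppm, j_hz = j_hz,
         proton_multiplet = proton_multiplet, broad = broad,
         broad_fwhm_hz = if (broad) broad_fwhm_hz else 0,
         n_phosphorus = n),
    class = "spin_system")
}

#' Build a symmetric J-coupling matrix from pair specifications
#'
#' @param n Number of nuclei.
#' @param ... Named couplings `"i-j" = J_hz`.
#' @return `n x n` symmetric matrix with zero diagonal.
#' @export
j_matrix <- function(n, ...) {
  J <- matrix(0, n, n)
  pairs <- list(...)
  for (nm in names(pairs)) {
    ij <- as.integer(strsplit(nm, "-", fixed = TRUE)[[1]])
    stopifnot(length(ij) == 2, all(ij >= 1), all(ij <= n), ij[1] != ij[2])
    J[ij[1], ij[2]] <- J[ij[2], ij[1]] <- pairs[[nm]]
  }
  J
}

#' @export
print.spin_system <- function(x, ...) {
  if (x$broad) {
    cat(sprintf("<spin_system> %s: broad, %.2f ppm, FWHM %g Hz\n",
                x$name, x$shifts_ppm, x$broad_fwhm_hz))
  } else {
    cat(sprintf("<spin_system> %s: %d x 31P at %s ppm\n", x$name,
                x$n_phosphorus, paste(format(x$shifts_ppm), collapse = ", ")))
  }
  invisible(x)
}

# Canonical metabolite display order used everywhere (tables, matrices).
.metabolite_order <- c("PCr", "ATP", "NAD+", "NADH", "UDPG", "GPC", "GPE",
                       "Pi_ex", "Pi_in", "PC", "PE", "MP")

#' Default brain 31P spin-system table
#'
#' Literature-convention chemical shifts (ppm, PCr = 0) and couplings for the
#' 12 components of the spectral model covering -20..10 ppm: PCr, ATP
#' (gamma/alpha/beta at -2.53/-7.56/-16.18 ppm, J = 16.3 Hz), NAD+ and NADH
#' (each a strongly coupled pyrophosphate AB pair, centered at -8.30 and
#' -8.15 ppm, J = 20 Hz), UDPG (-9.8/-11.6 ppm, J = 20 Hz; used at 7 T only),
#' the downfield phosphomono-/diesters and inorganic phosphate pools
#' (PE 6.78, PC 6.24, Pi_ex 5.25, Pi_in 4.85, GPE 3.50, GPC 2.95 ppm, with
#' effective undecoupled 1H triplets on the esters), and a broad MP component
#' at 1.7 ppm whose intrinsic width is field dependent (250 Hz at 3 T, 450 Hz
#' at 7 T). All values are configuration, not ground truth, and can be
#' overridden via [load_spin_systems()].
#'
#' @param field `"3T"` or `"7T"` (controls the MP width; the shift table is
#'   field independent).
#' @return Named list of [spin_system()] objects in canonical order.
#' @export
default_spin_systems <- function(field = c("3T", "7T")) {
  field <- match.arg(field)
  mp_fwhm <- if (field == "3T") 250 else 450
  systems <- list(
    spin_system("PCr", 0.00),
    # nuclei ordered gamma, alpha, beta; both couplings to beta are 16.3 Hz
    spin_system("ATP", c(-2.53, -7.56, -16.18),
                j_hz = j_matrix(3, "1-3" = 16.3, "2-3" = 16.3)),
    spin_system("NAD+", c(-8.33, -8.27), j_hz = j_matrix(2, "1-2" = 20)),
    spin_system("NADH", c(-8.18, -8.12), j_hz = j_matrix(2, "1-2" = 20)),
    spin_system("UDPG", c(-9.8, -11.6), j_hz = j_matrix(2, "1-2" = 20)),
    spin_system("GPC", 2.95, proton_multiplet = c(3, 6.3)),
    spin_system("GPE", 3.50, proton_multiplet = c(3, 7.3)),
    spin_system("Pi_ex", 5.25),
    spin_system("Pi_in", 4.85),
    spin_system("PC", 6.24, proton_multiplet = c(3, 6.3)),
    spin_system("PE", 6.78, proton_multiplet = c(3, 7.3)),
    spin_system("MP", 1.7, broad = TRUE, broad_fwhm_hz = mp_fwhm)
  )
  names(systems) <- vapply(systems, `[[`, "", "name")
  systems[intersect(.metabolite_order, names(systems))]
}

#' Read a spin-system table from a YAML file
#'
#' The file holds one record per metabolite with fields `name`, `shifts_ppm`,
#' optional `j_hz` (row-major full matrix), optional
#' `proton_multiplet` (`[multiplicity, J_hz]`), and optional `broad` /
#' `broad_fwhm_hz`. A template is shipped at
#' `system.file("extdata", "spin_systems.yaml", package = "p31corr")`.
#'
#' @param path YAML file path.
#' @return Named list of [spin_system()] objects.
#' @export
load_spin_systems <- function(path) {
  raw <- yaml::read_yaml(path)
  systems <- lapply(raw, function(rec) {
    n <- length(rec$shifts_ppm)
    jm <- if (is.null(rec$j_hz)) NULL else
      matrix(unlist(rec$j_hz), n, n, byrow = TRUE)
    spin_system(rec$name, rec$shifts_ppm, j_hz = jm,
                proton_multiplet = if (is.null(rec$proton_multiplet)) NULL
                                   else unlist(rec$proton_multiplet),
                broad = isTRUE(rec$broad),
                broad_fwhm_hz = rec$broad_fwhm_hz)
  })
  names(systems) <- vapply(systems, `[[`, "", "name")
  systems
}

#' Write a spin-system table to YAML
#' @param systems Named list of [spin_system()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spin_systems <- function(systems, path) {
  recs <- lapply(unname(systems), function(s) {
    r <- list(name = s$name, shifts_ppm = as.list(s$shifts_ppm))
    if (any(s$j_hz != 0)) r$j_hz <- apply(s$j_hz, 1, as.list, simplify = FALSE)
    if (!is.null(s$proton_multiplet))
      r$proton_multiplet <- as.list(s$proton_multiplet)
    if (s$broad) { r$broad <- TRUE; r$broad_fwhm_hz <- s$broad_fwhm_hz }
    r
  })
  yaml::write_yaml(recs, path)
  invisible(path)
}
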