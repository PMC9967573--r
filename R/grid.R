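#' Acquisition grid for a 31P MRS experiment
#'
#' Describes the sampling raster and the field-dependent Larmor frequency on
#' which all FIDs and spectra live. The rotating-frame origin (0 ppm) is
#' placed at phosphocreatine (PCr), the standard 31P reference.
#'
#' The nominal fields are 3.0 and 7.0 T with 31P Larmor frequencies of
#' 51.705 and 120.645 MHz (gamma/2pi = 17.235 MHz/T).
#'
#' @param field `"3T"` or `"7T"`.
#' @param sweep_hz Spectral width in Hz.
#' @param n_points Number of complex time-domain points.
#' @param reference_ppm ppm value assigned to the PCr resonance.
#' @return An object of class `acq_grid` with fields `b0`, `larmor_mhz`
#'   (so 1 ppm corresponds to `larmor_mhz` Hz), `sweep_hz`, `n_points`,
#'   `dwell` (s, `1/sweep_hz`) and `reference_ppm`.
#' @export
#' @examples
#' g <- acq_grid("3T")
#' g$dwell * g$sweep_hz  # always 1
acq_grid <- function(field = c("3T", "7T"), sweep_hz = 5000, n_points = 1024,
                     reference_ppm = 0) {
  field <- match.arg(field)
  b0 <- if (field == "3T") 3.0 else 7.0
  larmor <- 17.235 * b0  # MHz
  stopifnot(sweep_hz > 0, n_points >= 8)
  structure(
    list(field = field, b0 = b0, larmor_mhz = larmor, sweep_hz = sweep_hz,
         n_points = as.integer(n_points), dwell = 1 / sweep_hz,
         reference_ppm = reference_ppm),
    class = "acq_grid")
}

#' @export
print.acq_grid <- function(x, ...) {
  cat(sprintf("<acq_grid> %s (%.1f T, 31P %.3f MHz), %d pts @ %g Hz sweep\n",
              x$field, x$b0, x$larmor_mhz, x$n_points, x$sweep_hz))
  invisible(x)
}

#' Time axis of an acquisition grid
#' @param grid An [acq_grid()].
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
grid_times <- function(grid) (seq_len(grid$n_points) - 1) * grid$dwell

.assert_grid <- function(grid) {
  if (!inherits(grid, "acq_grid")) stop("`grid` must be an acq_grid object")
  invisible(grid)
}
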