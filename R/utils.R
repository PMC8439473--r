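# Shared numeric helpers.

# speed of light in cm/fs; converts wavenumber (cm^-1) to cycles/fs
C_CM_PER_FS <- 2.99792458e-5

# weights of the four-frame phase-cycling combination; the raw-data emitter
# and the preprocessor must agree on this single definition
PHASE_CYCLE_WEIGHTS <- c(1, -1, -1, 1) / 4

# probe detector pixel pitch in cm^-1
PROBE_RESOLUTION <- 2.5

#' Test spectral frequencies for equality within the probe resolution
#'
#' Two frequencies are considered the same measurement when they differ by no
#' more than the probe resolution (2.5 cm^-1 by default), absorbing
#' calibration drift between acquisition sessions.
#'
#' @param f1,f2 Frequencies in cm^-1 (vectorized).
#' @param resolution Non-negative tolerance in cm^-1.
#' @return Logical vector.
#' @export
frequencies_equal <- function(f1, f2, resolution = PROBE_RESOLUTION) {
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution < 0)
    stop("'resolution' must be a single non-negative number")
  if (any(!is.finite(f1)) || any(!is.finite(f2)))
    stop("frequencies must be finite")
  abs(f1 - f2) <= resolution
}

# index of the grid point nearest to 'target'; NA if farther than 'tol'
nearest_index <- function(axis, target, tol = PROBE_RESOLUTION) {
  i <- which.min(abs(axis - target))
  if (abs(axis[i] - target) > tol) return(NA_integer_)
  i
}

# three-point parabolic peak refinement around index i of y sampled on x
# (uniform spacing assumed); returns the refined abscissa
parabolic_refine <- function(x, y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(x[i])
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (abs(denom) < .Machine$double.eps * max(abs(y), 1)) return(x[i])
  delta <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
  delta <- max(min(delta, 0.5), -0.5)
  x[i] + delta * (x[min(i + 1L, n)] - x[i])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
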