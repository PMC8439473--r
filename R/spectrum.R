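# 2D amide-I spectra: container, lineshape rendering, linear mixing.

#' Default pump and probe frequency axes
#'
#' The probe axis models the 64-element MCT detector with its 2.5 cm^-1
#' pixel pitch; the pump axis is the Fourier axis sampled on the same pitch
#' over the amide I region.
#'
#' @param n_probe Number of detector elements.
#' @return List with \code{pump} and \code{probe} numeric axes (cm^-1).
#' @export
default_axes <- function(n_probe = 64L) {
  list(pump = seq(1580, 1720, by = PROBE_RESOLUTION),
       probe = 1580 + PROBE_RESOLUTION * seq_len(n_probe) - PROBE_RESOLUTION)
}

#' Construct a 2D spectrum
#'
#' @param pump_axis,probe_axis Monotonically increasing frequency axes,
#'   cm^-1.
#' @param amplitude Signed matrix indexed \code{[pump, probe]}.
#' @param meta Named list of metadata (sample class, environment, pixel).
#' @return Object of class \code{Spectrum2D}.
#' @export
spectrum2d <- function(pump_axis, probe_axis, amplitude, meta = list()) {
  if (any(diff(pump_axis) <= 0) || any(diff(probe_axis) <= 0))
    stop("axes must be strictly increasing")
  amplitude <- as.matrix(amplitude)
  if (nrow(amplitude) != length(pump_axis) ||
      ncol(amplitude) != length(probe_axis))
    stop("amplitude dimensions must match axis lengths")
  structure(list(pump_axis = pump_axis, probe_axis = probe_axis,
                 amplitude = amplitude, meta = meta),
            class = "Spectrum2D")
}

#' @export
print.Spectrum2D <- function(x, ...) {
  cat(sprintf("<Spectrum2D %dx%d, pump %.1f-%.1f, probe %.1f-%.1f cm-1>\n",
              length(x$pump_axis), length(x$probe_axis),
              min(x$pump_axis), max(x$pump_axis),
              min(x$probe_axis), max(x$probe_axis)))
  invisible(x)
}

# Rotated-frame 2D Gaussian centered at (cx, cy): unit peak, width sd along
# the diagonal direction (pump = probe) and sa along the anti-diagonal.
gauss2d_rot <- function(wp, wr, cx, cy, sd, sa) {
  dp <- wp - cx
  dr <- wr - cy
  d <- (dp + dr) / sqrt(2)
  a <- (dr - dp) / sqrt(2)
  exp(-d^2 / (2 * sd^2) - a^2 / (2 * sa^2))
}

# evaluate one component on arbitrary (vectorized, recycled) coordinates
component_field <- function(c, wp, wr) {
  A <- c$mu^4
  val <- A * (gauss2d_rot(wp, wr, c$omega0, c$omega0,
                          c$sigma_diag, c$sigma_antidiag) -
              gauss2d_rot(wp, wr, c$omega0, c$omega0 - c$delta,
                          c$sigma_diag, c$sigma_antidiag))
  if (!is.null(c$crosspeak)) {
    xp <- c$crosspeak
    # off-diagonal lobes: unrotated Gaussian; pump width is the isotropic
    # compromise of the two diagonal widths, probe width the homogeneous one
    sp <- sqrt((c$sigma_diag^2 + c$sigma_antidiag^2) / 2)
    sr <- c$sigma_antidiag
    g <- function(cy) exp(-(wp - xp$nu_pump)^2 / (2 * sp^2) -
                            (wr - cy)^2 / (2 * sr^2))
    val <- val + A * xp$amplitude_ratio *
      (g(xp$nu_perp) - g(xp$nu_perp - c$delta))
  }
  val
}

#' Render one spectral component onto a frequency grid
#'
#' The 2DIR signature of a single band: a positive fundamental lobe at
#' (omega0, omega0) and a negative overtone lobe displaced by the anharmonic
#' shift along the probe axis, both 2D Gaussians elongated along the
#' diagonal; beta-sheet components add a cross-peak pair at the component's
#' cross-peak coordinates. The peak amplitude scales as \code{mu^4}.
#'
#' Detector pixels integrate over their width: with \code{oversample > 1}
#' each probe pixel value is the box average of \code{oversample} sub-points
#' spanning the pixel (0.5 cm^-1 sub-grid at the default pitch and
#' \code{oversample = 5}).
#'
#' @param component A \code{SpectralComponent}.
#' @param pump_axis,probe_axis Target axes, cm^-1; must cover the component
#'   (peak truncation beyond 1\% of mass is rejected).
#' @param oversample Integer >= 1; probe-pixel box-averaging factor.
#' @return A \code{Spectrum2D}.
#' @export
render_component <- function(component, pump_axis, probe_axis,
                             oversample = 1L) {
  # 2.5-sigma margins keep truncated mass below ~1% per lobe
  sm <- sqrt((component$sigma_diag^2 + component$sigma_antidiag^2) / 2)
  probe_lo <- component$omega0 - component$delta - 2.5 * sm
  probe_hi <- component$omega0 + 2.5 * sm
  pump_lo <- component$omega0 - 2.5 * sm
  pump_hi <- component$omega0 + 2.5 * sm
  if (!is.null(component$crosspeak)) {
    probe_hi <- max(probe_hi,
                    component$crosspeak$nu_perp +
                      2.5 * component$sigma_antidiag)
    pump_lo <- min(pump_lo, component$crosspeak$nu_pump - 2.5 * sm)
    pump_hi <- max(pump_hi, component$crosspeak$nu_pump + 2.5 * sm)
  }
  if (min(probe_axis) > probe_lo || max(probe_axis) < probe_hi ||
      min(pump_axis) > pump_lo || max(pump_axis) < pump_hi)
    stop("axes too narrow for component '", component$name,
         "': peak truncation would exceed 1% of mass")
  oversample <- as.integer(oversample)
  if (oversample < 1L) stop("'oversample' must be >= 1")
  if (oversample == 1L) {
    wp <- matrix(pump_axis, length(pump_axis), length(probe_axis))
    wr <- matrix(probe_axis, length(pump_axis), length(probe_axis),
                 byrow = TRUE)
    amp <- component_field(component, wp, wr)
  } else {
    pitch <- median(diff(probe_axis))
    off <- (seq_len(oversample) - (oversample + 1) / 2) * pitch / oversample
    amp <- 0
    for (o in off) {
      wp <- matrix(pump_axis, length(pump_axis), length(probe_axis))
      wr <- matrix(probe_axis + o, length(pump_axis), length(probe_axis),
                   byrow = TRUE)
      amp <- amp + component_field(component, wp, wr)
    }
    amp <- amp / oversample
  }
  spectrum2d(pump_axis, probe_axis, amp,
             meta = list(component = component$name))
}

#' Compose a mixture spectrum from weighted components
#'
#' Linear superposition of rendered component bands plus i.i.d. Gaussian
#' noise; stands in for the heterogeneous distribution of secondary
#' structures within one tissue location.
#'
#' @param weights Named non-negative weights over library components,
#'   summing to 1 (components may be omitted; omitted means 0).
#' @param library Component library from \code{\link{component_library}}.
#' @param axes List with \code{pump} and \code{probe} axes (default
#'   \code{\link{default_axes}()}).
#' @param noise_sd Standard deviation of additive Gaussian noise, in
#'   post-normalization amplitude units. Uses the current RNG stream;
#'   deterministic under \code{set.seed}.
#' @param oversample Probe-pixel box-averaging factor (see
#'   \code{\link{render_component}}).
#' @param meta Metadata list stored on the result.
#' @return A \code{Spectrum2D}.
#' @export
compose_spectrum <- function(weights, library, axes = default_axes(),
                             noise_sd = 0, oversample = 1L, meta = list()) {
  if (is.null(names(weights)) || !all(names(weights) %in% names(library)))
    stop("weights must be named after library components")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  amp <- matrix(0, length(axes$pump), length(axes$probe))
  for (nm in names(weights)) {
    if (weights[[nm]] == 0) next
    amp <- amp + weights[[nm]] *
      render_component(library[[nm]], axes$pump, axes$probe,
                       oversample = oversample)$amplitude
  }
  if (noise_sd > 0)
    amp <- amp + matrix(stats::rnorm(length(amp), sd = noise_sd),
                        nrow(amp), ncol(amp))
  spectrum2d(axes$pump, axes$probe, amp, meta = meta)
}

#' Robust noise-floor estimate from a signal-free corner of the grid
#'
#' Median absolute deviation (scaled to SD) of the low-frequency corner of
#' the amplitude grid, where no amide-I band has mass.
#'
#' @param s A \code{Spectrum2D}.
#' @param n Corner block size in grid points.
#' @return Non-negative scalar noise SD estimate.
#' @export
noise_floor <- function(s, n = 6L) {
  block <- s$amplitude[seq_len(min(n, nrow(s$amplitude))),
                       seq_len(min(n, ncol(s$amplitude)))]
  stats::mad(as.numeric(block), center = 0)
}
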