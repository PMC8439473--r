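# Raw pump-delay (time-domain) emission and the matching preprocessing
# chain: phase-cycling combination, pump-axis Fourier transform, probe-axis
# calibration.

#' Emit synthetic raw pump-delay data for a 2D spectrum
#'
#' Inverts the pump-axis Fourier transform: for each probe pixel the pump
#' frequency content becomes a cosine series over the pump delay, emitted as
#' four phase-cycling frames per delay whose fixed linear combination
#' (\code{(+f1 - f2 - f3 + f4) / 4}) recovers the signal and cancels any
#' common-mode background.
#'
#' With the default \code{delay_step} the delay grid is chosen so every pump
#' axis frequency falls exactly on a Fourier bin, making the round trip
#' through \code{\link{transform_pump_axis}} exact to machine precision.
#'
#' @param s A \code{Spectrum2D} whose pump axis is uniformly spaced.
#' @param n_delays Number of pump delays (power of two recommended).
#' @param delay_step Delay spacing in fs; \code{NULL} picks the exact-bin
#'   value \code{1 / (n_delays * pump_spacing * c)}.
#' @param background Common-mode background level added to every frame.
#' @return List of class \code{RawPixelRecord}: \code{delays} (fs),
#'   \code{frames} (array \code{[n_delays, 4, n_probe]}),
#'   \code{probe_axis}, \code{pump_axis} (the source axis, for round trips).
#' @export
emit_time_domain <- function(s, n_delays = 2048L, delay_step = NULL,
                             background = 0) {
  dnu <- diff(s$pump_axis)
  if (max(abs(dnu - dnu[1])) > 1e-9) stop("pump axis must be uniform")
  spacing <- dnu[1]
  n_delays <- as.integer(n_delays)
  if (is.null(delay_step))
    delay_step <- 1 / (n_delays * spacing * C_CM_PER_FS)
  # resolution: delay span must resolve the pump spacing
  if (n_delays * delay_step * C_CM_PER_FS < 1 / spacing)
    stop("delay grid too short to resolve the pump axis spacing")
  # Nyquist: the maximum pump frequency must be below 1/(2*dt*c)
  if (max(s$pump_axis) >= 1 / (2 * delay_step * C_CM_PER_FS))
    stop("delay grid too coarse: maximum pump frequency would alias")
  delays <- (seq_len(n_delays) - 1L) * delay_step
  # [n_delays x n_pump] cosine kernel times [n_pump x n_probe] amplitudes
  phase <- 2 * pi * C_CM_PER_FS * outer(delays, s$pump_axis)
  signal <- cos(phase) %*% s$amplitude
  frames <- array(0, dim = c(n_delays, 4L, length(s$probe_axis)))
  eps <- c(1, -1, -1, 1)
  for (k in 1:4) frames[, k, ] <- background + eps[k] * signal
  structure(list(delays = delays, frames = frames,
                 probe_axis = s$probe_axis, pump_axis = s$pump_axis),
            class = "RawPixelRecord")
}

#' Combine four phase-cycling frames into a background-free signal
#'
#' Applies the fixed four-frame combination \code{(+f1 - f2 - f3 + f4) / 4},
#' which is linear in each frame and rejects any signal common to all four
#' frames (scatter, probe background).
#'
#' @param frames Array \code{[n_delays, 4, n_probe]}, matrix
#'   \code{[n_delays, 4]}, or length-4 vector.
#' @return Combined signal with the frame dimension removed.
#' @export
combine_phase_frames <- function(frames) {
  w <- PHASE_CYCLE_WEIGHTS
  if (is.vector(frames)) {
    if (length(frames) != 4L) stop("exactly 4 phase frames are required")
    return(sum(w * frames))
  }
  d <- dim(frames)
  if (length(d) == 2L) {
    if (d[2] != 4L) stop("exactly 4 phase frames are required")
    return(as.numeric(frames %*% w))
  }
  if (length(d) == 3L) {
    if (d[2] != 4L) stop("exactly 4 phase frames are required")
    out <- w[1] * frames[, 1, ] + w[2] * frames[, 2, ] +
      w[3] * frames[, 3, ] + w[4] * frames[, 4, ]
    return(out)
  }
  stop("frames must be a vector, matrix or 3D array with 4 frames")
}

#' Fourier transform pump delays into the pump frequency axis
#'
#' Combines the phase-cycling frames, optionally applies a Hann window and
#' zero-padding, and returns the real part of the discrete Fourier transform
#' over pump delay as a function of pump frequency.
#'
#' @param record A \code{RawPixelRecord} (or list with \code{delays} and
#'   either \code{frames} or a combined \code{signal} matrix
#'   \code{[n_delays, n_probe]}).
#' @param window \code{"none"} or \code{"hann"}.
#' @param zero_pad Integer padding factor (1 = none).
#' @return List: \code{pump_axis} (cm^-1, non-negative half),
#'   \code{amplitude} matrix \code{[n_pump, n_probe]}.
#' @export
transform_pump_axis <- function(record, window = c("none", "hann"),
                                zero_pad = 1L) {
  window <- match.arg(window)
  delays <- record$delays
  dt <- diff(delays)
  if (length(dt) == 0 || max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("pump delays must be uniformly spaced")
  signal <- if (!is.null(record$frames)) combine_phase_frames(record$frames)
            else record$signal
  signal <- as.matrix(signal)
  n <- nrow(signal)
  w <- switch(window,
              none = rep(1, n),
              # periodic Hann; amplitude rescaled by its coherent gain
              hann = 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n))
  gain <- mean(w)
  sw <- signal * w
  n_fft <- as.integer(zero_pad) * n
  if (n_fft > n) sw <- rbind(sw, matrix(0, n_fft - n, ncol(sw)))
  ft <- stats::mvfft(sw)
  n_half <- floor(n_fft / 2) + 1L
  amp <- Re(ft[seq_len(n_half), , drop = FALSE]) * (2 / (n * gain))
  amp[1, ] <- amp[1, ] / 2  # DC bin is not doubled
  freq <- (seq_len(n_half) - 1L) / (n_fft * dt[1] * C_CM_PER_FS)
  list(pump_axis = freq, amplitude = amp)
}

#' Reconstruct a 2D spectrum from raw pump-delay data
#'
#' Runs \code{\link{transform_pump_axis}} and samples the result at the
#' requested pump axis (nearest Fourier bin), restoring a
#' \code{Spectrum2D}. Windowing is off by default so that the
#' \code{\link{emit_time_domain}} round trip is exact.
#'
#' @param record A \code{RawPixelRecord}.
#' @param pump_axis Target pump axis; defaults to the record's source axis.
#' @param window,zero_pad Passed to \code{\link{transform_pump_axis}}.
#' @return A \code{Spectrum2D}.
#' @export
reconstruct_spectrum <- function(record, pump_axis = record$pump_axis,
                                 window = "none", zero_pad = 1L) {
  ft <- transform_pump_axis(record, window = window, zero_pad = zero_pad)
  bins <- vapply(pump_axis, function(f) which.min(abs(ft$pump_axis - f)), 1L)
  spectrum2d(pump_axis, record$probe_axis,
             ft$amplitude[bins, , drop = FALSE])
}

#' Calibrate the probe axis against known water absorption lines
#'
#' Least-squares affine fit of detector pixel index to frequency using
#' reference water lines; the fitted mapping must be strictly monotone over
#' the detector.
#'
#' @param lines Data frame or matrix with columns \code{pixel} (0-based
#'   detector element index) and \code{freq} (known frequency, cm^-1); at
#'   least two lines.
#' @return Object of class \code{ProbeCalibration}: \code{intercept},
#'   \code{slope} (cm^-1 per pixel), \code{residuals} (cm^-1),
#'   \code{lines}.
#' @export
calibrate_probe_axis <- function(lines) {
  lines <- as.data.frame(lines)
  if (!all(c("pixel", "freq") %in% names(lines)))
    names(lines)[1:2] <- c("pixel", "freq")
  if (nrow(lines) < 2L) stop("at least 2 reference lines are required")
  fit <- stats::lm(freq ~ pixel, data = lines)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration fit is not strictly monotone increasing")
  structure(list(intercept = unname(stats::coef(fit)[1]), slope = slope,
                 residuals = unname(stats::residuals(fit)), lines = lines),
            class = "ProbeCalibration")
}

#' Evaluate a probe calibration on detector pixels
#'
#' @param cal A \code{ProbeCalibration}.
#' @param pixels 0-based detector element indices (default the 64-element
#'   array).
#' @return Frequencies in cm^-1.
#' @export
probe_axis_from <- function(cal, pixels = 0:63) {
  cal$intercept + cal$slope * pixels
}
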