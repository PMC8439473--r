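# Shared fixtures, built in code at test time.

fx_axes <- default_axes()

fx_lib <- function(environment = "ffpe", host = "mouse")
  component_library(environment, host)

# noiseless FFPE mouse mixture with the given amyloid fraction
fx_mixture <- function(f, lib = fx_lib(), helix = 0, noise_sd = 0,
                       oversample = 5L) {
  w <- c(native_beta = 1 - helix - f, amyloid_beta = f, helix_coil = helix)
  compose_spectrum(w, lib, fx_axes, noise_sd = noise_sd,
                   oversample = oversample)
}

# independent evaluation of the stated lineshape: rotated-frame Gaussian
# fundamental/overtone pair plus optional cross-peak pair. Deliberately
# written long-hand (scalar loops) as the oracle for render_component.
fx_component_oracle <- function(cmp, wp, wr) {
  g <- function(x, y, cx, cy, sd_, sa) {
    d <- ((x - cx) + (y - cy)) / sqrt(2)
    a <- ((y - cy) - (x - cx)) / sqrt(2)
    exp(-d^2 / (2 * sd_^2) - a^2 / (2 * sa^2))
  }
  A <- cmp$mu^4
  out <- matrix(0, length(wp), length(wr))
  for (i in seq_along(wp)) for (j in seq_along(wr)) {
    v <- A * (g(wp[i], wr[j], cmp$omega0, cmp$omega0,
                cmp$sigma_diag, cmp$sigma_antidiag) -
              g(wp[i], wr[j], cmp$omega0, cmp$omega0 - cmp$delta,
                cmp$sigma_diag, cmp$sigma_antidiag))
    if (!is.null(cmp$crosspeak)) {
      sp <- sqrt((cmp$sigma_diag^2 + cmp$sigma_antidiag^2) / 2)
      sr <- cmp$sigma_antidiag
      xg <- function(cy) exp(-(wp[i] - cmp$crosspeak$nu_pump)^2 / (2 * sp^2) -
                               (wr[j] - cy)^2 / (2 * sr^2))
      v <- v + A * cmp$crosspeak$amplitude_ratio *
        (xg(cmp$crosspeak$nu_perp) - xg(cmp$crosspeak$nu_perp - cmp$delta))
    }
    out[i, j] <- v
  }
  out
}

# naive O(N^2) real-part DFT oracle: amplitude of cosine content
fx_dft_oracle <- function(signal, delays) {
  n <- length(signal)
  dt <- delays[2] - delays[1]
  n_half <- floor(n / 2) + 1L
  freq <- (seq_len(n_half) - 1L) / (n * dt * lens2dir:::C_CM_PER_FS)
  amp <- vapply(seq_len(n_half), function(k) {
    s <- 0
    for (j in seq_len(n))
      s <- s + signal[j] * cos(2 * pi * (k - 1) * (j - 1) / n)
    s * 2 / n
  }, numeric(1))
  amp[1] <- amp[1] / 2
  list(pump_axis = freq, amplitude = amp)
}
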