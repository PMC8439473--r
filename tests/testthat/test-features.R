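# Diagonal slices, ratios, peak frequencies, cross peaks, anharmonicity.

test_that("diagonal slice picks the diagonal and fixes the sign", {
  s <- fx_mixture(0)
  d <- diagonal_slice(s)
  expect_lt(abs(d$freq[which.max(d$intensity)] - 1641), 2.6)
  z <- spectrum2d(fx_axes$pump, fx_axes$probe,
                  matrix(0, length(fx_axes$pump), length(fx_axes$probe)))
  expect_true(all(diagonal_slice(z)$intensity == 0))
  # flipped instrument convention: measurements unchanged
  neg <- s; neg$amplitude <- -neg$amplitude
  dn <- diagonal_slice(neg)
  expect_true(dn$sign_flipped)
  expect_equal(dn$intensity, d$intensity)
  expect_error(diagonal_slice(spectrum2d(seq(1580, 1590, 2.5),
                                         seq(1700, 1710, 2.5),
                                         matrix(0, 5, 5))), "overlap")
})

test_that("isotropic Gaussian slices to the analytic diagonal profile", {
  sg <- 6
  amp <- outer(fx_axes$pump, fx_axes$probe, function(p, r)
    exp(-((p - 1636)^2 + (r - 1636)^2) / (2 * sg^2)))
  d <- diagonal_slice(spectrum2d(fx_axes$pump, fx_axes$probe, amp))
  expect_equal(d$intensity, exp(-(d$freq - 1636)^2 / sg^2),
               tolerance = 1e-12)
})

test_that("normalization pins the class frequency to 1 and is idempotent", {
  d <- diagonal_slice(fx_mixture(0.1))
  n1 <- normalize_slice(d, "tissue_FFPE")
  i <- which.min(abs(n1$freq - 1641))
  expect_equal(n1$intensity[i], 1)
  expect_true(n1$normalized)
  n2 <- normalize_slice(n1, "tissue_FFPE")
  expect_equal(n2$intensity, n1$intensity, tolerance = 1e-12)
  # scale invariance of the normalized result
  dk <- d; dk$intensity <- 7.3 * d$intensity
  expect_equal(normalize_slice(dk, "tissue_FFPE")$intensity, n1$intensity,
               tolerance = 1e-12)
  # class table
  expect_equal(normalization_frequency("tissue_FFPE"), 1641)
  expect_equal(normalization_frequency("protein_aB"), 1639)
  expect_equal(normalization_frequency("protein_R120G"), 1632)
  expect_equal(normalization_frequency("tissue_frozen"), 1632)
  expect_error(normalization_frequency("plasma"), "valid classes")
  # QC floor flags instead of dividing by junk
  weak <- d; weak$intensity <- d$intensity * 1e-9
  expect_true(attr(normalize_slice(weak, "tissue_FFPE", qc_floor = 1e-6),
                   "qc_fail"))
})

test_that("diagonal ratio matches analytic evaluation for pure native", {
  lib <- fx_lib()
  s <- compose_spectrum(c(native_beta = 1), lib, fx_axes, oversample = 1L)
  d <- normalize_slice(diagonal_slice(s), "tissue_FFPE")
  r <- diagonal_ratio(d)
  # oracle: lineshape evaluated at the same nearest-grid diagonal points
  f_num <- fx_axes$probe[which.min(abs(fx_axes$probe - 1636))]
  f_den <- fx_axes$probe[which.min(abs(fx_axes$probe - 1641))]
  o <- fx_component_oracle(lib$native_beta, c(f_num, f_den),
                           c(f_num, f_den))
  expect_equal(r, o[1, 1] / o[2, 2], tolerance = 1e-9)
  # flat slice gives ratio 1
  flat <- structure(list(freq = fx_axes$probe,
                         intensity = rep(2, length(fx_axes$probe)),
                         norm_freq = NA, normalized = FALSE),
                    class = "DiagonalSlice")
  expect_equal(diagonal_ratio(flat), 1)
  expect_error(diagonal_ratio(d, f_num = 1500), "within the slice")
})

test_that("diagonal ratio is strictly increasing in amyloid weight", {
  ratios <- vapply(seq(0, 0.5, by = 0.1), function(w) {
    s <- fx_mixture(w)
    diagonal_ratio(normalize_slice(diagonal_slice(s), "tissue_FFPE"))
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("peak frequency: impulse exact, mixture matches dense search", {
  freq <- seq(1600, 1660, by = 2)
  y <- rep(0, length(freq)); y[freq == 1626] <- 1
  d <- structure(list(freq = freq, intensity = y), class = "DiagonalSlice")
  expect_equal(as.numeric(peak_frequency(d)), 1626)
  # two overlapping Gaussians: oracle is a 0.01 cm-1 grid search
  f2 <- function(x) 0.7 * exp(-(x - 1641)^2 / 72) +
    0.3 * exp(-(x - 1636)^2 / 72)
  grid <- fx_axes$probe
  d2 <- structure(list(freq = grid, intensity = f2(grid)),
                  class = "DiagonalSlice")
  dense <- seq(1600, 1660, by = 0.01)
  expect_lt(abs(as.numeric(peak_frequency(d2)) -
                  dense[which.max(f2(dense))]), 0.2)
  # band-edge maxima are flagged
  expect_true(attr(peak_frequency(d2, band = c(1600, 1630)), "edge"))
})

test_that("room-temperature protein presets peak at the printed values", {
  mk <- function(host, f) {
    lib <- fx_lib("ffpe", host)
    compose_spectrum(c(native_beta = 0.9 - f, amyloid_beta = f,
                       helix_coil = 0.1), lib, fx_axes, oversample = 5L)
  }
  p_ab <- peak_frequency(diagonal_slice(mk("protein_aB", 0.01)))
  p_mut <- peak_frequency(diagonal_slice(mk("protein_R120G", 0.03)))
  expect_lt(abs(p_ab - 1639), 2.5)
  expect_lt(abs(p_mut - 1633), 2.5)
})

test_that("cross-peak baseline subtraction recovers constructed heights", {
  np <- length(fx_axes$pump); nr <- length(fx_axes$probe)
  ramp <- 0.3 + 0.002 * fx_axes$pump
  s_lin <- spectrum2d(fx_axes$pump, fx_axes$probe,
                      matrix(ramp, np, nr))
  m0 <- crosspeak_measure(s_lin, probe_freq = 1700, pump_freq = 1650)
  expect_lt(abs(m0$intensity), 1e-12)
  # Gaussian bump of height h on the ramp; flanks clear of the tails
  h <- 0.42
  bump <- h * exp(-(fx_axes$pump - 1650)^2 / (2 * 25))
  s_b <- spectrum2d(fx_axes$pump, fx_axes$probe,
                    matrix(ramp + bump, np, nr))
  m1 <- crosspeak_measure(s_b, probe_freq = 1700, pump_freq = 1650,
                          flank_windows = list(c(1605, 1620),
                                               c(1680, 1695)))
  expect_equal(m1$intensity, h, tolerance = 1e-6)
  expect_lt(abs(m1$max_coords[["pump"]] - 1650), 2.5)
  # flank windows that touch the peak window are rejected
  expect_error(crosspeak_measure(s_b, 1700, 1650,
                                 flank_windows = list(c(1645, 1655),
                                                      c(1680, 1695))),
               "exclude")
})

test_that("mutant pixels show larger cross-peak intensity than WT", {
  wt <- fx_mixture(0.01)
  mut <- fx_mixture(0.025)
  get <- function(s) pixel_features(s, "tissue_FFPE", 1701,
                                    1632)$xpeak_intensity
  expect_gt(get(mut), get(wt))
})

test_that("cross-peak intensity is linear in the amplitude ratio", {
  mk <- function(a) {
    cmp <- spectral_component("x", 1636, 10, 8, 3, 1,
                              crosspeak = list(nu_pump = 1632,
                                               nu_perp = 1701,
                                               amplitude_ratio = a))
    s <- render_component(cmp, fx_axes$pump, fx_axes$probe)
    crosspeak_measure(s, 1701, 1632)$intensity
  }
  v <- vapply(c(0.05, 0.1, 0.2), mk, numeric(1))
  expect_equal(v[2] / v[1], 2, tolerance = 1e-9)
  expect_equal(v[3] / v[1], 4, tolerance = 1e-9)
})

test_that("cross peaks are located at the printed coordinates", {
  mouse <- fx_mixture(0.025)
  loc_m <- crosspeak_locate(mouse)
  expect_true(loc_m$detected)
  expect_lt(abs(loc_m$pump - 1632), 2.5)
  expect_lt(abs(loc_m$probe - 1701), 2.5)
  human <- compose_spectrum(c(native_beta = 0.76, amyloid_beta = 0.04,
                              helix_coil = 0.2), fx_lib("ffpe", "human"),
                            fx_axes, oversample = 5L)
  loc_h <- crosspeak_locate(human)
  expect_true(loc_h$detected)
  expect_lt(abs(loc_h$pump - 1632), 2.5)
  expect_lt(abs(loc_h$probe - 1695), 2.5)
  helix <- compose_spectrum(c(helix_coil = 1), fx_lib(), fx_axes,
                            oversample = 5L)
  expect_false(crosspeak_locate(helix)$detected)
})

test_that("anharmonic shift recovers the generator anharmonicity", {
  native <- compose_spectrum(c(native_beta = 1), fx_lib(), fx_axes,
                             oversample = 5L)
  an <- anharmonicity(native)
  expect_false(an$flagged)
  expect_lt(abs(an$shift - 14), 1.25)
  # positive-only spectrum is flagged
  pos <- spectrum2d(fx_axes$pump, fx_axes$probe,
                    outer(fx_axes$pump, fx_axes$probe, function(p, r)
                      exp(-((p - 1641)^2 + (r - 1641)^2) / 72)))
  expect_true(anharmonicity(pos)$flagged)
})

test_that("overlapping-component shift matches a dense analytic search", {
  lib <- fx_lib()
  s <- fx_mixture(0.5, oversample = 1L)
  an <- anharmonicity(s)
  # analytic probe profile at the measured pump frequency
  wr <- seq(1580, 1737.5, by = 0.01)
  prof <- 0.5 * fx_component_oracle(lib$native_beta, an$pump_freq, wr) +
          0.5 * fx_component_oracle(lib$amyloid_beta, an$pump_freq, wr)
  prof <- as.numeric(prof)
  jpos <- which.max(prof)
  below <- which(wr < wr[jpos])
  jneg <- below[which.min(prof[below])]
  expect_lt(abs(an$shift - (wr[jpos] - wr[jneg])), 0.3)
})

test_that("mutant preset shows smaller median anharmonicity than WT", {
  wt <- simulate_cube("wt_mouse", 12, 12, noise_sd = 0, seed = 4)
  mut <- simulate_cube("r120g_mouse", 12, 12, noise_sd = 0, seed = 4)
  med <- function(cube) {
    m <- build_feature_map(cube, "anharm")
    stats::median(m$values[m$qc_mask])
  }
  expect_lt(med(mut), med(wt))
})

test_that("all features are invariant to positive rescaling", {
  s <- fx_mixture(0.1)
  for (k in c(0.01, 3, 250)) {
    sk <- s; sk$amplitude <- k * s$amplitude
    a <- pixel_features(s, "tissue_FFPE", 1701, 1632)
    b <- pixel_features(sk, "tissue_FFPE", 1701, 1632)
    expect_equal(b$diag_ratio, a$diag_ratio, tolerance = 1e-9)
    expect_equal(b$xpeak_intensity, a$xpeak_intensity, tolerance = 1e-9)
    expect_equal(b$peak_freq, a$peak_freq)
    expect_equal(b$anharm, a$anharm, tolerance = 1e-9)
  }
})

test_that("peak frequency and ratio are unbiased under default noise", {
  # full-precision references: the 0.1 cm-1 reporting rounding would
  # otherwise inject a constant offset into every error
  get <- function(noise_sd = 0) {
    s <- fx_mixture(0.02, noise_sd = noise_sd)
    d <- normalize_slice(diagonal_slice(s), "tissue_FFPE")
    c(as.numeric(peak_frequency(d, digits = 10)), diagonal_ratio(d))
  }
  ref <- get()
  set.seed(20260910)
  n <- 200
  est <- vapply(seq_len(n), function(i) get(noise_sd = 0.005), numeric(2))
  for (k in 1:2) {
    err <- est[k, ] - ref[k]
    expect_lt(abs(mean(err)), 2 * stats::sd(err) / sqrt(n))
  }
})
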