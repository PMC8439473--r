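# Component library and 2D spectrum rendering.

test_that("component library reproduces the printed tissue frequencies", {
  frozen <- fx_lib("frozen")
  ffpe <- fx_lib("ffpe")
  expect_equal(frozen$native_beta$omega0, 1632)
  expect_equal(frozen$amyloid_beta$omega0, 1621)
  expect_equal(ffpe$native_beta$omega0, 1641)
  expect_equal(ffpe$amyloid_beta$omega0, 1636)
  # native/amyloid separation narrows from 11 to 5 cm-1 with fixation
  expect_equal(frozen$native_beta$omega0 - frozen$amyloid_beta$omega0, 11)
  expect_equal(ffpe$native_beta$omega0 - ffpe$amyloid_beta$omega0, 5)
  # room-temperature crystallin native bands
  expect_equal(fx_lib(host = "protein_aB")$native_beta$omega0, 1639)
  expect_equal(fx_lib(host = "protein_R120G")$native_beta$omega0, 1633)
})

test_that("library invariants hold across every environment and host", {
  for (env in c("frozen", "dried", "ffpe")) {
    for (host in c("mouse", "human", "protein_aB", "protein_R120G")) {
      lib <- fx_lib(env, host)
      expect_length(lib, 3)
      for (cmp in lib) {
        expect_gt(cmp$delta, 0)
        expect_gte(cmp$sigma_diag, cmp$sigma_antidiag)
        expect_gt(cmp$sigma_antidiag, 0)
        expect_gt(cmp$mu, 0)
        if (!is.null(cmp$crosspeak))
          expect_gt(cmp$crosspeak$nu_perp, cmp$omega0)
      }
      expect_gt(lib$amyloid_beta$mu, lib$native_beta$mu)
      expect_lt(lib$amyloid_beta$sigma_antidiag,
                lib$helix_coil$sigma_antidiag)
      expect_lt(lib$amyloid_beta$delta, lib$native_beta$delta)
      # cross peaks only on the beta-sheet components
      expect_null(lib$helix_coil$crosspeak)
      expect_false(is.null(lib$native_beta$crosspeak))
      expect_false(is.null(lib$amyloid_beta$crosspeak))
    }
    expect_gt(fx_lib("ffpe")$native_beta$omega0,
              fx_lib("frozen")$native_beta$omega0)
  }
  expect_equal(fx_lib("ffpe", "mouse")$amyloid_beta$crosspeak$nu_perp, 1701)
  expect_equal(fx_lib("ffpe", "human")$amyloid_beta$crosspeak$nu_perp, 1695)
})

test_that("unknown presets are rejected with the valid names", {
  expect_error(component_library("vacuum"), "frozen.*dried.*ffpe")
  expect_error(component_library("ffpe", "zebrafish"), "mouse.*human")
  expect_error(simulate_cube("t_rex"), "wt_mouse")
})

test_that("component constructor enforces its invariants", {
  expect_error(spectral_component("x", 1641, delta = -1, 10, 5, 1),
               "delta")
  expect_error(spectral_component("x", 1641, 14, 4, 8, 1), "sigma")
  expect_error(spectral_component("x", 1641, 14, 10, 5, mu = 0), "mu")
  expect_error(
    spectral_component("x", 1641, 14, 10, 5, 1,
                       crosspeak = list(nu_perp = 1600,
                                        amplitude_ratio = 0.1)),
    "nu_perp")
})

test_that("2DIR amplitude scales as the fourth power of the dipole", {
  base <- spectral_component("x", 1641, 14, 10, 5, mu = 1)
  for (k in c(2, 1.5, 3)) {
    scaled <- base
    scaled$mu <- k * base$mu
    r1 <- render_component(base, fx_axes$pump, fx_axes$probe)
    r2 <- render_component(scaled, fx_axes$pump, fx_axes$probe)
    expect_equal(r2$amplitude, k^4 * r1$amplitude, tolerance = 1e-12)
    expect_equal(max(abs(r2$amplitude)) / max(abs(r1$amplitude)), k^4,
                 tolerance = 1e-6)
  }
})

test_that("fundamental is positive, overtone negative", {
  cmp <- spectral_component("x", 1641, 20, 10, 5, 1)
  r <- render_component(cmp, fx_axes$pump, fx_axes$probe)
  i <- which.min(abs(fx_axes$pump - 1641))
  j_fund <- which.min(abs(fx_axes$probe - 1641))
  j_over <- which.min(abs(fx_axes$probe - (1641 - 20)))
  expect_gt(r$amplitude[i, j_fund], 0)
  expect_lt(r$amplitude[i, j_over], 0)
})

test_that("rendering matches independent evaluation of the lineshape", {
  cmp <- spectral_component("x", 1641, 14, sigma_diag = 6,
                            sigma_antidiag = 6, mu = 1.2)
  r <- render_component(cmp, fx_axes$pump, fx_axes$probe)
  expect_equal(r$amplitude,
               fx_component_oracle(cmp, fx_axes$pump, fx_axes$probe),
               tolerance = 1e-12)
  # with a cross peak too
  xcmp <- spectral_component("x", 1636, 10, 8, 3, 1.3,
                             crosspeak = list(nu_pump = 1632,
                                              nu_perp = 1701,
                                              amplitude_ratio = 0.1))
  rx <- render_component(xcmp, fx_axes$pump, fx_axes$probe)
  expect_equal(rx$amplitude,
               fx_component_oracle(xcmp, fx_axes$pump, fx_axes$probe),
               tolerance = 1e-12)
})

test_that("too-narrow axes are rejected", {
  cmp <- spectral_component("x", 1641, 14, 10, 5, 1)
  expect_error(render_component(cmp, seq(1630, 1650, 2.5),
                                seq(1630, 1650, 2.5)), "too narrow")
})

test_that("composition is linear and validates its weights", {
  lib <- fx_lib()
  s_mix <- fx_mixture(0.5, oversample = 1L)
  manual <- 0.5 * render_component(lib$native_beta, fx_axes$pump,
                                   fx_axes$probe)$amplitude +
            0.5 * render_component(lib$amyloid_beta, fx_axes$pump,
                                   fx_axes$probe)$amplitude
  expect_equal(s_mix$amplitude, manual, tolerance = 1e-12)
  expect_error(fx_mixture(-0.1), "non-negative")
  expect_error(compose_spectrum(c(native_beta = 0.5), fx_lib()), "sum to 1")
  expect_error(compose_spectrum(c(nope = 1), fx_lib()), "named")
})

test_that("helix-only spectra have an empty cross-peak region", {
  s <- compose_spectrum(c(helix_coil = 1), fx_lib(), fx_axes)
  sel_p <- abs(s$pump_axis - 1632) <= 3
  sel_r <- abs(s$probe_axis - 1701) <= 3
  expect_lt(max(abs(s$amplitude[sel_p, sel_r])), 1e-9)
})

test_that("amyloid admixture raises the 1636 diagonal amplitude", {
  s0 <- fx_mixture(0)
  s3 <- fx_mixture(0.3)
  i <- which.min(abs(fx_axes$pump - 1636))
  j <- which.min(abs(fx_axes$probe - 1636))
  expect_gt(s3$amplitude[i, j], s0$amplitude[i, j])
})

test_that("noise is reproducible under a fixed seed", {
  set.seed(42); a <- fx_mixture(0.1, noise_sd = 0.01)
  set.seed(42); b <- fx_mixture(0.1, noise_sd = 0.01)
  set.seed(43); c <- fx_mixture(0.1, noise_sd = 0.01)
  expect_identical(a$amplitude, b$amplitude)
  expect_false(identical(a$amplitude, c$amplitude))
})
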