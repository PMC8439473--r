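Package: lens2dir
Title: Two-Dimensional Infrared Imaging Analysis of Amyloid-Like
    Beta-Sheet Structure in Lens Tissue
Version: 0.1.0
Authors@R:
    person("lens2dir", "developers", email = "lens2dir@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of hyperspectral two-dimensional
    infrared (2DIR) amide-I images of eye lens tissue. Provides a
    synthetic-data generator that composes per-pixel 2D spectra from
    secondary-structure component bands (native beta-sheet, amyloid-like
    beta-sheet, alpha-helix/random coil), raw pump-delay emission and the
    matching preprocessing chain (four-frame phase cycling, pump-axis
    Fourier transform, probe-axis calibration against water lines),
    per-pixel feature extraction (diagonal-slice ratios, baseline-subtracted
    cross-peak intensities, peak frequencies, anharmonic shifts), spatial
    feature maps with torn-tissue quality control, group statistics with
    two-tailed t-tests, and calibration-curve estimation of the percent of
    amyloid-like structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
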