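# lens2dir

Analysis of hyperspectral two-dimensional infrared (2DIR) amide-I images
of eye lens tissue, built for detecting and quantifying amyloid-like
beta-sheet secondary structure — the protein misfolding signature
associated with cataract.

Intended users: vibrational spectroscopists and structural-biology groups
working with 2DIR tissue images (or wanting a tested reference
implementation of the standard feature chain), and methods developers who
need a synthetic generator with ground truth to validate against.

## What it computes

Each tissue pixel holds a signed 2D amplitude map over pump and probe
frequency (cm⁻¹): positive fundamental lobes on the diagonal, negative
overtone lobes displaced by the anharmonic shift Δ, and off-diagonal cross
peaks from beta-strand mode coupling. The 2DIR amplitude scales as |μ|⁴ in
the transition dipole, over-weighting delocalized amyloid modes. From each
pixel the package extracts:

- **diagonal ratio** I(1636)/I(1641) on the slice ω_pump = ω_probe,
  normalized at the class frequency (FFPE tissue 1641, frozen tissue 1632,
  αB-crystallin 1639, αB-R120G 1632 cm⁻¹) — the amyloid proxy;
- **cross-peak intensity**: pump-slice height at the target coordinates
  (mutant mouse 1632/1701, human cataract 1632/1695 cm⁻¹) after
  subtracting a least-squares straight-line baseline fitted on flanking
  windows, plus the location of the cross-peak maximum;
- **diagonal peak frequency** (sub-bin refined, reported to 0.1 cm⁻¹) and
  **anharmonic shift** (fundamental-to-overtone separation; smaller for
  amyloid).

Pixels are assembled into feature maps with torn-tissue QC rejection,
percent-of-locations frequency histograms, per-lens means with 95% CIs,
Welch two-tailed t-tests at the 95/99/99.5% confidence levels, and a
monotone calibration curve mapping a feature to percent amyloid-like
structure.

Because no raw lens 2DIR tissue data are publicly deposited, the package
includes a first-class synthetic generator: component bands at the
printed frequencies (frozen 1632/1621, FFPE 1641/1636 cm⁻¹ for
native/amyloid), |μ|⁴ scaling, 2.5 cm⁻¹ probe pixels, lens-shaped masks
with smoothly varying amyloid fraction, torn regions, and optional raw
pump-delay emission (four-frame phase cycling) for round-trip testing of
the preprocessing chain. See `vignettes/lens2dir-methods.Rmd` for the
model, parameter defaults and their rationale, and known limitations.

## Worked example

```r
library(lens2dir)

cube_wt  <- simulate_cube("wt_mouse",    nx = 16, ny = 16, seed = 1)
cube_mut <- simulate_cube("r120g_mouse", nx = 16, ny = 16, seed = 2)

wt  <- summarize_lens(feature_table(cube_wt),  lens_id = "wt_1",  group = "wt")
mut <- summarize_lens(feature_table(cube_mut), lens_id = "mut_1", group = "r120g")
sprintf("WT mean ratio %.4f, mutant %.4f", wt$mean_diag_ratio, mut$mean_diag_ratio)
#> "WT mean ratio 0.7748, mutant 0.7906"

compare_groups(mut$pixels$xpeak_intensity, wt$pixels$xpeak_intensity,
               feature = "xpeak_intensity", group_a = "r120g", group_b = "wt")
#> <GroupComparison xpeak_intensity: r120g vs wt, +7.71%, t=5.598, p=4.977e-08, sig at {95, 99, 99.5}>

curve <- fit_calibration(calibration_standards(0:6))
est <- estimate_percent_amyloid(mut, curve)
sprintf("mutant lens percent amyloid: %.2f%% (95%% CI %.2f-%.2f)",
        est$percent, est$lower, est$upper)
#> "mutant lens percent amyloid: 2.53% (95% CI 2.38-2.69)"
```

The mutant lens was generated with a true mean amyloid fraction of 2.5%;
the calibration-curve estimate recovers 2.53%. The cross-peak intensity
difference (+7.71% for this single pair of small lenses) is significant at
all three levels; the printed group means, t statistic and p-value are the
Welch test on pooled pixels. The simulated mutant cross peak localizes at
the mutant-mouse coordinates:

```r
idx <- which(cube_mut$mask, arr.ind = TRUE)
amp <- Reduce(`+`, lapply(seq_len(nrow(idx)), function(k)
  cube_mut$amplitude[idx[k, 1], idx[k, 2], , ])) / nrow(idx)
crosspeak_locate(spectrum2d(cube_mut$pump_axis, cube_mut$probe_axis, amp))[c("pump", "probe")]
#> $pump  [1] 1631.9
#> $probe [1] 1701
```

An end-to-end run (simulate → features → maps → histograms → stats →
manifest) is:

```r
run_pipeline(list(seed = 1, out_dir = "out"))
```

and a command-line interface wraps the same verbs:

```sh
Rscript inst/cli/lens2dir.R simulate --preset r120g_mouse --seed 1 --out cube.rds
Rscript inst/cli/lens2dir.R features --in cube.rds --out features.tsv
```

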