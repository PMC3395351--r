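# spectvoi

Volumetric quantification of cardiac I-123 MIBG SPECT acquisitions.

Cardiac sympathetic innervation is imaged with I-123
*meta*-iodobenzylguanidine (MIBG), a norepinephrine analogue. Conventional
quantification draws 2D regions of interest on anterior planar images; this
package implements the volumetric alternative: ellipsoidal and box-shaped
volumes of interest (VOIs) defined in physical millimetre coordinates are
rasterized onto the reconstructed SPECT count volume, and decay-corrected
uptake and washout indices are computed from the resulting mean count
densities. It is written for nuclear-medicine physicists and methods
researchers who need a scriptable, testable version of that workflow, plus
the agreement statistics used to evaluate it and a synthetic digital thorax
phantom to validate it end-to-end.

## The indices

With `eH, eM` (`dH, dM`) the early (delayed) mean counts per voxel of a
target and a reference region, and the physical decay factor
`f = 0.5^(Δt/T)` (T = 13.2235 h for I-123):

* **Uptake ratio** (three VOI combinations): heart-to-mediastinum
  `HM = H/M`, myocardial wall-to-mediastinum `MM = W/M`, wall-to-lumen
  `ML = W/L`, where wall counts are heart-VOI counts minus lumen-VOI counts.
* **Washout rate**: `WOR = ((eH − eM) − (dH/f − dM/f)) / (eH − eM)` — the
  fractional loss of specific (background-subtracted) cardiac uptake after
  removing physical decay.
* **Organ washout**: `(eOrgan − dOrgan/f) / eOrgan` for each organ VOI
  (heart, wall, lumen, mediastinum, lung, liver).

Reproducibility of repeated segmentations is summarized by the paired
coefficient of variation `CV = 100·mean|m₁ − m₂| / (√2 · grand mean)`, the
ANOVA intraclass correlation (absolute-agreement ICC(2,1) or consistency
ICC(3,1), with F-based 95% CIs), a one-sample t-test of the absolute
differences, correlation, and forward-stepwise regression.

## Worked example

```r
library(spectvoi)

# a synthetic thorax: 128 x 128 x 64 voxels at 3.3 mm, organ densities on a
# counts/voxel scale, 15 mm PSF, Poisson noise
spec <- phantom_spec(poisson_noise = TRUE, seed = 7)
st   <- generate_study(spec)
vois <- phantom_vois(spec, "clinical")

report <- spect_index_report(st$pair, vois$heart, vois$lumen,
                             vois$mediastinum, vois$lung, vois$liver)
report
#> SPECT index report (decay factor 0.82155)
#> HM: early 1.641, delayed 1.683, WOR -0.113
#> MM: early 1.651, delayed 1.693, WOR -0.112
#> ML: early 1.499, delayed 1.498, WOR -0.069
#> organ washouts:
#>       heart       lumen mediastinum        lung       liver        wall
#>     -0.0710     -0.0722     -0.0443      0.0464     -0.1541     -0.0710
```

The early HM ratio of 1.64 means the heart VOI's mean count density is 1.64
times the mediastinal reference — in the range seen clinically for
moderately reduced innervation. Negative washout values indicate continued
tracer accumulation between the early (0.25 h) and delayed (4 h)
acquisitions after decay correction; the phantom's configured biological
washout fractions (e.g. −0.07 for myocardium, 0 for lung) are recovered up
to blur and noise.

Reproducibility of a re-segmentation (here: seeded 2 mm VOI-centre jitter):

```r
rec <- recovery_experiment(spec, n_replicates = 20, voi_jitter_mm = 2, seed = 11)
subset(rec$agreement, quantity == "heart_early_density")
#>              quantity     mean mean_abs_diff cv_percent   icc
#>   heart_early_density 7.694619    0.00791752 0.07275252 0.927
```

A command-line front end over the same functions ships at
`system.file("cli", "spectvoi", package = "spectvoi")` with subcommands
`quantify`, `planar`, `phantom`, `agreement` and `recovery`.

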