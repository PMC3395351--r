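---
title: "Volumetric MIBG SPECT quantification: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric MIBG SPECT quantification: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectvoi)
```

## The quantification model

Cardiac I-123 MIBG uptake is quantified from paired early/delayed
acquisitions. All indices operate on **mean counts per voxel** (or per pixel
on planar images); because every index is a ratio of densities from the same
acquisition, the unknown calibration between counts and activity cancels, as
does any global scaling of the images.

Five VOIs are used: an ellipsoid containing the entire heart, a second
ellipsoid inside the left-ventricular lumen, and box-shaped VOIs in the
mediastinum, right lung and liver (box sizes conventionally kept between 10
and 15 cm³ — violations warn, never abort). The myocardial wall is not
segmented directly: its counts are heart-VOI counts minus lumen-VOI counts,
which presumes containment; `spect_index_report()` verifies that the lumen
mask is a subset of the heart mask and refuses the subtraction otherwise
rather than silently producing negative wall counts.

Three uptake ratios are formed — heart/mediastinum (HM), wall/mediastinum
(MM), wall/lumen (ML) — at both time points, and a washout rate per
combination:

$$\mathrm{WOR} = \frac{(e_H - e_M) - (d_H/f - d_M/f)}{e_H - e_M},
\qquad f = 0.5^{\Delta t / T},$$

plus a per-organ washout $(e - d/f)/e$. The decay factor $f$ removes
physical decay of I-123 ($T = 13.2235$ h by default, configurable) from the
delayed counts so that washout reflects biology only. WOR is reported as a
raw fraction, may legitimately fall outside $[0, 1]$, and is undefined when
the early specific uptake $e_H - e_M$ vanishes; in batch reports that case
becomes a flagged `NA` rather than an exception, since low-uptake patients
genuinely approach that regime. Whether planar densities are additionally
decay-corrected before forming the HM ratio is immaterial: the factor
cancels in any same-time ratio.

## Rasterization

A voxel belongs to a VOI iff its **centre** satisfies the closed inequality
(`≤`) for the shape — for an ellipsoid with semi-axes $a$ and rotation $R$,
$\lVert \mathrm{diag}(1/a)\, R^\top (c - \mathrm{center}) \rVert^2 \le 1$.
No partial-volume weighting is applied: centre inclusion is deterministic
and can be verified exactly by a brute-force loop over voxel centres, which
the tests do. Surface ties are included (closed boundary) for
reproducibility. A clinical workstation may weight boundary voxels
differently, so counts can differ slightly in the last boundary shell; the
effect shrinks linearly with voxel size, and a 10 mm sphere at 1 mm spacing
is already within 1% of its analytic volume. VOIs extending past the grid
are clipped with a warning. Ellipsoid rotation is supported so VOIs can be
placed in a reoriented cardiac frame without resampling the volume; the
default is the identity.

Coordinates follow one convention throughout: the centre of voxel index
$(i,j,k)$ (0-based) lies at $\mathrm{origin} + (i,j,k)\cdot\mathrm{spacing}$,
and volumes are used in their native axis frame (no automatic short-axis
reorientation). Planar polygons are rasterized by the even-odd rule at pixel
centres, with centres lying exactly on an edge included.

## Agreement statistics

Repeated segmentations (same observer twice, or two observers) are compared
per quantity with:

* **Paired CV** $= 100\cdot\overline{|m_1 - m_2|}\,/\,(\sqrt{2}\,\bar m)$,
  with $\bar m$ the grand mean over all $2n$ values. The $\sqrt 2$ scales
  the difference of two replicates to a single-measurement dispersion. This
  formula reproduces published reproducibility-table CV cells from their
  printed means and mean absolute differences to one decimal across all ten
  count-density cells (`inst/extdata/reference_reproducibility.csv`), which
  is how it was selected; one published VOI-size cell (early mediastinum,
  18.4) is inconsistent with its own printed mean and difference (the
  formula gives 12.9) and looks like a transcription duplicate of the
  corresponding density cell, so size cells are excluded from that check.
* **ICC** from the two-way ANOVA mean squares, single-measure form. Both the
  absolute-agreement ICC(2,1) and the consistency ICC(3,1) are exposed
  because published reports rarely state the variant; ICC(2,1) is the
  default since it penalizes systematic rater shifts, and negative ICCs —
  observed in practice for poorly reproducible box sizes — arise naturally
  from the ANOVA form. 95% CIs follow the McGraw–Wong F-distribution
  constructions (Satterthwaite degrees of freedom for ICC(2,1)). Zero
  between-subject variance is flagged undefined.
* A **one-sample t-test of the absolute differences** against zero, the
  convention used alongside such tables; it measures the magnitude of
  disagreement, not bias, and is essentially always significant when
  replicates differ at all.
* Pearson/Spearman correlation (`stats::cor.test`; exact Spearman p for
  n ≤ 10, t-approximation above) and OLS (`stats::lm`) reported as
  coefficient B, classical se, and model $R^2$.
* **Stepwise regression**: forward entry of the most significant candidate
  at p < 0.05, backward removal at p > 0.10 — common statistical-package
  defaults, both configurable. Entry stops once the fit is numerically
  perfect, where partial p-values lose meaning.

## The digital thorax phantom

`phantom_spec()` emulates reconstructed (not projection-domain) data: organs
are painted by voxel-centre membership with deterministic precedence
(lumen > myocardial shell > liver > lung > background), then an isotropic
Gaussian PSF is applied, then Poisson noise. Defaults, chosen once as the
package's study conditions:

| parameter | default | rationale |
|---|---|---|
| grid | 128×128×64 at 3.3 mm | 128-matrix cardiac SPECT with a ~1.5 zoom; reconstructed voxel sizes of 3–5 mm are typical |
| heart shell | ellipsoids (50,50,45) / (28,28,25) mm | heart VOI volumes around 470–530 mL as reported clinically |
| densities | myocardium 9.3, lumen 5.0, liver 28, lung 12.8, background 4.8 | the regime of published mean count densities (arbitrary counts/voxel scale) |
| biological washout $w$ | myocardium −0.07, lumen −0.07, background −0.04, lung 0, liver −0.16 | back-solved so paired densities sit in the published early/delayed regime at Δt = 3.75 h; negative $w$ = continued accumulation |
| times | 0.25 h / 4.0 h post-injection | conventional early/delayed protocol |
| PSF FWHM | 15 mm | typical Gaussian post-filter of OSEM cardiac reconstructions |

The delayed volume is the early one scaled per organ by
$(1 - w)\,f$: washout and decay compose multiplicatively and decay is
applied to the delayed image only. That makes the generative model exactly
invertible — with blur and noise off, `organ_washout()` returns the
configured $w$ and the ratios return the configured density quotients to
machine precision, which is the phantom's core testable contract
(`phantom_vois(spec, "matched")` aligns the measurement VOIs with the
anatomical boundaries for this purpose).

The Gaussian blur is a separable banded-matrix convolution with zero
padding; it conserves counts to better than 0.1% for objects at least
3 FWHM from the grid boundary (the liver region touches the inferior
boundary, so whole-volume totals are not conserved — only interior objects
are). Blur moves counts from hot to cold regions (spill-out), so measured
HM ratios decrease monotonically with FWHM, and lumen densities are
inflated by wall spill-in, as in real reconstructions.

`phantom_vois(spec, "clinical")` mimics practice: a heart ellipsoid 2 mm
larger than the organ ("contain the entire heart"), a ~10 mL lumen
ellipsoid in the cavity centre, and 23.1 mm boxes (≈12.3 mL after
rasterization) at the organ centres. The mediastinal box is derived from
anatomical landmarks the way the planar methodology prescribes — against
the lung border (14 mm standoff from the lung face, so the box stays
outside lung voxels over a 2 mm re-segmentation jitter) and superior to the
heart base. This placement matters: the mediastinum is the lowest-density
region and sits in the blurred gradient of the adjacent lung, which is what
makes its density the least reproducible quantity under re-segmentation. A
box floating in the middle of a wide uniform region instead measures almost
nothing but Poisson noise and would understate mediastinal variability.

`recovery_experiment()` emulates the reproducibility design: each replicate
is a fresh phantom realization quantified twice with independently jittered
VOI centres (uniform per-axis offsets — the stand-in for manual
re-segmentation; sizes are not varied). By default both segmentations share
the replicate's noise realization, as when one acquisition is segmented
twice; `resample_noise = TRUE` gives each segmentation independent noise
(repeated acquisition), which isolates pure Poisson counting error — under
that mode hot organs show lower density CVs than cold ones, the expected
$1/\sqrt{\text{counts}}$ scaling. Under the default mode with 2 mm jitter
and Poisson noise at 50 replicate pairs, the cardiac ordering of published
test-retest tables is reproduced qualitatively: heart density CV < lumen
density CV < mediastinum density CV. Absolute CV magnitudes are smaller
than published values because translation-only jitter is far gentler than
full manual re-segmentation (published VOI sizes varied by 10–30% between
sessions).

What passing these tests shows — and does not show. The phantom validates
the arithmetic chain (rasterization → count statistics → indices →
agreement statistics) and the qualitative effects of blur, noise and
re-segmentation. It does not model attenuation, scatter, collimator
response, OSEM noise correlations, anatomical variability, or organ motion,
so it cannot certify clinical accuracy — only that the implementation
computes the intended quantities and degrades in the physically expected
direction.

## Numerical choices and degenerate inputs

* Closed boundaries everywhere (ellipsoid, box, rectangle, polygon edge):
  deterministic tie-breaks.
* `washout_rate()` raises on $e_H = e_M$; batch paths convert that to a
  flagged `NA` and a warning.
* Empty masks/ROIs, geometry mismatches, negative/NaN counts, non-subset
  lumen masks, rank-deficient regressions and zero-variance agreement
  tables all fail loudly with diagnostic messages.
* NIfTI volumes are written as float64 (lossless); spacing round-trips
  through the float32 header, i.e. to ~7 significant digits.
* Seeds: every stochastic component (noise, jitter) flows from a single
  integer seed; the ambient RNG state is saved and restored around phantom
  generation.

## Problem sizes used in the shipped validation

The test suite and `scripts/acceptance.R` run the exact-inversion and
Poisson-recovery checks at the full default 128×128×64 grid (100 noise
seeds), the recovery experiment at 50 replicate pairs, rasterization
accuracy on a 10 mm sphere at 1 and 0.5 mm spacing (with a brute-force
voxel-loop oracle at 1 mm), and ICC/regression oracles on small closed-form
examples plus null simulations at n = 200. These sizes were chosen to make
Monte-Carlo standard errors small relative to the tested tolerances.

## Known limitations

* No attenuation/scatter/collimator modelling; the phantom is a
  reconstruction-domain emulator, and the planar projection is a plain
  column sum without depth weighting.
* VOI placement is an input everywhere — there is no automatic heart
  detection, and the landmark logic for the mediastinal VOI is only encoded
  in the phantom defaults, not detected from images.
* The re-segmentation model jitters VOI centres only; real observers also
  change VOI size and orientation, so simulated CVs underestimate clinical
  ones.
* Which ICC variant published tables used is generally unknowable; both
  variants are provided and reported CIs assume the two-way model holds.
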