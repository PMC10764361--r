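---
title: "Quantifying angiogenic sprouts: skeleton morphometry and puncta profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying angiogenic sprouts: skeleton morphometry and puncta profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(sproutmorph)
```

## The measurement problem

Angiogenesis-on-a-chip assays grow endothelial sprouts from a monolayer
edge into a 3-D hydrogel along a growth-factor gradient. Confocal imaging
of such chips yields multi-channel z-stacks in which the biology of
interest is encoded morphologically — how long, wide and branched the
sprouts are — and spatially — where autophagosomes (LC3B-positive puncta)
sit along each sprout. `sproutmorph` turns those images into numbers:

1. a **morphometry panel** per image (sample): sprout area, total skeleton
   length, tip-side endpoint count, average sprout length coefficient,
   average sprout width coefficient, branch-point count;
2. **radial puncta profiles**: summed LC3B signal (or pixel counts) in
   concentric 10 µm distance bins around each sprout's tip endpoint, in
   absolute micrometres or percent of sprout length;
3. the **mCherry/GFP tandem-reporter flux ratio** by sprout region
   (basement vs leading);
4. **group statistics** in the reporting style standard for these assays:
   one-way ANOVA with Tukey's post-hoc over condition panels, unpaired
   two-sided t-tests for two-group designs, mean ± SD summaries.

Because no public raw images accompany this class of chip experiment, the
package ships a seeded synthetic image generator with exact ground truth;
every quantitative claim the test suite makes is made against that truth
or against an independent brute-force oracle.

## The processing model

All analysis happens on maximum-intensity z-projections (`max_project()`),
cropped to a shared region of interest. The growth axis is normalised so
sprouts grow toward +y (image row index increasing); the *root band* is
the strip `y <= root_band_px` adjoining the monolayer.

The segmentation chain is deliberately simple and deterministic:

| step | function | default | why |
|---|---|---|---|
| denoise | `gaussian_denoise()` | σ = 2 px | suppresses shot noise without moving sprout boundaries; separable kernel, reflective (half-sample) boundaries so total intensity is conserved |
| threshold | `binarize()` | pooled Otsu | one threshold for the *whole analysis set*, derived from the pooled intensity histogram, so no per-image adaptivity can create artificial condition differences; a fixed manual threshold is available |
| clean | `remove_small_blobs()` | 200 px | deletes debris and filter speckle below a size that no real sprout cross-section can have at ~1 µm/px |
| label | `label_sprouts()` | 8-connectivity | individual sprout components, flagged root-attached if they touch the root band |

Thresholding is strict (`>`), fixed once per analysis set, which makes
every downstream count bit-reproducible.

## Skeleton morphometry

`skeletonize_mask()` thins the mask to a one-pixel, 8-connected skeleton
(Zhang–Suen thinning with a sequential cleanup pass that removes redundant
staircase pixels; without that pass, shallow diagonal runs carry 2×2 pixel
blocks that masquerade as junctions). On the skeleton:

- **endpoints** are pixels with exactly one skeleton neighbour;
- **junction clusters** are 8-adjacent groups of pixels with ≥ 3
  neighbours, counted once per cluster — the branch-point count;
- **total length** is the skeleton pixel count (a diagonal-corrected
  variant, orthogonal steps 1 and diagonal steps √2, is also reported as
  `length_corrected_px` for users who want geometric length);
- the **median-y endpoint filter** retains endpoints whose y exceeds the
  sample-wide median y strictly. Sprout roots generate many spurious
  endpoints near the monolayer; the filter removes them without any tuned
  threshold. Ties at the median are excluded, and the median of an even
  count is the mean of the two central values. The filter is applied per
  image (per sample); per-sprout profiling then picks, per sprout, the
  retained endpoint with maximal y (ties broken toward smaller x);
- the **average sprout length coefficient** is the mean y of retained
  endpoints, and the **average sprout width coefficient** is mask area
  divided by skeleton length, so `width × length = area` holds exactly by
  construction.

Two properties of this estimator family are worth knowing. First, in 2-D
projections two sprouts crossing in z produce one junction cluster, so
branch points over-count true branching events; this is intrinsic to
projected imaging and is retained as-is. Second, the width coefficient of
a tube with rounded ends exceeds the tube's diameter by ~πr²/L of end-cap
area per unit length; for slender sprouts this is a few percent, for short
wide stubs it can reach tens of percent. The synthetic ground truth
therefore records both the nominal tube width and the analytic width
coefficient of the rendered shape, and accuracy is assessed against the
latter (the quantity the estimator actually targets).

## Puncta profiling

`detect_puncta()` thresholds the LC3B channel (default: background median
+ 5×MAD, a robust rule that needs no tuning), labels 8-connected
components, keeps those within 4–400 px, and assigns each punctum to the
sprout underlying its intensity-weighted centroid. `radial_profile()` bins
every puncta pixel by its Euclidean distance from the tip endpoint into
contiguous bins of 10 µm (the contour interval); the bin value is the
summed pixel intensity or the pixel count. Distances are straight-line,
matching circular iso-distance contours around the tip; profiles can be
re-expressed in percent of the sprout's measured skeleton length with
`to_relative_profile()` (default 5% bins), which conserves total signal
exactly. The line from the endpoint through the puncta centre of gravity
is computed for QC rendering only and plays no quantitative role.
`aggregate_profiles()` pools per-sprout profiles as sums or as mean ± SEM.

A zero-denominator situation (sprout without retained endpoint, GFP signal
of zero in the flux ratio, empty masks) always yields an explicit missing
value or an excluded sprout, never a silent zero.

## The synthetic generator

`sprout_spec()` + `generate_sample()` emulate a cropped chip field:

- sprouts are **stadium tubes**: disks of radius width/2 stamped along a
  bounded-curvature random-walk centreline anchored in the root band. The
  medial axis of that shape is the centreline itself, so the ground-truth
  length is the centreline arc length and skeleton-based length recovery
  is meaningfully testable (5% band). The monolayer sheet itself lies
  above the cropped field, as in ROI-cropped chip images;
- geometry defaults echo the assay's scale: 1 µm/px, lengths 100–600 µm
  (lognormal, mean 300), widths 10–40 µm (lognormal, mean 20), a ~1000 px
  field — fixture choices, not recovered constants;
- **branches** spawn secondary polylines at 30–60° with width × 0.8,
  separated by ≥ 30 px of parent arc so each bifurcation is an
  unambiguous, isolated junction; an exact per-sprout branch count can be
  requested for branch-recovery experiments;
- **puncta** are 2-D Gaussian spots placed at arc distances from the tip
  drawn from Beta(26, 66.91) — mode 0.275 of sprout length, sd ≈ 0.046.
  The concentration was fixed a priori from the distribution itself: with
  23 sprouts averaging ~7 puncta, the modal 5% bin must be statistically
  identifiable from a single sample (probability ≈ 0.99 under perfect
  measurement, by direct Monte-Carlo on the Beta), mirroring the clearly
  dominant 25–30% peak such assays report. A point-mass placement is
  available for exactness tests;
- **noise** is a constant background (20) plus additive Gaussian noise
  (sd 4), with optional Poisson resampling. Optics are deliberately not
  modelled: no PSF, no z-attenuation, no bleed-through;
- **dual-reporter mode** splits each punctum's intensity between GFP and
  mCherry at a per-punctum ratio drawn uniformly from 1.5–3, emulating
  predominately acidified autophagosomes.

Identical spec + seed gives bit-identical images and truth. Holes cannot
occur in rendered tubes (enclosed background components are filled), which
matters because topology-preserving thinning converts any hole into a
skeleton loop and thence into spurious junctions.

What the generator does *not* emulate — uneven illumination, lumen
darkening inside tubes, touching/crossing sprout bundles in z, dead-cell
debris with sprout-like shapes — bounds what passing tests show: they
validate the computational chain against its own definitions on clean
geometry, not the segmentation's robustness on difficult real images.

## Statistics

`compare_groups()` wraps one-way ANOVA (`aov`) with `TukeyHSD` — which
implements the Tukey–Kramer correction under unequal group sizes, the
situation these assays are usually in — and the unpaired two-sided t-test
(equal-variance by default, Welch on request). Stars follow the four-level
convention (0.05/0.01/0.001/0.0001). The four morphology metrics are
reported independently, without cross-metric multiplicity correction,
matching standard practice for these panels; `tidy()` and `glance()`
return the pairwise table and the omnibus row as tibbles.

## Verification at scale, and the problem sizes used

The long-running checks in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` use these study conditions, chosen once:

- geometry recovery: 30 single-tube images, 660×200 px, lengths 100–600 µm,
  widths 10–40 µm, noise-free;
- branch recovery: 30 single-sprout images, 560×360 px, k ∈ {1,2,3} exact
  bifurcations;
- peak recovery: 50 replicates × 23 single-sprout images at 660×240 px
  (unbranched, so the relative-distance denominator is the sprout's own
  main-axis length);
- effect detection: 200 replicates of a two-condition set (control vs 50%
  length-scaled), n = 12 samples per condition, 4 sprouts per 480×300 px
  image — the group size real panels use; the null calibration runs 1000
  three-group ANOVA replicates on pure noise;
- oracle equivalences (endpoint/junction detection, radial binning,
  median filter) run on 50, 100 and 1000 random cases respectively.

## Known limitations

- Morphometry is 2-D by design; volumetric effects (crossings, lumen
  geometry) appear only as their projected artefacts.
- Branch counts over-count crossings (see above).
- The skeleton pixel count under-measures diagonal and curved paths by up
  to ~8%; use `length_corrected_px` where geometric length matters.
- Pooled-Otsu thresholds assume the condition mix does not shift the
  pooled histogram's modes; with extreme effect sizes a fixed threshold
  chosen on controls is preferable.
- Relative profiles divide by the per-sprout skeleton length, so branched
  sprouts shift relative distances downward; profile unbranched sprouts
  or interpret accordingly.
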