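---
title: "Measuring ommatidial lattice disorder: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ommatidial lattice disorder: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ommatidia)
```

## The measurement model

A wild-type *Drosophila* compound eye packs its ommatidia on a triangular
lattice: each interior facet has six equidistant neighbors separated by 60°
angular gaps. `ommatidia` measures departure from that ideal. The pipeline
for one image is:

1. **Detection.** Enhance the image so facets become bright blobs
   (`preprocess_eye()`), threshold with Otsu's method, take local maxima of
   the foreground distance transform as candidates, suppress candidates
   closer than half the estimated lattice spacing, and refine each surviving
   center to sub-pixel precision (`detect_centers()`).
2. **Fans.** For each detected center, find its six nearest neighbors and
   record the six center-to-center vectors, sorted by azimuth
   (`build_neighbor_fans()`).
3. **Scores.** Per fan, odi_d is the summed excess of the five longest vector
   lengths over the shortest, and odi_a the summed excess of the five largest
   angular gaps over the smallest (`score_ommatidium()`). A perfectly
   hexagonal fan scores zero on both.
4. **Stability.** Fans containing any vector longer than
   `stable_factor = 2` times the lattice spacing are flagged unstable;
   this removes rim and isolated detections whose "neighbors" are distant
   interior points (`classify_stable()`).
5. **Aggregation.** Stable ommatidia are ranked by ascending odi; the
   `N_used = min(N, stable count)` most ordered contribute
   `ODI_D`, `ODI_A`, and `ODI = ODI_D + ODI_A`. `Z` counts all detections.
   The phenotypic score is `P = ODI / N_used` (`aggregate_scores()`).

The assumptions are those of the underlying biology and imaging: facets are
roughly circular, brighter than their immediate surround after background
subtraction (bright-field) or dome-shaded with bright crowns (SEM), and
arranged with a single dominant spacing. Images violating these — heavy
occlusion, strong vignetting beyond what illumination flattening removes,
multiple eyes per frame — are out of scope.

## Design decisions where the method was open

Several ingredients of the published score family are described only loosely
in the literature; the package fixes them as follows and isolates each choice
behind one function so it can be swapped.

- **"Angles between the vectors"** is read as the six consecutive azimuthal
  gaps of the angle-sorted fan (which sum to 360° and are 60° each in a
  perfect hexagon). The alternative reading — all 15 pairwise angles — is
  inconsistent with a "five largest plus one smallest" structure.
- **"Stable"** is defined by the 2 × spacing neighbor-length rule above. It
  is cheap, oracle-checkable, and removes exactly the boundary artifacts
  that would otherwise dominate ODI_A (a straight-rim fan contributes ~60°
  of angular excess purely from geometry).
- **The phenotypic score** is `P = ODI / N_used`. Z enters through the cap
  `N_used = min(N, stable count)`: a severely rough eye with few stable
  facets is averaged over what remains, making P comparable across images of
  different sizes. The division lives in one place (`aggregate_scores()`).
- **Units are mixed deliberately**: odi_d is in pixels, odi_a in degrees,
  and odi is their plain sum, following the literal "sum" formulation.
  Consequently ODI and P depend on image scale through the distance
  component (odi_d scales with magnification, odi_a does not); comparisons
  should be made at a single magnification.
- **The `-sem` flag** strictly selects SEM preprocessing
  (difference-of-Gaussians band-pass at σ = r and 3r before the top-hat);
  the `-h` flag applies one global 90° counterclockwise rotation at load so
  a single vertical code path handles both orientations.
- **`-h` vs help**: the horizontal flag keeps the `-h` short form for
  compatibility with the original tool's conventions; help is `--help` only.

## Detection parameters

| parameter | default | units | role |
|---|---|---|---|
| `expected_radius` | auto | px | facet radius; auto-estimated as the median equivalent radius (√(area/π)) of connected components after a provisional Otsu threshold, then one re-run of the chain |
| `min_separation_factor` | 0.5 | — | non-maximum-suppression radius as a fraction of the estimated spacing; pairs closer than this merge |
| `flatten_sigma_factor` | 4 | — | bright-field illumination flattening: the image is divided by its Gaussian blur at σ = 4 × radius; 0 disables |
| `mask_enabled` | TRUE | — | restrict candidates to the convex hull of the largest connected foreground region (drops stray background blobs) |
| `stable_factor` | 2 | × spacing | stability threshold on fan vector lengths |
| `n` | 200 | count | most-ordered stable ommatidia aggregated (the `-n` flag) |

The enhancement chain (flattening → white top-hat with a disk of radius
1.5 × facet radius → Gaussian smoothing at radius/2, rescaled to [0, 1]) was
chosen for being parameter-light and robust to uneven illumination. Sub-pixel
centers come from an iterated Gaussian-weighted centroid (σ = radius/1.5),
run first on the enhanced grid for robustness and then on a *bare top-hat*
measurement grid: flattening and smoothing help thresholding but tilt each
facet's intensity profile slightly, while the plain top-hat keeps profiles
symmetric about their true centers. On noise-free synthetic images this
two-stage refinement localizes centers to ~0.01 px (the test suite asserts
mean error ≤ 1 px and 95th percentile ≤ 1.5 px; the acceptance script reports
the measured value).

## The synthetic generator as ground truth

`eye_spec()` defaults describe a wild-type-like bright-field image: a
480 × 560 px frame, an elliptical eye region with 190 × 240 px semi-axes,
20 px lattice spacing, 6 px facet radius, foreground/background intensities
0.85/0.15, and light pixel noise (σ = 0.01) — about 400 facets, chosen once
as a realistic desk-scale stand-in for a ~750-facet eye at moderate
magnification. Disorder is injected three ways: isotropic Gaussian jitter of
the centers (`jitter_sigma`), Bernoulli facet dropout (`dropout_fraction`),
and additive pixel noise (`noise_sigma`). One integer seed drives a single
RNG stream consumed in a documented order — dropout uniforms, then jitter
normals (x then y per point), then pixel noise — so tests can replay the
draws exactly.

The generator emulates facet packing, rim clipping by the eye outline,
sub-pixel positioning, anti-aliased rendering, the two imaging modalities and
both orientations. It does **not** emulate bristles, lens glints,
necrotic patches, depth-of-field falloff, or correlated (non-white) noise;
passing tests therefore demonstrate correctness of the geometry and the
detection contract under controlled conditions, not robustness to every
artifact of real micrographs. Real-image performance still depends on the
enhancement chain's assumptions listed above.

## Numerical choices and the zero-disorder floor

Scores are computed in double precision with these conventions:

- **Gap computation.** Angular gaps are computed pairwise as
  `atan2(cross, dot)` of consecutive azimuth-sorted vectors rather than by
  subtracting azimuths. The pairwise form is symmetric in its two arguments,
  so geometrically congruent vector pairs produce bit-identical gaps; gaps
  above 180° (rim fans) wrap up by 360°.
- **Ties.** Neighbor selection breaks distance ties by point index; azimuth
  sorting breaks (measure-zero) ties by nearest-first order; aggregation
  breaks equal-odi ties by ommatidium index; equal-response detection maxima
  keep the smaller (y, x) center.
- **Lattice representation.** The generator lays coordinates on a 2⁻³⁶ px
  binary grid: spacing and row pitch are quantized so every lattice
  coordinate, and hence every inter-center offset, is computed exactly in
  double precision. All interior fans of a jitter-free lattice then share
  bit-identical offsets, and nearest-neighbor distances equal the nominal
  spacing exactly. Among grid-representable pitches the generator picks the
  one whose ideal-fan score floor is smallest.
- **The floor is tiny but not exactly zero.** An exactly regular hexagon is
  not representable in binary floating point: it would require dyadic
  rationals with x² + y² = 3 · 4ⁿ, which is impossible (3 divides a² + b²
  only when 3 divides both a and b, forcing 3 | 4ⁿ). Every representable
  "perfect" lattice is therefore genuinely, minutely irregular, and a
  faithful scorer reports a positive floor — here about 1.3 × 10⁻¹² degrees
  of odi_a per fan (ODI_A ≈ 2.6 × 10⁻¹⁰ aggregated over 200 fans, ODI_D
  ≈ 5 × 10⁻¹¹ px). The package reports this floor rather than snapping
  near-equal gaps to equality, so that no genuine sub-micro-degree disorder
  is ever silently discarded.
- **Degenerate inputs.** Images smaller than 64 px on a side are rejected at
  load; a flat field enhances to an all-zero grid (guarded at a 10⁻¹²
  maximum, below which normalization would only amplify FFT residue); fewer
  than 7 detections, or zero stable fans, raise typed errors rather than
  returning scores.

## Problem sizes used by the test and acceptance suites

Chosen as desk-scale defaults: detection fidelity and the jitter response run
on ~215–400-facet synthetic eyes (340 × 380 to 480 × 560 px); the jitter
series uses five jitter levels between 0 and 0.15 × spacing with ten seeds
each; oracle equivalence uses 100 point sets of 20–50 points against a
scalar-loop brute-force reimplementation; the batch contract uses 20 (tests)
or 12 (acceptance script) 512 × 512 px images compared byte-for-byte between
one and four workers.

## Known limitations

- ODI mixes pixels and degrees; cross-magnification comparisons need a fixed
  scale (a dimensionless odi_d/v_min variant was considered and deliberately
  left out to keep the score family literal).
- The detector assumes a single dominant facet scale; eyes with strong
  within-image spacing gradients will bias the single spacing estimate used
  for suppression and stability.
- `Z` counts all detections, stable or not; on images whose rim is heavily
  fragmented, Z can exceed the biological facet count.
- The eye-region mask is a convex hull; strongly concave eye outlines (e.g.
  large necrotic bites) may admit stray rim detections.
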