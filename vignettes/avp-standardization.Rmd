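---
title: "Standardized morphometry of the anterior visual pathway: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardized morphometry of the anterior visual pathway: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avpmorph)
```

## The problem

The anterior visual pathway (aVP) — optic nerve, chiasm and optic tract,
from the retina to the lateral geniculate nucleus — is a thin (5–15 mm²
cross-section), sharply curved tubular structure roughly 45–70 mm long.
Because every subject's pathway bends differently, voxel-wise group
comparisons of segmentation masks are meaningless in native space, and
naive axis-aligned measurements (diameters on a fixed plane, volumes of
oblique slabs) are geometrically biased by the local course of the nerve.

`avpmorph` implements a standardization pipeline for binary segmentation
masks of the five anatomical subdivisions — intraorbital (iOrb),
intracanalicular (iCan) and intracranial (iCran) optic nerve, optic chiasm
hemi-trunk (OC, split at the midsagittal plane), and optic tract (OT) — on
a 0.6 mm isotropic grid:

1. **Straightening.** For every coronal (y-orthogonal) slice of a segment
   mask, the in-plane centroid is computed; consecutive centroids are
   joined by chords of length \(D_i\), and the segment's total length is
   \(TL = \sum_i D_i\). Each slice pattern is translated to the image
   centerline. Because a straightened stack at the original 0.6 mm pitch
   would be shorter than the curved path, the axial dimension is rebuilt at
   a 0.06 mm fine pitch with \(n_i = \mathrm{round}(D_i/0.06)\) sub-slices
   per gap (nearest-source replication), so the straightened length equals
   \(TL\) within 0.03 mm per gap.
2. **Length normalization.** The straightened whole pathway is linearly
   rescaled to a common target length (the cohort mean \(TL\); 61.1 mm in
   the normative adult cohort) and resampled back to the 0.6 mm isotropic
   grid on a fixed cohort-wide field of view, with the origin at the optic
   nerve head.
3. **Probabilistic atlas.** The normalized binary masks (left, plus
   right mirrored to left) are averaged voxel-wise and scaled by 100, so
   each voxel holds the percentage of cohort pathways covering it.
   Generalizability is quantified by leave-one-out Dice similarity
   \(DSI(A,B) = 2|A \cap B| / (|A| + |B|)\) against the left-out atlas
   thresholded at 50%.
4. **Biometry.** Per segment and side: volume (voxel count × voxel
   volume), length (\(TL\)), mean cross-sectional area
   (\(mCSA = V / TL\), the curvature-unbiased spinal-cord-style
   estimate), and the ellipticity index
   \(\varepsilon = (h_1 - h_2)/h_1\) of the equivalent cross-sectional
   ellipse with hemi-axes \(h_1 \ge h_2\) (0 = circle, →1 = flat).

The pipeline's central guarantee — and the property every stage is tested
against — is that the cross-sectional area of every slice survives
straightening and normalization **exactly**: slices are only ever
translated by whole voxels and replicated, never resampled in-plane.

## Conventions and parameters

* **Axes.** x = left–right, y = anterior–posterior with slice index 0 at
  the most anterior nonempty iOrb slice (the nerve head), z =
  inferior–superior. Files are reoriented on load to the NIfTI "RPS"
  orientation when their header carries a usable transform. Voxel indices
  are 0-based; a voxel's world position is its center, at
  index × spacing mm.
* **Chiasm split.** The OC is split into hemi-trunks at a sagittal plane,
  either the grid x-midline (`"auto"`) or any explicit voxel plane; which
  of the two a study should use depends on how well head position was
  standardized at acquisition, so both are supported.
* **Binarization.** Label files often store label integers; any nonzero
  value maps to 1.
* **Fine pitch** 0.06 mm (a tenth of the acquisition spacing), so a
  straight 0.6 mm gap yields exactly ten replicas. `round(D/0.06)` uses
  round-half-away-from-zero, fixed for reproducibility; the minimum is one
  sub-slice per gap.
* **Sub-slice sourcing.** Within a gap, the first half of the sub-slices
  copies the anterior slice and the second half the posterior one; an odd
  middle sub-slice goes to the anterior. Deterministic and symmetric up to
  one slice.
* **Working grid** 64 × 64 in-plane (38.4 mm at 0.6 mm), output grid
  64 × 128 × 64 (76.8 mm axially); both configurable. Patterns that would
  clip at the border are an error, never silently cropped.
* **Rescaling.** The fine stack is length-scaled by
  \(s = \text{target}/\text{current}\) via nearest-neighbour index
  mapping to `round(F * s)` slices — equivalent to cumulative rounding of
  the scaled per-gap distances. Independent per-gap rounding would lose
  the sub-slice fractions (a uniform 0.611 mm scaled gap would still round
  to ten 0.06 mm sub-slices), accumulating more than a voxel of length
  error over a ~100-gap pathway; cumulative mapping guarantees the
  normalized length matches the target within half a fine pitch, and it
  reduces to the identity when \(s = 1\). Shrinking (subjects longer than
  the target) uses the same mapping with slice deletion.
* **Axial aggregation (10 fine → 1 output slice).** An output voxel is set
  iff its occupancy across the group exceeds 0.5 — unbiased for monotone
  boundaries. A group that straddles two source slices exactly evenly
  would make the 0.5 level ambiguous (union if inclusive, intersection if
  exclusive, both distorting the cross-section); such tie voxels follow
  the group's dominant source pattern (anterior on a further tie), so
  every output slice stays a faithful copy of a measured cross-section.
* **Atlas threshold** comparisons are inclusive (≥), making the 50% level
  well defined for even cohort sizes. Dice of two empty operands is 1
  (identical emptiness), of one empty operand 0; segment-restricted
  comparisons can legitimately produce empty masks.
* **Leave-one-out unit.** Both masks of a subject are withheld together;
  a subject's score is the mean of its two Dice indices. Withholding only
  one side would leak the contralateral anatomy into the reference. The
  summary reports the median and the 5th percentile (the similarity
  reached by 95% of subjects).

## Shape measurement on voxel masks

The ellipticity formula needs hemi-axes, but a binary mask has no axes —
only pixels. We use the equivalent ellipse of the in-plane second central
moments: with \(\lambda_1 \ge \lambda_2\) the eigenvalues of the
coordinate covariance of the pixelated region, \(h = 2\sqrt{\lambda}\)
(a filled ellipse with hemi-axes \(a, b\) has coordinate variance
\(a^2/4, b^2/4\)). Moments are rotation-covariant, so the estimate does
not prefer grid-aligned axes the way a caliper or bounding box would. The
covariance includes each pixel's own uniform-square variance
(\(s^2/12\) per axis), i.e. it is the covariance of the union of pixel
squares, not of the lattice of pixel centers: this converges to the
analytic region moments under grid refinement and keeps
\(h_2 > 0\) even for single-pixel-wide (collinear) slices. Slices with
fewer than three voxels are moment-degenerate and are excluded from the
segment mean; a single-voxel slice has \(\varepsilon = 0\) by convention.
Segment ellipticity is the unweighted mean over its slices.

When several connected components appear in one slice (the nerve sheath
may fragment near boundaries), centroid and moments are computed over
their union.

## Compound segments and the fencepost

Optic nerve (ON = iOrb + iCan + iCran) and entire-aVP rows are **exact
sums** of their member segments' volumes and lengths (compound
mCSA = ΣV/ΣL, compound ε the slice-count-weighted mean). Summed lengths
deliberately omit the chord that crosses each segment boundary — about one
slice pitch per junction — which keeps additivity exact and matches how
per-segment lengths are defined. The geometrically faithful length of the
whole pathway, including those chords, is available as
`avp_total_length()` and is what length-recovery validation uses.

The same fencepost appears in volumes after normalization: a segment of
\(n\) slices straightens to \(n-1\) gaps, so up to one 0.6 mm slab of its
cross-section is absorbed at each boundary. Volume biometrics are
therefore taken from the native masks (as in the normative cohort), and
the normalization round-trip is verified to conserve volume within 2%
plus that one-slab quantization per segment.

## The phantom generator

Synthetic cohorts stand in for scan data in every test. A phantom is a
curved tube voxelized on the acquisition grid:

* The **centerline is parameterized by arc length**: transverse offsets
  \(u(s), w(s)\) are natural cubic splines through control points
  (defaults emulate the orbital S-bend and the gentler vertical course),
  and the axial coordinate is
  \(y(s) = \int_0^s \sqrt{1 - u'^2 - w'^2}\,ds\), so the requested total
  length *is* the arc length — no iterative length calibration. Slopes
  steeper than ~0.87 and curvature radii below the tube hemi-axis
  (self-intersection) are rejected.
* **Cross-sections** are ellipses with per-segment hemi-axes derived from
  the requested mCSA (\(\pi h_1 h_2\)) and ellipticity. A coronal cut of a
  tilted tube is the perpendicular ellipse sheared along the drift
  direction (area \(\pi h_1 h_2 / \cos\theta\)); the voxelizer evaluates
  the perpendicular-plane coordinates of the in-plane displacement, so the
  voxelized volume integrates to \(\int \pi h_1 h_2\, ds\) exactly and
  the analytic truth table is exact, not approximate.
* **Voxelization** sets a voxel iff its center lies inside the tube,
  matching the counting-based CSA used throughout. The centerline is
  offset from the voxel lattice by a fixed irrational (golden-ratio)
  sub-voxel fraction: a lattice-aligned circle of radius 2.5 voxels counts
  21 pixels against a true area of 19.6 (+7%), a commensuration resonance
  that no generic alignment exhibits. Validation phantoms for tolerances
  tighter than the 0.6 mm discretization floor (e.g. the 3% cylinder-mCSA
  check) are generated grid-refined at 0.15 mm, where the pixel-count
  error is below 1.3% at any alignment.
* **Defaults are the normative adult conditions**: total length 61.1 mm;
  segment arc-length fractions 36.6 / 11.4 / 25.7 / 10.7 / 15.6%; segment
  mCSA 7.67 / 5.62 / 6.92 / 14.37 / 7.61 mm²; ellipticity 0.15 / 0.20 /
  0.43 / 0.57 / 0.39 (left/right-averaged normative values, see
  `reference_biometry()`). Cohorts draw per-subject parameters around
  these with a configurable fractional variability (default 0.05): total
  length lognormal, profiles jittered multiplicatively, bend control
  points jittered additively, the right side's bend mirrored, all
  reproducible from one integer seed.

What the phantoms deliberately do **not** emulate: manual-segmentation
noise (ragged surfaces, inter-rater disagreement), partial-volume effects
at the mask boundary, fragmented slices, and true chiasmal fiber-crossing
geometry (the OC hemi-trunk is just a wider, flatter tube). Tests passing
on phantoms therefore validate the geometry and bookkeeping of the
pipeline, not the segmentation quality of any real cohort.

## Statistics

Cohort summaries report mean, SD, min/max, t-based 95% CI, median and
quartiles per segment/side/metric, with a Shapiro–Wilk p-value (α = 0.05)
flagging metrics better presented as median/quartiles. Left–right
comparison uses the paired t-test (all-zero differences return t = 0;
constant nonzero differences are an error, the statistic being undefined).
Between-subject coefficients of variation are computed as the plain
sd/mean of left/right-averaged per-subject values — a deliberate
simplification: variance-components (mixed-model) CVs, as used for the
normative cohort's published variability table, are out of scope, so
published mixed-model CVs and "variation from mean" estimates are not
exact reproduction targets for this package. Standardized metrics express
volume and length as percentages of the subject's entire aVP, and mCSA/ε
as percentage deviation from the whole-pathway value. Report tables round
half-away-from-zero to two decimals (`round_report()`).

## Problem sizes used in validation

The bundled validation suite exercises: a 20-subject synthetic cohort
(both sides, ~100 slices each) for the bit-exact CSA-conservation sweep;
phantoms spanning total lengths 45–70 mm for length-normalization checks;
a 6-mask cohort against an exhaustive atlas-counting oracle; an 8-subject
cohort for the leave-one-out ordering check (the LOO Dice median must
strictly exceed the same masks' median against a 3 mm axially shifted
atlas); and a grid-refined 60 mm straight cylinder for the mCSA accuracy
check. These sizes were chosen so each property is measured well away
from its small-sample noise floor while the whole suite stays quick to
run routinely.

## Known limitations

* Ellipticity is measured on coronal cuts after centerline shifts; in
  sharply bent sections the coronal cut overestimates the perpendicular
  ellipticity (the shear factor \(1/\cos\theta\)), an effect shared with
  the underlying measurement protocol.
* Per-segment lengths and post-normalization per-segment volumes carry
  the one-slab boundary quantization described above; short segments
  (iCan, OC) are most affected.
* The atlas is single-sided (left + mirrored right); side asymmetries,
  where present, are averaged away by construction.
* No nonlinear axial warping: each subject is scaled by a single global
  factor, so segment-boundary variability remains visible in the atlas
  (and is itself informative).
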