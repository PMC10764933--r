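# avpmorph

Standardized morphometry of the **anterior visual pathway** (aVP) — optic
nerve, chiasm and optic tract — from high-resolution 3-D binary
segmentation masks (NIfTI, 0.6 mm isotropic).

The aVP is a thin, sharply curved tube: axis-aligned measurements and
native-space voxel averaging are both geometrically biased by each
subject's individual course. `avpmorph` is for neuroimaging researchers
who have per-segment masks (intraorbital **iOrb**, intracanalicular
**iCan**, intracranial **iCran** optic nerve, optic chiasm hemi-trunk
**OC**, optic tract **OT**) and want:

* **geometrically unbiased biometrics** per segment and side — volume,
  centroid-path length *TL = Σ Dᵢ* (sum of 3-D inter-centroid
  distances), mean cross-sectional area *mCSA = V / TL*, and the
  ellipticity index *ε = (h₁ − h₂)/h₁* of the equivalent cross-sectional
  ellipse;
* a **standardized (straightened + length-normalized) representation**:
  every coronal slice is shifted to the image centerline by whole voxels
  (cross-sectional area preserved *exactly*), the axial dimension is
  rebuilt at 0.06 mm pitch so the straightened length equals *TL*, and
  each subject is linearly rescaled to the cohort-mean length and
  resampled to a common isotropic grid with the origin at the nerve head;
* a **probabilistic atlas**: voxel-wise percentage overlap (0–100) of all
  normalized masks, left plus right-mirrored-to-left, with per-segment
  child atlases and leave-one-out Dice (*DSI = 2|A∩B| / (|A|+|B|)*)
  validation;
* a **synthetic phantom generator** (curved elliptical tubes with
  analytic ground truth, defaults at normative adult geometry) so the
  whole pipeline is testable without any scan data.

## Worked example

A fully synthetic 4-subject cohort, end to end:

```r
library(avpmorph)

gc  <- generate_cohort(4, variability = 0.05, seed = 42)
write_cohort(gc$cohort, "demo/cohort")          # NIfTI files + manifest.tsv

cfg <- pipeline_config("demo/cohort/manifest.tsv", "demo/out", seed = 42)
res <- run_pipeline(cfg)

subset(res$biometry, subject_id == "S01" & side == "left")
res$loo
```

```
  segment volume_mm3 length_mm mcsa_mm2 epsilon
     iOrb     197.21    23.198    8.501  0.1719
     iCan      40.61     6.792    5.979  0.2123
    iCran     129.60    16.380    7.912  0.4235
       OC     103.68     6.640   15.614  0.5472
       OT      81.43     9.745    8.356  0.3595
       ON     367.42    46.370    7.924  0.2684
 wholeAVP     552.53    62.755    8.804  0.3142

<loo_validation> 4 subjects @ 50% threshold  median DSI 0.861, 5th pct 0.858
```

Reading the output: this subject's intracanalicular nerve is 6.8 mm long
with a 5.98 mm² mean cross-section and a near-circular section
(ε ≈ 0.21), while the chiasm hemi-trunk is the widest (15.6 mm²) and most
elliptical (ε ≈ 0.55) segment — the expected anatomical pattern. The
compound optic-nerve row (ON) is the exact sum of its three subsegments.
The leave-one-out Dice of ~0.86 means a held-out subject's normalized
pathway overlaps the atlas of the remaining subjects at a level
conventionally regarded as good agreement.

`run_pipeline()` writes everything under the output directory:
straightened fine-pitch volumes with provenance sidecars, normalized
masks with segment-boundary tables, whole-aVP and per-segment atlases,
Dice results, biometry/summary/CV/standardized tables, and a resolved
config snapshot. A thin command-line wrapper with `phantom`,
`straighten` and `run` subcommands is installed at
`inst/cli/avpmorph`.

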