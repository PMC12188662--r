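---
title: "Quantifying aggregate pathology in 3D z-stacks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aggregate pathology in 3D z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxquant)
```

`voxquant` measures misfolded-SOD1 (disSOD1) pathology in multi-channel
confocal z-stacks of midbrain tissue: how much aggregate volume there is,
where it sits (inside dopamine neurons, inside astrocytes, or elsewhere),
how large the astrocyte territory is, how many dopamine neurons remain per
mm³ of the substantia nigra, and — in the spinal cord — how many
ISL-1/ChAT double-positive motor neurons there are per millimetre of cord.
This vignette explains the underlying procedures, the parameters that
matter, what the synthetic phantoms do and do not establish, and the design
choices made where the problem was genuinely open.

## The measurement model

All images live in a fixed `(channel, z, y, x)` axis order with a strictly
positive voxel spacing in micrometres. Volumes are voxel counts times the
voxel volume (the product of the three pitches; 0.5 µm isotropic pitch
gives 0.125 µm³ per voxel). A stack with no calibration — neither embedded
metadata nor an explicit override — is a hard error rather than a silent
1 µm default: every downstream number is a physical volume, and a guessed
pitch would corrupt all of them multiplicatively.

### disSOD1 and its compartments

The disSOD1 channel is thresholded with a per-stack manual threshold
(stain intensity varies between staining runs, so a single global cutoff
is not defensible; the threshold is an input, recorded per stack).
Foreground is intensity ≥ t throughout the package. The thresholded mask
is partitioned voxelwise:

* `in_neuron`: disSOD1 voxels inside the segmented TH-positive mask;
* `in_astro`: inside the astrocyte mask but not the neuron mask;
* `other`: the remainder.

Neurons take priority where the two cell masks overlap (TH/GFAP overlap is
rare but possible); the rule is deterministic and guarantees
`in_neuron + in_astro + other = total` exactly, at voxel precision, which
the suite asserts on randomized mask triples. Compartment volumes can be
re-expressed as percentages of one reference total (by convention the
whole-SN disSOD1 volume of the highest-burden group), so the reference
group's compartments sum to 100%.

### Neuron segmentation: 2.5D stitching

A 2D segmenter — any function from an intensity slice to an integer label
image; the built-in one is threshold-plus-8-connected-components, and a
learned model can be plugged in behind the same contract — labels each
z-slice. Two instances on adjacent slices belong to the same 3D cell when
their masks overlap with intersection-over-union at least `iou_min`
(default 0.25). Linkage is a union-find over *all* adjacent-slice pairs
meeting the threshold, not a best-match assignment: the published rule is
stated as a condition, and the union-find closure is its minimal
deterministic reading. A consequence worth knowing is that one large
cross-section can merge two chains into one cell. There is no linking
across gaps: an object absent from the next slice terminates there.

The stitched volume is then binarized and cleaned — dilate by a radius-1
ball (the 3×3×3 Chebyshev ball, consistent with 26-connectivity), fill
holes, erode, remove components below a physical volume cutoff — and
relabelled by 26-connected components. The cleaned labels are the sole
basis for all counts and volumes (the alternative, accounting volumes on
pre-cleanup voxels, would let counts and volumes disagree about what a
cell is). Cleanup is idempotent up to relabelling on its own output.

On well-separated convex objects whose adjacent cross-sections always meet
the IoU threshold, stitching is provably equivalent to 3D 26-connected
component labelling; the tests construct such objects (cylinders, cuboids,
cones with taper bounded so adjacent-disc IoU ≥ 0.5) and assert exact
equality of instance counts and voxel sets on 20 seeded phantoms. Raising
`iou_min` can only split chains, so the object count is monotone
non-decreasing in it — also asserted.

### Astrocyte volumetry

Astrocyte morphology (branched, overlapping processes) prevents reliable
instance counting, so the GFAP channel is measured as a volume. The
default pipeline is:

1. subtract a flat background of 25 gray levels (clipped at zero);
2. auto-threshold with Yen's maximum-correlation criterion on a 256-bin
   histogram (optionally restricted to an ROI mask, which fully ignores
   outside voxels);
3. smooth the resulting *binary mask* with a Gaussian of `blur_sigma_um`
   (default 0.5 µm) and re-binarize at the half level;
4. remove components below `min_volume_um3` (default 8 µm³ — 64 voxels at
   0.5 µm pitch; there is no published cutoff, so the value is explicit in
   the configuration and logged).

Two choices here deserve justification. First, the smoothing is applied to
the mask, not the intensities. Auto-thresholds for a sparse bright
structure on a dark background land just above the background mode; if the
intensities are blurred *before* thresholding, the entire smoothing halo
around every process clears that low threshold, and on ground-truth
phantoms the measured astrocyte volume inflates roughly two-fold.
Half-level smoothing of the binary mask regularizes ragged edges while
preserving volume to first order; with it, noiseless phantoms recover
astrocyte volume within 15%. The blur-before-threshold sequence remains
available (`smooth = "intensity"`) and the choice is recorded in the
mask's operation trace. Second, "triangular yen" thresholding names two
distinct algorithms (Triangle; Yen); both are implemented, Yen is the
default, and the method used is logged.

A known limitation either way: on realistically noisy, PSF-blurred
renderings the auto-threshold still admits part of the *rendering* halo,
overestimating astrocyte volume by roughly a third. The bias is consistent
across groups, so ratios and fold changes are far more trustworthy than
absolute astrocyte volumes — which is how such measurements are used.

### Stereology and densities

Dopamine neuron counts become densities by dividing by the ROI volume
(cells per mm³; 1 mm³ = 10⁹ µm³). ROI membership of a cell is decided by
its centroid voxel, while disSOD1 volume is attributed to ROIs voxelwise —
volume accounting is voxel-based throughout, object accounting is
centroid-based.

A spinal motor neuron is an ISL-1 nucleus with ChAT signal within
`proximity_um` of it (default 5 µm, the scale of a soma's cytoplasmic rim;
proximity is otherwise a qualitative notion, so the radius is an explicit,
logged parameter). The test is
an exact Euclidean dilation of the ChAT mask; enlarging the radius can
only add cells. Counts normalize to cord length as
`count / (n_sections × thickness / 1000)`: 50 sections of 30 µm represent
1.5 mm. No split-nucleus correction (e.g. Abercrombie) is applied; the
detection operates on per-section maximum-intensity projections. Whether a
nucleus spanning two sections is double-counted is therefore a property of
the sectioning, not corrected post hoc.

### Validation metrics

Predicted and true instances are matched one-to-one greedily by descending
pairwise IoU, eligible at IoU ≥ 0.5 (the de-facto instance-segmentation
standard; the threshold is a parameter). TP/FP/FN then give
F1 = 2·TP/(2·TP+FP+FN). For IoU thresholds above 0.5 the greedy matching
coincides with the exhaustive optimal assignment, which the tests verify
by brute force on small instances. Matching is instance-level, not
pixel-level, consistent with reporting cell counts alongside. Cronbach's
alpha treats raters as the items of the classical reliability design, with
sample (n−1) variances; it is 1 for identical raters and invariant to a
constant offset between raters.

### Cohort statistics

Fold changes are directional ratios of raw group means (x-fold increase
when the comparison exceeds the reference, x-fold decrease otherwise);
whether to compute them on raw or log-transformed means was open, and raw
means are used and logged. Dopamine turnover is (DOPAC + HVA)/dopamine,
scale-invariant in the analytes. Outliers are excluded per group and
metric at Tukey-style far-out fences Q1 − 3·IQR / Q3 + 3·IQR — the strict
reading of an "≥ 3× the interquartile range" rule whose reference point
was left ambiguous — and exclusions are counted in the output.

## The phantom generator

Because the original image data are not publicly deposited, every stage is
validated against synthetic phantoms with exact ground truth. The default
`phantom_spec()` emulates one acquisition: a 40×96×96 voxel stack at
0.5 µm isotropic pitch (a 20 µm-deep field, the depth of the emulated
z-stacks), with 5 TH somata, 3 astrocytes and 40 disSOD1 puncta placed
10% / 30% / 60% within neurons / within astrocytes / elsewhere.

Geometry is the simplest that exercises the pipeline: somata are random
ellipsoids with 5–12 µm diameters, kept ≥ 1.5 µm apart (adjacent somata at
these densities are optically resolvable, and the gap ensures a radius-1
closing cannot weld two instances); astrocytes are a 2.5–4 µm-radius soma
plus dilated random-walk branches spanning 20–40 µm; aggregates are
spheres with radius 0.6 ± 0.2 µm (punctate, ~1 µm diameter); nuclei are
small spheres inside somata. An aggregate's true compartment is decided by
its centroid, and it may overhang the compartment edge — which is exactly
why voxelwise measured fractions differ from truth fractions by a few
points, a gap the recovery tolerances absorb. Channels render as
foreground/background mean intensities (16-bit), optionally PSF-blurred
(Gaussian, 0.25 µm default) and degraded with additive Gaussian noise
(sd 40), clipped to [0, 65535]. Two abutting half-volume ROIs ("SNc" and
the full "SNc+SNr") exercise ROI-restricted reporting.

Cohorts derive per-animal seeds deterministically from a master seed and
scale the expected aggregate count by per-group multipliers, so group mean
true volume scales with the multiplier in expectation. The suite checks
that a programmed 4-fold effect is recovered within 25% from n = 8 per
group — both from truth manifests and through the measurement pipeline.

What passing these tests does *not* show: the phantoms have no depth-
dependent attenuation, no spectral bleed-through, no staining batch
effects, no non-convex somata, and their noise is additive Gaussian rather
than Poisson-dominated. Results on real acquisitions depend on the quality
of the per-stack thresholds and of the plugged-in 2D segmenter; the
phantoms validate the machinery around those inputs, not the inputs
themselves.

## Numerical and engineering choices

* Connectivity is 26-neighbour in 3D and 8-neighbour in 2D everywhere,
  consistent with the radius-1 Chebyshev ball used for morphology; hole
  filling treats background components not touching the volume border as
  holes, under the same connectivity.
* Yen/Triangle thresholds are computed on 256 equal-width bins spanning
  the (masked) intensity range; the returned threshold is the centre of
  the first foreground bin, and a constant image is a degenerate-histogram
  error rather than an arbitrary answer. The Yen implementation was
  checked against an exhaustive criterion search (and, during development,
  against an independent implementation) to within one bin.
* Gaussian blur is separable with per-axis voxel sigmas
  `sigma_um / spacing[axis]`, so anisotropic stacks blur isotropically in
  physical units; edges are replicate-padded and interior-supported signal
  is conserved.
* Greedy instance matching breaks IoU ties by ascending prediction then
  truth id, making reports deterministic.
* Stage outputs of `run_pipeline()` are content-addressed by a hash of
  their parameters and upstream hashes: re-running an unchanged
  configuration skips every stage and two identical seeded runs produce
  byte-identical tables. An optional blinding mode codes stack identities
  at simulation time and un-blinds only in the statistics stage, mirroring
  blinded scoring practice.
* Stacks are stored as channel-major multi-page 16-bit TIFF with a JSON
  sidecar carrying channel names, spacing and provenance; ROI masks as
  0/255 8-bit TIFF; labels as 16-bit TIFF. All tables are plain CSV with a
  schema-version column so cohort merges can reject mixed schemas;
  duplicate stack ids survive a merge but are flagged.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at the default phantom scale (40×96×96 voxels; 16-animal cohorts for
effect-recovery checks; 20 phantoms for the stitching oracle), sizes at
which every check completes in seconds while still exercising thousands of
voxels per object. All generators and the pipeline are seeded; identical
seeds give bit-identical stacks, manifests and result tables.
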