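# voxquant

Voxel-calibrated quantification of protein-aggregate pathology in 3D
immunofluorescence z-stacks, with 2.5D instance stitching and a synthetic
phantom generator for end-to-end validation.

## The problem

Quantifying misfolded-protein pathology in brain tissue asks several
questions of the same multi-channel confocal stack: how much
structurally-disordered SOD1 (disSOD1) signal is there, how much of it sits
inside dopamine neurons (TH channel) versus astrocytes (GFAP channel)
versus elsewhere, how large is the astrocyte territory, and how many
dopamine neurons are present per unit volume of the substantia nigra (SNc,
SNr)? A companion question for the spinal cord is stereological: how many
ISL-1/ChAT double-positive motor neurons per millimetre of cord?

These measurements hinge on image-analysis steps that are easy to get
subtly wrong — stitching 2D per-slice segmentations into 3D cells,
conserving volume when partitioning signal between compartments, and
calibrating voxel counts into µm³. `voxquant` implements the full pipeline
as tested, seeded, reusable functions, and ships a phantom generator with
exact ground-truth manifests so every stage can be validated without any
microscope data.

## Core methods

* **2.5D stitching.** A pluggable 2D segmenter labels each z-slice; masks
  on adjacent slices are merged into one 3D cell when their intersection
  over union satisfies IoU = |A∩B| / |A∪B| ≥ 0.25, with union-find closure
  over all adjacent-slice pairs. The stitched volume is binarized and
  cleaned (dilate, fill holes, erode, remove small objects) and relabelled
  into discrete cells. On well-separated convex objects this provably
  reproduces 3D 26-connected component labelling, which is the oracle the
  test suite checks against.
* **Voxel-calibrated volumetrics.** Every volume is a foreground-voxel
  count times the voxel volume (product of the z/y/x pitches; at 0.5 µm
  isotropic pitch, 1 voxel = 0.125 µm³). disSOD1 volume is partitioned
  voxelwise into within-neuron / within-astrocyte / other with exact
  conservation, and compartment volumes can be expressed as percentages of
  a reference group's total. Neuron counts become densities per mm³ of ROI.
* **Astrocyte volumetry.** GFAP is too entangled for instance counting, so
  the pipeline measures volume: background subtraction (25 gray levels),
  Yen auto-thresholding (Triangle available), mask smoothing and a
  physical size filter.
* **Stereology.** A motor neuron is an ISL-1 nucleus with ChAT signal
  within a proximity radius (default 5 µm). Counts are normalized to cord
  length: 50 sections × 30 µm = 1.5 mm, so counts divide by 1.5.
* **Validation metrics.** Instance-matching confusion counts with
  F1 = 2·TP / (2·TP + FP + FN), count correlation (R²), and Cronbach's
  alpha for inter-rater reliability.
* **Cohort statistics.** Directional fold changes between group means,
  dopamine turnover (DOPAC + HVA) / dopamine, Spearman/Pearson
  correlations, group mean ± SEM with a 3×IQR outlier rule.

## Worked example

Generate a ground-truth phantom, run segmentation and quantification, and
compare with the manifest:

```r
library(voxquant)

spec <- phantom_spec(noise_sd = 0, blur_sigma_um = 0, seed = 1)  # 40x96x96 @ 0.5 um
ph   <- generate_stack(spec)

# segment dopamine neurons: slice-wise 2D labels -> IoU stitching -> cleanup
slices  <- segment_slices(get_channel(ph$stack, "TH"), builtin_segmenter(1200))
neurons <- morph_cleanup(stitch_slices(slices, iou_min = 0.25,
                                       ph$stack$voxel_spacing_um), 8)
count_instances(neurons)
#> [1] 5                  # truth: 5 somata

# partition disSOD1 volume by compartment
dis  <- get_channel(ph$stack, "disSOD1") >= 2000
part <- partition_aggregate_volume(dis, ph$truth$labels$neuron > 0,
                                   ph$truth$labels$astrocyte > 0,
                                   spec$voxel_spacing_um)
round(part, 2)
#> in_neuron  in_astro     other     total
#>      2.75     21.75     30.38     54.88
round(ph$truth$totals$aggregate_volume_um3, 2)
#>    neuron astrocyte     other     total
#>      3.38     24.88     26.62     54.88
```

The measured total equals the truth total exactly on a noiseless phantom;
the compartment split differs slightly because truth assigns a punctum to
its centroid's compartment while the partition counts voxels, so puncta
overhanging a mask edge trade volume between neighbouring compartments.

The scripts under `analysis/` run the same machinery as a narrative
workflow over a simulated four-group cohort (01 simulate … 05 cohort
stats), writing tables to `results/` and regenerable images to `scratch/`.
The final script reports, among other things, a programmed treatment
effect recovered by the pipeline as a `4.49-fold decrease` in whole-SN
disSOD1 volume against the disease-vehicle reference group.

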