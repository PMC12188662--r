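#' Physical volume of one voxel
#'
#' Product of the three pitches; the calibration behind every volume the
#' pipeline reports (at 0.5 um isotropic pitch, 1 voxel = 0.125 um^3).
#'
#' @param spacing (z, y, x) voxel pitch in micrometres, strictly positive.
#' @return voxel volume in um^3.
#' @export
#' @examples
#' voxel_volume_um3(c(0.5, 0.5, 0.5))  # 0.125
voxel_volume_um3 <- function(spacing) {
  prod(check_spacing(spacing))
}

#' Physical volume of a binary mask
#'
#' Foreground-voxel count times voxel volume, optionally restricted to a
#' region of interest.
#'
#' @param mask logical 3D array (or `mask_volume`).
#' @param spacing (z, y, x) um pitch.
#' @param roi optional logical array of the same shape.
#' @return volume in um^3.
#' @export
mask_volume_um3 <- function(mask, spacing, roi = NULL) {
  arr <- as_mask_array(mask)
  if (!is.null(roi)) {
    roi <- as_mask_array(roi)
    if (!identical(dim(arr), dim(roi))) {
      stop("mask/roi shape mismatch", call. = FALSE)
    }
    arr <- arr & roi
  }
  sum(arr) * voxel_volume_um3(spacing)
}

#' Partition aggregate volume by cell compartment
#'
#' Splits thresholded disSOD1 signal voxelwise into volume within the
#' neuron mask, within the astrocyte mask, and elsewhere. Where the two
#' cell masks overlap, neurons take priority (deterministic and
#' conservation-preserving), so the three parts always sum exactly to the
#' total disSOD1 volume inside the ROI.
#'
#' @param dis_mask,neuron_mask,astro_mask logical 3D arrays of equal shape.
#' @param spacing (z, y, x) um pitch.
#' @param roi optional ROI restriction.
#' @return named numeric: `in_neuron`, `in_astro`, `other`, `total` (um^3).
#' @export
partition_aggregate_volume <- function(dis_mask, neuron_mask, astro_mask,
                                       spacing, roi = NULL) {
  dis <- as_mask_array(dis_mask)
  neu <- as_mask_array(neuron_mask)
  ast <- as_mask_array(astro_mask)
  if (!identical(dim(dis), dim(neu)) || !identical(dim(dis), dim(ast))) {
    stop("partition: mask shape mismatch", call. = FALSE)
  }
  if (!is.null(roi)) {
    roi <- as_mask_array(roi)
    if (!identical(dim(dis), dim(roi))) {
      stop("partition: roi shape mismatch", call. = FALSE)
    }
    dis <- dis & roi
  }
  vox <- voxel_volume_um3(spacing)
  n_in_neuron <- sum(dis & neu)
  n_in_astro <- sum(dis & ast & !neu)
  n_total <- sum(dis)
  c(in_neuron = n_in_neuron * vox,
    in_astro = n_in_astro * vox,
    other = (n_total - n_in_neuron - n_in_astro) * vox,
    total = n_total * vox)
}

#' Scale compartment volumes to a reference total
#'
#' Expresses raw compartment volumes as percentages of one fixed reference
#' total (e.g. the total disSOD1 volume in the whole SN of the
#' vehicle-treated disease group, the maximum burden in the study), so the
#' reference group's compartments sum to 100%.
#'
#' @param volumes_um3 numeric vector of compartment volumes.
#' @param reference_total_um3 positive reference volume.
#' @return percentages (same names as `volumes_um3`).
#' @export
reference_scaled_percentages <- function(volumes_um3, reference_total_um3) {
  if (!is.numeric(reference_total_um3) || length(reference_total_um3) != 1L ||
      is.na(reference_total_um3) || reference_total_um3 <= 0) {
    stop("reference total must be > 0", call. = FALSE)
  }
  if (any(volumes_um3 < 0)) stop("volumes must be >= 0", call. = FALSE)
  volumes_um3 * 100 / reference_total_um3
}

#' Neuron density per cubic millimetre
#'
#' @param count non-negative cell count.
#' @param roi_volume_um3 ROI volume in um^3 (> 0).
#' @return cells per mm^3 (1 mm^3 = 1e9 um^3).
#' @export
neuron_density <- function(count, roi_volume_um3) {
  if (!is.numeric(roi_volume_um3) || length(roi_volume_um3) != 1L ||
      is.na(roi_volume_um3) || roi_volume_um3 <= 0) {
    stop("roi_volume_um3 must be > 0", call. = FALSE)
  }
  if (count < 0) stop("count must be >= 0", call. = FALSE)
  count / roi_volume_um3 * 1e9
}

# neurons counted in an ROI by centroid membership
count_neurons_in_roi <- function(neuron_labels, roi) {
  arr <- label_array(neuron_labels)
  ids <- unique(arr[arr > 0L])
  if (length(ids) == 0L) return(0L)
  n <- 0L
  for (id in ids) {
    w <- which(arr == id, arr.ind = TRUE)
    ctr <- round(colMeans(w))
    n <- n + as.integer(roi[ctr[1], ctr[2], ctr[3]])
  }
  n
}

#' Per-stack compartment report
#'
#' The per-z-stack output table: one row per ROI with the ROI volume, total
#' disSOD1 volume and its partition by compartment, astrocyte volume,
#' neuron count and density, and the derived normalizations (disSOD1 per
#' astrocyte volume, neuronal disSOD1 per neuron, disSOD1 fraction of the
#' ROI). The compartment partition is exact: `dis_in_neuron_um3 +
#' dis_in_astro_um3 + dis_other_um3 == dis_total_um3` at voxel precision.
#'
#' @param stack_id stack identifier.
#' @param dis_mask thresholded disSOD1 mask.
#' @param neuron_labels `label_volume` (or integer array) of segmented
#'   neurons.
#' @param astro_mask astrocyte-positive mask.
#' @param rois named list of logical ROI arrays.
#' @param spacing (z, y, x) um pitch.
#' @return data.frame, one row per ROI.
#' @export
quantify_stack <- function(stack_id, dis_mask, neuron_labels, astro_mask,
                           rois, spacing) {
  stopifnot(is.list(rois), length(rois) >= 1L, !is.null(names(rois)))
  neu_arr <- label_array(neuron_labels)
  rows <- lapply(names(rois), function(rn) {
    roi <- as_mask_array(rois[[rn]])
    part <- partition_aggregate_volume(dis_mask, neu_arr > 0L, astro_mask,
                                       spacing, roi = roi)
    roi_vol <- mask_volume_um3(roi, spacing)
    astro_vol <- mask_volume_um3(astro_mask, spacing, roi = roi)
    n_neu <- count_neurons_in_roi(neu_arr, roi)
    data.frame(
      stack_id = stack_id, roi_name = rn,
      roi_volume_um3 = roi_vol,
      dis_total_um3 = unname(part["total"]),
      dis_in_neuron_um3 = unname(part["in_neuron"]),
      dis_in_astro_um3 = unname(part["in_astro"]),
      dis_other_um3 = unname(part["other"]),
      astro_volume_um3 = astro_vol,
      neuron_count = n_neu,
      neuron_density_per_mm3 = neuron_density(n_neu, roi_vol),
      dis_per_astro_volume = if (astro_vol > 0)
        unname(part["total"]) / astro_vol else NA_real_,
      dis_in_neuron_per_neuron = if (n_neu > 0)
        unname(part["in_neuron"]) / n_neu else NA_real_,
      dis_fraction_of_roi = unname(part["total"]) / roi_vol,
      schema_version = REPORT_SCHEMA_VERSION,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
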