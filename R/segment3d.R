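#' Labelled 3D instance volume
#'
#' Container for stitched, cleaned cell instances: a non-negative integer
#' (z, y, x) array with labels dense in 1..K, plus calibration and
#' provenance (segmenter id and stitching parameters).
#'
#' @param data integer 3D array, background 0.
#' @param voxel_spacing_um (z, y, x) um triple.
#' @param provenance named list describing how the labels were produced.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(data, voxel_spacing_um, provenance = list()) {
  stopifnot(length(dim(data)) == 3L)
  if (min(data) < 0) stop("labels must be non-negative", call. = FALSE)
  structure(list(data = data, voxel_spacing_um = check_spacing(voxel_spacing_um),
                 provenance = provenance),
            class = "label_volume")
}

label_array <- function(x) if (inherits(x, "label_volume")) x$data else x

# relabel nonzero values to dense 1..K in first-appearance scan order
relabel_dense <- function(lab) {
  u <- sort(unique(lab[lab > 0L]))
  if (length(u) == 0L) return(lab)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  out <- lab
  out[out > 0L] <- map[out[out > 0L]]
  out
}

#' Built-in threshold-and-label 2D segmenter
#'
#' A deterministic stand-in for a learned 2D cell segmenter, honouring the
#' same contract (2D intensity slice in, 2D integer label image out):
#' intensity `>= threshold` followed by 8-connected component labelling.
#' Used to exercise the stitching and quantification stages on phantoms.
#'
#' @param threshold foreground intensity cutoff.
#' @return a function `(slice2d) -> integer label matrix`.
#' @export
builtin_segmenter <- function(threshold) {
  force(threshold)
  function(slice) {
    m <- slice >= threshold
    lab3 <- label_components(array(m, c(1L, nrow(slice), ncol(slice))), 26L)
    matrix(lab3[1L, , ], nrow(slice), ncol(slice))
  }
}

#' Run a 2D segmenter over every z-slice of a channel
#'
#' @param channel numeric 3D (z, y, x) array.
#' @param segmenter a `Segmenter2D`: function from 2D intensity slice to 2D
#'   integer label matrix (0 = background, labels positive).
#' @return list of integer label matrices, one per slice.
#' @export
segment_slices <- function(channel, segmenter) {
  stopifnot(length(dim(channel)) == 3L, is.function(segmenter))
  d <- dim(channel)
  lapply(seq_len(d[1]), function(z) {
    out <- tryCatch(segmenter(matrix(channel[z, , ], d[2], d[3])),
                    error = function(e) {
                      stop(sprintf("segmenter failed on slice %d: %s",
                                   z, conditionMessage(e)), call. = FALSE)
                    })
    if (!is.matrix(out) || !identical(dim(out), d[2:3])) {
      stop(sprintf("segmenter contract violated on slice %d: output shape %s != %s",
                   z, paste(dim(out), collapse = "x"),
                   paste(d[2:3], collapse = "x")), call. = FALSE)
    }
    if (any(out < 0)) {
      stop(sprintf("segmenter contract violated on slice %d: negative labels", z),
           call. = FALSE)
    }
    storage.mode(out) <- "integer"
    out
  })
}

#' Intersection over union of two binary masks
#'
#' `|A n B| / |A u B|`, defined as 0 when both masks are empty.
#'
#' @param mask_a,mask_b logical arrays of equal shape.
#' @return ratio in `[0, 1]`.
#' @export
iou <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) {
    stop("iou: shape mismatch", call. = FALSE)
  }
  u <- sum(mask_a | mask_b)
  if (u == 0L) return(0)
  sum(mask_a & mask_b) / u
}

# union-find root lookup (iterative; no mutation so it stays referentially
# transparent for callers that keep `parent` as a plain vector)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Stitch per-slice 2D instances into 3D objects by IoU linkage
#'
#' Two instances on adjacent slices belong to the same 3D object iff they
#' are linked, directly or transitively, through adjacent-slice mask pairs
#' whose intersection-over-union is at least `iou_min` (default 0.25, the
#' published linkage rule). Linkage is union-find over all qualifying
#' adjacent-slice pairs, so a large cross-section can merge two chains; an
#' object absent from the next slice terminates (no linking across gaps).
#' The result is symmetric in slice direction and invariant to the 2D
#' label ids.
#'
#' @param labels_2d list of integer label matrices sharing one shape.
#' @param iou_min linkage threshold in `[0, 1]`.
#' @param voxel_spacing_um calibration carried into the result.
#' @param segmenter_id provenance string.
#' @return a `label_volume` with dense labels.
#' @export
stitch_slices <- function(labels_2d, iou_min = 0.25,
                          voxel_spacing_um = c(1, 1, 1),
                          segmenter_id = "unknown") {
  if (!is.numeric(iou_min) || length(iou_min) != 1L || is.na(iou_min) ||
      iou_min < 0 || iou_min > 1) {
    stop("iou_min must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(is.list(labels_2d), length(labels_2d) >= 1L)
  shp <- dim(labels_2d[[1]])
  for (z in seq_along(labels_2d)) {
    if (!identical(dim(labels_2d[[z]]), shp)) {
      stop("stitch_slices: slices do not share one shape", call. = FALSE)
    }
  }
  nz <- length(labels_2d)
  # global ids per (slice, local label)
  n_local <- vapply(labels_2d, function(l) max(0L, max(l)), integer(1))
  offset <- cumsum(c(0L, n_local[-nz]))
  n_glob <- sum(n_local)
  if (n_glob == 0L) {
    return(label_volume(array(0L, c(nz, shp)), voxel_spacing_um,
                        list(segmenter = segmenter_id, iou_min = iou_min)))
  }
  parent <- seq_len(n_glob)
  # areas per global id
  areas <- integer(n_glob)
  for (z in seq_len(nz)) {
    l <- labels_2d[[z]]
    if (n_local[z] > 0L) {
      areas[offset[z] + seq_len(n_local[z])] <-
        tabulate(l[l > 0L], nbins = n_local[z])
    }
  }
  for (z in seq_len(nz - 1L)) {
    a <- labels_2d[[z]]; b <- labels_2d[[z + 1L]]
    sel <- a > 0L & b > 0L
    if (!any(sel)) next
    pair_code <- (as.numeric(a[sel]) - 1) * n_local[z + 1L] + as.numeric(b[sel])
    tab <- table(pair_code)
    codes <- as.numeric(names(tab))
    ia <- floor((codes - 1) / n_local[z + 1L]) + 1
    ib <- codes - (ia - 1) * n_local[z + 1L]
    inter <- as.integer(tab)
    ga <- offset[z] + as.integer(ia)
    gb <- offset[z + 1L] + as.integer(ib)
    iou_pair <- inter / (areas[ga] + areas[gb] - inter)
    link <- which(iou_pair >= iou_min)
    for (k in link) {
      ra <- uf_find(parent, ga[k]); rb <- uf_find(parent, gb[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n_glob), function(i) uf_find(parent, i), integer(1))
  out <- array(0L, c(nz, shp))
  for (z in seq_len(nz)) {
    l <- labels_2d[[z]]
    sel <- l > 0L
    if (any(sel)) {
      slab <- array(0L, shp)
      slab[sel] <- roots[offset[z] + l[sel]]
      out[z, , ] <- slab
    }
  }
  label_volume(relabel_dense(out), voxel_spacing_um,
               list(segmenter = segmenter_id, iou_min = iou_min))
}

# fill interior holes: background components (26-connected) not touching the
# volume border become foreground
fill_holes3d <- function(mask) {
  bg <- !mask
  lab <- label_components(bg, 26L)
  d <- dim(mask)
  border_labels <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                            lab[, , c(1, d[3])]))
  border_labels <- border_labels[border_labels > 0L]
  hole <- bg & !(array(lab %in% border_labels, d))
  mask | hole
}

dilate_cube <- function(mask) {
  out <- mask
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    s <- shift3d(mask, 1L, dz, pad = FALSE)
    s <- shift3d(s, 2L, dy, pad = FALSE)
    s <- shift3d(s, 3L, dx, pad = FALSE)
    out <- out | s
  }
  out
}

erode_cube <- function(mask) {
  out <- mask
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    s <- shift3d(mask, 1L, dz, pad = TRUE)
    s <- shift3d(s, 2L, dy, pad = TRUE)
    s <- shift3d(s, 3L, dx, pad = TRUE)
    out <- out & s
  }
  out
}

#' Morphological cleanup of a stitched label volume
#'
#' Applies, in order: binarize, dilate (3x3x3 cube, the r = 1 voxel ball in
#' the Chebyshev metric), fill holes, erode (same element), remove
#' components below `min_volume_um3`, and relabel 1..K by 26-connected
#' components. The cleaned volume is the sole basis for all downstream
#' counts and volumes. Idempotent on its own output up to relabelling.
#'
#' @param labels a `label_volume` or integer 3D array.
#' @param min_volume_um3 physical size cutoff (default 0: keep all).
#' @param voxel_spacing_um calibration; taken from `labels` when it is a
#'   `label_volume`.
#' @return a `label_volume`.
#' @export
morph_cleanup <- function(labels, min_volume_um3 = 0,
                          voxel_spacing_um = NULL) {
  if (inherits(labels, "label_volume")) {
    if (is.null(voxel_spacing_um)) voxel_spacing_um <- labels$voxel_spacing_um
    prov <- labels$provenance
  } else prov <- list()
  if (is.null(voxel_spacing_um)) voxel_spacing_um <- c(1, 1, 1)
  arr <- label_array(labels)
  m <- arr > 0L
  m <- dilate_cube(m)
  m <- fill_holes3d(m)
  m <- erode_cube(m)
  if (min_volume_um3 > 0 && any(m)) {
    m <- as_mask_array(remove_small_objects(m, min_volume_um3, voxel_spacing_um))
  }
  lab <- label_components(m, 26L)
  prov$cleanup <- list(element = "cube3", min_volume_um3 = min_volume_um3)
  label_volume(lab, voxel_spacing_um, prov)
}

#' Number of distinct instances in a label volume
#' @param labels a `label_volume` or integer array.
#' @return integer count of distinct nonzero labels.
#' @export
count_instances <- function(labels) {
  arr <- label_array(labels)
  length(unique(arr[arr > 0L]))
}
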