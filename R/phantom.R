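#' Specification of a synthetic multi-channel z-stack phantom
#'
#' Describes the geometry, object counts, placement statistics and imaging
#' model of one synthetic midbrain z-stack: tyrosine-hydroxylase (TH)
#' somata rendered as ellipsoids, branched GFAP astrocyte territories,
#' punctate disordered-SOD1 (disSOD1) aggregates placed with programmed
#' compartment fractions, and a nuclear channel. Defaults emulate a 20 um
#' deep confocal stack sampled at 0.5 um voxel pitch (1 voxel = 0.125 um^3).
#'
#' @param shape integer (z, y, x) voxel counts.
#' @param voxel_spacing_um (z, y, x) voxel pitch in micrometres.
#' @param n_neurons number of TH-positive somata.
#' @param n_astrocytes number of branched GFAP structures.
#' @param n_aggregates number of disSOD1 puncta.
#' @param aggregate_placement fractions of aggregates whose centroid falls
#'   within a neuron, within an astrocyte, or elsewhere; must sum to 1.
#' @param aggregate_radius_um mean and sd of the aggregate sphere radius (um).
#' @param intensity_levels named list, one `c(bg, fg)` pair of 16-bit mean
#'   intensities per channel (`disSOD1`, `TH`, `GFAP`, `nuclear`).
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @param blur_sigma_um optional isotropic Gaussian blur applied to the
#'   noiseless rendering (a crude point-spread stand-in); 0 disables it.
#' @param seed integer RNG seed; identical specs give bit-identical phantoms.
#'
#' @return an object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(shape = c(16, 32, 32), n_neurons = 2,
#'                      n_astrocytes = 1, n_aggregates = 5, seed = 1)
phantom_spec <- function(shape = c(40L, 96L, 96L),
                         voxel_spacing_um = c(0.5, 0.5, 0.5),
                         n_neurons = 5L,
                         n_astrocytes = 3L,
                         n_aggregates = 40L,
                         aggregate_placement = c(within_neuron = 0.1,
                                                 within_astrocyte = 0.3,
                                                 elsewhere = 0.6),
                         aggregate_radius_um = c(mean = 0.6, sd = 0.2),
                         intensity_levels = list(
                           disSOD1 = c(bg = 100, fg = 4000),
                           TH      = c(bg = 120, fg = 2500),
                           GFAP    = c(bg = 110, fg = 2000),
                           nuclear = c(bg = 90,  fg = 3000)),
                         noise_sd = 40,
                         blur_sigma_um = 0.25,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 1L)) {
    stop("shape must be three positive voxel counts (z, y, x)", call. = FALSE)
  }
  voxel_spacing_um <- check_spacing(voxel_spacing_um)
  counts <- c(n_neurons, n_astrocytes, n_aggregates)
  if (anyNA(counts) || any(counts < 0)) {
    stop("object counts must be >= 0", call. = FALSE)
  }
  p <- as.numeric(aggregate_placement)
  if (length(p) != 3L || anyNA(p) || any(p < 0) || any(p > 1) ||
      abs(sum(p) - 1) > 1e-9) {
    stop("aggregate_placement must be three fractions in [0,1] summing to 1",
         call. = FALSE)
  }
  names(p) <- c("within_neuron", "within_astrocyte", "elsewhere")
  r <- as.numeric(aggregate_radius_um)
  if (length(r) != 2L || anyNA(r) || r[1] <= 0 || r[2] < 0) {
    stop("aggregate_radius_um must be c(mean > 0, sd >= 0)", call. = FALSE)
  }
  stopifnot(is.list(intensity_levels),
            all(c("disSOD1", "TH", "GFAP", "nuclear") %in% names(intensity_levels)))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (blur_sigma_um < 0) stop("blur_sigma_um must be >= 0", call. = FALSE)
  structure(list(shape = shape,
                 voxel_spacing_um = voxel_spacing_um,
                 n_neurons = as.integer(n_neurons),
                 n_astrocytes = as.integer(n_astrocytes),
                 n_aggregates = as.integer(n_aggregates),
                 aggregate_placement = p,
                 aggregate_radius_um = c(mean = r[1], sd = r[2]),
                 intensity_levels = intensity_levels,
                 noise_sd = noise_sd,
                 blur_sigma_um = blur_sigma_um,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# voxel indices (matrix n x 3, 1-based z,y,x) of an ellipsoid with the given
# centre (voxel coords, may be fractional), semi-axes in um, on a grid with
# the given spacing and bounds.
ellipsoid_voxels <- function(center, semi_axes_um, spacing, dims) {
  half_vox <- semi_axes_um / spacing
  lo <- pmax(1L, floor(center - half_vox))
  hi <- pmin(dims, ceiling(center + half_vox))
  if (any(lo > hi)) return(matrix(integer(0), ncol = 3))
  zz <- seq.int(lo[1], hi[1]); yy <- seq.int(lo[2], hi[2]); xx <- seq.int(lo[3], hi[3])
  g <- as.matrix(expand.grid(z = zz, y = yy, x = xx))
  d2 <- ((g[, 1] - center[1]) * spacing[1] / semi_axes_um[1])^2 +
        ((g[, 2] - center[2]) * spacing[2] / semi_axes_um[2])^2 +
        ((g[, 3] - center[3]) * spacing[3] / semi_axes_um[3])^2
  g[d2 <= 1, , drop = FALSE]
}

sphere_voxels <- function(center, radius_um, spacing, dims) {
  ellipsoid_voxels(center, rep(radius_um, 3), spacing, dims)
}

vox_index <- function(vox, dims) {
  # linear indices of an n x 3 (z,y,x) voxel matrix
  vox[, 1] + dims[1] * ((vox[, 2] - 1) + dims[2] * (vox[, 3] - 1))
}

placement_error <- function(what) {
  stop(structure(class = c("voxquant_placement_error", "error", "condition"),
                 list(message = paste0("could not place ", what,
                                       " within the retry budget; ",
                                       "reduce object counts or sizes"),
                      call = NULL)))
}

# one branched astrocyte: a small soma sphere at the root plus dilated
# random-walk processes; returns voxel matrix
astrocyte_voxels <- function(dims, spacing, span_um, n_branches) {
  root <- c(runif(1, 2, dims[1] - 1), runif(1, 2, dims[2] - 1),
            runif(1, 2, dims[3] - 1))
  soma <- sphere_voxels(root, runif(1, 2.5, 4), spacing, dims)
  step_um <- min(spacing)
  n_steps <- max(4L, round((span_um / 2) / step_um))
  pts <- matrix(root, ncol = 3)
  for (b in seq_len(n_branches)) {
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    pos <- root
    for (s in seq_len(n_steps)) {
      dir <- dir + rnorm(3, sd = 0.35)
      dir <- dir / sqrt(sum(dir^2))
      pos <- pos + dir * step_um / spacing
      pos <- pmin(pmax(pos, 1), dims)
      pts <- rbind(pts, pos)
    }
  }
  vox <- unique(round(pts))
  vox <- vox[vox[, 1] >= 1 & vox[, 1] <= dims[1] &
             vox[, 2] >= 1 & vox[, 2] <= dims[2] &
             vox[, 3] >= 1 & vox[, 3] <= dims[3], , drop = FALSE]
  # thicken the skeleton by one voxel in each direction (process calibre)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  thick <- vox[rep(seq_len(nrow(vox)), each = nrow(offs)), , drop = FALSE] +
    offs[rep(seq_len(nrow(offs)), times = nrow(vox)), , drop = FALSE]
  thick <- unique(rbind(thick, soma))
  thick[thick[, 1] >= 1 & thick[, 1] <= dims[1] &
        thick[, 2] >= 1 & thick[, 2] <= dims[2] &
        thick[, 3] >= 1 & thick[, 3] <= dims[3], , drop = FALSE]
}

#' Generate one ground-truth-labelled phantom z-stack
#'
#' Renders the four channels described by a [phantom_spec()] and returns both
#' the calibrated image stack and an exact truth manifest: per-class label
#' volumes, per-object records (centroid, volume, host compartment) and
#' per-class totals. Aggregate host compartments are assigned by centroid
#' membership in the neuron/astrocyte truth masks; aggregates may overhang a
#' compartment edge but never overlap each other, and cell structures of
#' different classes never overlap. Two abutting half-volume regions of
#' interest ("SNc", the x-low half, and "SNc+SNr", the full volume) are
#' included to exercise ROI-restricted reporting.
#'
#' @param spec a [phantom_spec()].
#' @param max_tries placement retry budget per object before a
#'   placement-failure error is raised.
#' @return a list with elements `stack` (an `image_stack`) and `truth`
#'   (a `phantom_truth`: `labels`, `objects`, `totals`, `rois`).
#' @export
generate_stack <- function(spec, max_tries = 200L) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$shape
  sp <- spec$voxel_spacing_um
  voxvol <- voxel_volume_um3(sp)

  with_seed(spec$seed, {
    neuron_lab <- array(0L, dims)
    astro_lab <- array(0L, dims)
    agg_lab <- array(0L, dims)
    nuc_lab <- array(0L, dims)
    objects <- list()

    # --- neurons: ellipsoidal somata, diameters 5-12 um. Somata keep a
    # clear gap of about 3 voxels (1.5 um at the default pitch): adjacent
    # somata at these densities are optically resolvable, and the gap is
    # wide enough that a radius-1 morphological closing cannot weld two
    # instances together downstream.
    for (i in seq_len(spec$n_neurons)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        semi <- runif(3, 2.5, 6)
        ctr <- c(runif(1, 1, dims[1]), runif(1, 1, dims[2]), runif(1, 1, dims[3]))
        vox <- ellipsoid_voxels(ctr, semi, sp, dims)
        if (nrow(vox) == 0L) next
        inflated <- ellipsoid_voxels(ctr, semi + 3 * max(sp), sp, dims)
        if (any(neuron_lab[vox_index(inflated, dims)] != 0L)) next
        idx <- vox_index(vox, dims)
        neuron_lab[idx] <- i
        # nucleus: small sphere at the soma centre
        nvox <- sphere_voxels(ctr, min(2, min(semi) * 0.6), sp, dims)
        nidx <- vox_index(nvox, dims)
        nidx <- nidx[neuron_lab[nidx] == i]
        nuc_lab[nidx] <- i
        objects[[length(objects) + 1L]] <- data.frame(
          object_id = paste0("neuron_", i), class = "neuron", label = i,
          centroid_z = ctr[1], centroid_y = ctr[2], centroid_x = ctr[3],
          volume_um3 = length(idx) * voxvol, compartment = NA_character_,
          stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) placement_error(sprintf("neuron %d", i))
    }

    # --- astrocytes: branched dilated random walks, disjoint from neurons
    for (i in seq_len(spec$n_astrocytes)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        vox <- astrocyte_voxels(dims, sp, span_um = runif(1, 20, 40),
                                n_branches = sample(3:5, 1))
        if (nrow(vox) == 0L) next
        idx <- vox_index(vox, dims)
        if (any(neuron_lab[idx] != 0L) || any(astro_lab[idx] != 0L)) next
        astro_lab[idx] <- i
        ctr <- colMeans(vox)
        objects[[length(objects) + 1L]] <- data.frame(
          object_id = paste0("astrocyte_", i), class = "astrocyte", label = i,
          centroid_z = ctr[1], centroid_y = ctr[2], centroid_x = ctr[3],
          volume_um3 = length(idx) * voxvol, compartment = NA_character_,
          stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) placement_error(sprintf("astrocyte %d", i))
    }

    # --- aggregates: spheres with programmed compartment placement
    comp_names <- c("neuron", "astrocyte", "other")
    if (spec$n_aggregates > 0L) {
      comp_draw <- sample(comp_names, spec$n_aggregates, replace = TRUE,
                          prob = spec$aggregate_placement)
    } else comp_draw <- character(0)
    in_neuron <- neuron_lab != 0L
    in_astro <- astro_lab != 0L
    cand <- list(neuron = which(in_neuron),
                 astrocyte = which(in_astro & !in_neuron),
                 other = which(!in_neuron & !in_astro))
    for (i in seq_len(spec$n_aggregates)) {
      comp <- comp_draw[i]
      pool <- cand[[comp]]
      if (length(pool) == 0L) placement_error(
        sprintf("aggregate %d in compartment '%s' (empty compartment)", i, comp))
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        lin <- pool[sample.int(length(pool), 1L)]
        ctr <- c((lin - 1L) %% dims[1] + 1L,
                 ((lin - 1L) %/% dims[1]) %% dims[2] + 1L,
                 (lin - 1L) %/% (dims[1] * dims[2]) + 1L)
        radius <- max(min(sp) * 0.51,
                      rnorm(1, spec$aggregate_radius_um["mean"],
                            spec$aggregate_radius_um["sd"]))
        vox <- sphere_voxels(as.numeric(ctr), radius, sp, dims)
        idx <- vox_index(vox, dims)
        if (any(agg_lab[idx] != 0L)) next
        agg_lab[idx] <- i
        objects[[length(objects) + 1L]] <- data.frame(
          object_id = paste0("aggregate_", i), class = "aggregate", label = i,
          centroid_z = ctr[1], centroid_y = ctr[2], centroid_x = ctr[3],
          volume_um3 = length(idx) * voxvol, compartment = comp,
          stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) placement_error(sprintf("aggregate %d", i))
    }

    objects <- if (length(objects)) do.call(rbind, objects) else data.frame(
      object_id = character(0), class = character(0), label = integer(0),
      centroid_z = numeric(0), centroid_y = numeric(0), centroid_x = numeric(0),
      volume_um3 = numeric(0), compartment = character(0),
      stringsAsFactors = FALSE)

    agg_by_comp <- setNames(numeric(3), comp_names)
    if (any(objects$class == "aggregate")) {
      tt <- tapply(objects$volume_um3[objects$class == "aggregate"],
                   factor(objects$compartment[objects$class == "aggregate"],
                          levels = comp_names), sum)
      agg_by_comp[names(tt)] <- ifelse(is.na(tt), 0, tt)
    }
    totals <- list(
      aggregate_volume_um3 = c(agg_by_comp, total = sum(agg_by_comp)),
      aggregate_count = spec$n_aggregates,
      neuron_count = spec$n_neurons,
      astrocyte_volume_um3 = sum(objects$volume_um3[objects$class == "astrocyte"]))

    # --- render channels
    masks <- list(disSOD1 = agg_lab != 0L, TH = neuron_lab != 0L,
                  GFAP = astro_lab != 0L, nuclear = nuc_lab != 0L)
    ch_names <- names(masks)
    data <- array(0, dim = c(length(ch_names), dims))
    for (k in seq_along(ch_names)) {
      lev <- spec$intensity_levels[[ch_names[k]]]
      vol <- array(lev[["bg"]], dims)
      vol[masks[[k]]] <- lev[["fg"]]
      if (spec$blur_sigma_um > 0) {
        vol <- gaussian_blur(vol, spec$blur_sigma_um, sp)
      }
      if (spec$noise_sd > 0) {
        vol <- vol + rnorm(length(vol), 0, spec$noise_sd)
      }
      data[k, , , ] <- round(pmin(pmax(vol, 0), 65535))
    }

    rois <- list(
      "SNc" = {
        m <- array(FALSE, dims); m[, , seq_len(floor(dims[3] / 2))] <- TRUE; m
      },
      "SNc+SNr" = array(TRUE, dims))

    stack <- image_stack(data, voxel_spacing_um = sp, channel_names = ch_names,
                         source_id = sprintf("phantom_seed%d", spec$seed))
    truth <- structure(list(
      labels = list(neuron = neuron_lab, astrocyte = astro_lab,
                    aggregate = agg_lab, nucleus = nuc_lab),
      objects = objects, totals = totals, rois = rois, spec = spec),
      class = "phantom_truth")
    list(stack = stack, truth = truth)
  })
}

#' Generate a cohort of phantoms with programmed group effects
#'
#' Emulates a multi-group animal study (e.g. genotype x treatment) in which
#' the true disSOD1 aggregate burden differs between groups by programmed
#' multipliers. The multiplier scales the expected number of aggregates per
#' animal, so mean true aggregate volume scales with it in expectation.
#' Per-animal seeds derive deterministically from `seed`.
#'
#' @param base_spec a [phantom_spec()] describing a reference animal.
#' @param group_effects named numeric vector of positive multipliers, one
#'   per group.
#' @param n_per_group animals per group (>= 1).
#' @param seed master seed for the cohort.
#' @return list with `animals` (list of `list(animal_id, group, stack,
#'   truth)`) and `table` (one row per animal with true totals).
#' @export
generate_cohort <- function(base_spec, group_effects, n_per_group, seed) {
  stopifnot(inherits(base_spec, "phantom_spec"))
  if (is.null(names(group_effects)) || any(!nzchar(names(group_effects)))) {
    stop("group_effects must be a named vector of multipliers", call. = FALSE)
  }
  if (any(group_effects <= 0)) stop("group multipliers must be > 0", call. = FALSE)
  if (n_per_group < 1) stop("n_per_group must be >= 1", call. = FALSE)
  groups <- names(group_effects)
  n_total <- length(groups) * n_per_group
  animal_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_total))
  animals <- vector("list", n_total)
  rows <- vector("list", n_total)
  k <- 0L
  for (g in groups) {
    for (a in seq_len(n_per_group)) {
      k <- k + 1L
      spec_a <- base_spec
      spec_a$n_aggregates <- as.integer(round(base_spec$n_aggregates *
                                                group_effects[[g]]))
      spec_a$seed <- animal_seeds[k]
      ph <- generate_stack(spec_a)
      id <- sprintf("%s_%02d", g, a)
      ph$stack$source_id <- id
      animals[[k]] <- list(animal_id = id, group = g,
                           stack = ph$stack, truth = ph$truth)
      tot <- ph$truth$totals
      rows[[k]] <- data.frame(
        animal_id = id, group = g, multiplier = unname(group_effects[[g]]),
        seed = animal_seeds[k],
        true_aggregate_volume_um3 = unname(tot$aggregate_volume_um3["total"]),
        true_neuron_count = tot$neuron_count,
        true_astrocyte_volume_um3 = tot$astrocyte_volume_um3,
        stringsAsFactors = FALSE)
    }
  }
  list(animals = animals, table = do.call(rbind, rows))
}

#' Generate a synthetic striatal neurochemistry table
#'
#' One row per animal with dopamine, DOPAC and HVA concentrations in ng per
#' mg protein, drawn around per-group means with additive Gaussian noise.
#' Negative draws are truncated at zero and flagged.
#'
#' @param group_means named list; each element `c(DA, DOPAC, HVA)` >= 0.
#' @param noise_sd per-analyte noise sd (length 1 or 3).
#' @param n_per_group animals per group.
#' @param seed integer seed.
#' @return data.frame with columns `animal_id`, `group`,
#'   `dopamine_ng_per_mg`, `dopac_ng_per_mg`, `hva_ng_per_mg`, `truncated`.
#' @export
generate_neurochem_table <- function(group_means, noise_sd = 0,
                                     n_per_group = 10L, seed = 1L) {
  stopifnot(is.list(group_means), length(group_means) >= 1L)
  if (any(vapply(group_means, function(m) any(m < 0), logical(1)))) {
    stop("group means must be >= 0", call. = FALSE)
  }
  if (n_per_group < 1) stop("n_per_group must be >= 1", call. = FALSE)
  sds <- rep_len(as.numeric(noise_sd), 3L)
  if (any(sds < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  with_seed(seed, {
    rows <- list()
    for (g in names(group_means)) {
      m <- as.numeric(group_means[[g]])
      stopifnot(length(m) == 3L)
      for (a in seq_len(n_per_group)) {
        draw <- m + rnorm(3, 0, sds)
        trunc <- any(draw < 0)
        draw <- pmax(draw, 0)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = sprintf("%s_%02d", g, a), group = g,
          dopamine_ng_per_mg = draw[1], dopac_ng_per_mg = draw[2],
          hva_ng_per_mg = draw[3], truncated = trunc,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a synthetic spinal-cord section image pair for stereology
#'
#' Produces a 2D nucleus label image (ISL-1-like) on a jittered grid plus a
#' ChAT-like binary mask built by offsetting a disc from each nucleus by a
#' known distance, so which nuclei count as double-positive at a given
#' proximity radius is controlled exactly.
#'
#' @param shape (y, x) pixel counts.
#' @param n_nuclei number of nuclei.
#' @param pixel_spacing_um isotropic pixel pitch, um.
#' @param nucleus_radius_um,chat_radius_um disc radii, um.
#' @param chat_offset_um distance from each nucleus boundary to the nearest
#'   edge of its ChAT disc (recycled over nuclei); negative values overlap.
#' @param chat_present logical vector, recycled: whether a nucleus gets a
#'   ChAT disc at all.
#' @param seed integer seed for grid jitter.
#' @return list with `isl1_labels` (integer matrix), `chat_mask` (logical
#'   matrix) and `truth` (data.frame: nucleus id, offset, expected
#'   double-positive flag at the generating offsets).
#' @export
generate_section_phantom <- function(shape = c(128L, 128L), n_nuclei = 9L,
                                     pixel_spacing_um = 0.5,
                                     nucleus_radius_um = 3,
                                     chat_radius_um = 2,
                                     chat_offset_um = 1,
                                     chat_present = TRUE,
                                     seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 8L), n_nuclei >= 0)
  offs <- rep_len(as.numeric(chat_offset_um), max(n_nuclei, 1L))
  pres <- rep_len(as.logical(chat_present), max(n_nuclei, 1L))
  rpx_n <- nucleus_radius_um / pixel_spacing_um
  rpx_c <- chat_radius_um / pixel_spacing_um
  with_seed(seed, {
    labs <- matrix(0L, shape[1], shape[2])
    chat <- matrix(FALSE, shape[1], shape[2])
    side <- ceiling(sqrt(max(n_nuclei, 1L)))
    margin <- rpx_n + rpx_c + max(offs, 0) / pixel_spacing_um + 2
    cy <- seq(margin, shape[1] - margin, length.out = side)
    cx <- seq(margin, shape[2] - margin, length.out = side)
    centres <- as.matrix(expand.grid(y = cy, x = cx))[seq_len(n_nuclei), ,
                                                      drop = FALSE]
    centres <- centres + matrix(runif(2 * n_nuclei, -1, 1), ncol = 2)
    truth <- NULL
    for (i in seq_len(n_nuclei)) {
      yy <- row(labs) - centres[i, 1]; xx <- col(labs) - centres[i, 2]
      labs[yy^2 + xx^2 <= rpx_n^2] <- i
      if (pres[i]) {
        # place the ChAT disc so its nearest edge sits offs[i] um from the
        # nucleus boundary, along a random direction
        ang <- runif(1, 0, 2 * pi)
        d_ctr <- rpx_n + offs[i] / pixel_spacing_um + rpx_c
        ccy <- centres[i, 1] + d_ctr * sin(ang)
        ccx <- centres[i, 2] + d_ctr * cos(ang)
        chat <- chat | ((row(labs) - ccy)^2 + (col(labs) - ccx)^2 <= rpx_c^2)
      }
      truth <- rbind(truth, data.frame(nucleus = i, chat_present = pres[i],
                                       offset_um = offs[i]))
    }
    list(isl1_labels = labs, chat_mask = chat, truth = truth)
  })
}
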