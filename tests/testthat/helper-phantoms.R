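# shared fixture builders (all generated in code at test time)

small_spec <- function(seed = 7, ...) {
  args <- list(shape = c(24L, 48L, 48L), n_neurons = 3L, n_astrocytes = 2L,
               n_aggregates = 15L, noise_sd = 0, blur_sigma_um = 0,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(phantom_spec, args)
}

# a binary volume of well-separated convex solids (cylinders, truncated
# cones with bounded taper, cuboids) whose adjacent cross-sections always
# satisfy the IoU >= 0.25 linkage premise; objects are >= 2 voxels apart so
# 26-connected components equal the true objects
convex_objects_volume <- function(seed, shape = c(20L, 40L, 40L),
                                  n_objects = 4L) {
  withr::with_seed(seed, {
    vol <- array(FALSE, shape)
    occupied <- array(FALSE, shape)   # objects dilated by the 2-voxel margin
    placed <- 0L
    tries <- 0L
    while (placed < n_objects && tries < 500L) {
      tries <- tries + 1L
      kind <- sample(c("cylinder", "cone", "cuboid"), 1L)
      z0 <- sample.int(shape[1] - 8L, 1L)
      z1 <- z0 + sample(4:8, 1L)
      if (z1 > shape[1]) next
      cy <- runif(1, 8, shape[2] - 8)
      cx <- runif(1, 8, shape[3] - 8)
      r0 <- runif(1, 3, 6)
      obj <- array(FALSE, shape)
      for (z in z0:z1) {
        r <- switch(kind,
                    cylinder = r0,
                    # taper keeps the ratio of adjacent radii >= sqrt(0.5),
                    # so adjacent-disc IoU = (r_min/r_max)^2 >= 0.5
                    cone = r0 * (1 - 0.3 * (z - z0) / max(1L, z1 - z0)),
                    cuboid = r0)
        if (kind == "cuboid") {
          ys <- max(1, round(cy - r)):min(shape[2], round(cy + r))
          xs <- max(1, round(cx - r)):min(shape[3], round(cx + r))
          obj[z, ys, xs] <- TRUE
        } else {
          d2 <- outer((seq_len(shape[2]) - cy)^2, (seq_len(shape[3]) - cx)^2, "+")
          obj[z, , ] <- obj[z, , ] | (d2 <= r^2)
        }
      }
      idx <- which(obj)
      if (length(idx) == 0L || any(occupied[idx])) next
      vol <- vol | obj
      grown <- obj
      for (k in 1:2) grown <- voxquant:::dilate_cube(grown)
      occupied <- occupied | grown
      placed <- placed + 1L
    }
    vol
  })
}

# per-slice 8-connected 2D labels of a binary volume (stitching input)
slice_labels <- function(vol) {
  d <- dim(vol)
  lapply(seq_len(d[1]), function(z) {
    lab3 <- label_components(array(vol[z, , ], c(1L, d[2], d[3])), 26L)
    matrix(lab3[1L, , ], d[2], d[3])
  })
}

# tiny deterministic pipeline config used by pipeline and acceptance tests
tiny_pipeline_config <- function(seed = 5L, n_per_group = 1L) {
  pipeline_config(
    base_spec = phantom_spec(shape = c(16L, 48L, 48L), n_neurons = 2L,
                             n_astrocytes = 1L, n_aggregates = 12L,
                             noise_sd = 0, blur_sigma_um = 0, seed = 1L),
    group_effects = c(vehicle = 4, treated = 1),
    n_per_group = n_per_group,
    seed = seed)
}
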