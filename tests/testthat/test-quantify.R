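test_that("voxel volume is the product of the three pitches", {
  expect_identical(voxel_volume_um3(c(0.5, 0.5, 0.5)), 0.125)
  expect_identical(voxel_volume_um3(c(1, 1, 1)), 1)
  expect_identical(voxel_volume_um3(c(2, 0.5, 0.5)), 0.5)
  expect_error(voxel_volume_um3(c(0, 1, 1)), "positive")
})

test_that("mask volume counts foreground voxels, optionally inside an ROI", {
  m <- array(FALSE, c(4, 4, 4))
  expect_equal(mask_volume_um3(m, c(0.5, 0.5, 0.5)), 0)
  m[2, 2, 2] <- TRUE
  expect_equal(mask_volume_um3(m, c(0.5, 0.5, 0.5)), 0.125)
  expect_error(mask_volume_um3(m, c(1, 1, 1), roi = array(TRUE, c(3, 3, 3))),
               "shape")
  withr::with_seed(3, {
    mm <- array(runif(1000) < 0.3, c(10, 10, 10))
    roi <- array(runif(1000) < 0.5, c(10, 10, 10))
    # exhaustive-scan oracle
    cnt <- 0L
    for (i in which(mm)) if (roi[i]) cnt <- cnt + 1L
    expect_equal(mask_volume_um3(mm, c(0.5, 0.5, 0.5), roi), cnt * 0.125)
  })
})

test_that("compartment partition is exhaustive, prioritized and conservative", {
  d <- c(6, 8, 8)
  sp <- c(0.5, 0.5, 0.5)
  dis <- array(FALSE, d); dis[2:3, 2:4, 2:4] <- TRUE
  neu <- array(FALSE, d); ast <- array(FALSE, d)

  # disSOD1 entirely inside the neuron mask
  neu[1:4, 1:6, 1:6] <- TRUE
  p <- partition_aggregate_volume(dis, neu, ast, sp)
  expect_equal(unname(p), c(p[["total"]], 0, 0, p[["total"]]))

  # masks disjoint from the signal
  p2 <- partition_aggregate_volume(dis, array(FALSE, d), array(FALSE, d), sp)
  expect_equal(p2[["other"]], p2[["total"]])

  # neuron priority where cell masks overlap
  ast[1:6, 1:8, 1:8] <- TRUE
  p3 <- partition_aggregate_volume(dis, neu, ast, sp)
  expect_equal(p3[["in_neuron"]], p3[["total"]])
  expect_equal(p3[["in_astro"]], 0)

  expect_error(partition_aggregate_volume(dis, array(FALSE, c(2, 2, 2)), ast, sp),
               "shape")

  # conservation at voxel precision on randomized mask triples
  withr::with_seed(19, {
    for (i in 1:25) {
      dd <- array(runif(512) < runif(1, 0.05, 0.5), c(8, 8, 8))
      nn <- array(runif(512) < runif(1, 0.05, 0.5), c(8, 8, 8))
      aa <- array(runif(512) < runif(1, 0.05, 0.5), c(8, 8, 8))
      roi <- array(runif(512) < 0.7, c(8, 8, 8))
      pp <- partition_aggregate_volume(dd, nn, aa, sp, roi)
      expect_identical(pp[["in_neuron"]] + pp[["in_astro"]] + pp[["other"]],
                       pp[["total"]])
      expect_identical(pp[["total"]], sum(dd & roi) * 0.125)
    }
  })
})

test_that("reference-scaled percentages follow the published convention", {
  expect_equal(reference_scaled_percentages(28.2, 100), 28.2)
  expect_equal(reference_scaled_percentages(50, 50), 100)
  v <- c(neuron = 10, astro = 30, other = 60)
  pct <- reference_scaled_percentages(v, sum(v))
  expect_equal(sum(pct), 100)
  expect_error(reference_scaled_percentages(v, 0), "> 0")
})

test_that("neuron density converts to cells per cubic millimetre", {
  expect_equal(neuron_density(0, 1e9), 0)
  expect_equal(neuron_density(5, 1e9), 5)   # 1e9 um^3 = 1 mm^3
  expect_error(neuron_density(5, 0), "> 0")

  # phantom neurons in a half-volume ROI equal the truth computation
  ph <- generate_stack(small_spec(seed = 8, n_neurons = 5L))
  roi <- ph$truth$rois$SNc
  n_in_roi <- voxquant:::count_neurons_in_roi(ph$truth$labels$neuron, roi)
  dens <- neuron_density(n_in_roi,
                         mask_volume_um3(roi, ph$stack$voxel_spacing_um))
  # brute-force: count truth neurons whose rounded centroid voxel is in ROI
  objs <- ph$truth$objects
  neu <- objs[objs$class == "neuron", ]
  cnt <- 0L
  for (i in seq_len(nrow(neu))) {
    w <- which(ph$truth$labels$neuron == neu$label[i], arr.ind = TRUE)
    ctr <- round(colMeans(w))
    if (roi[ctr[1], ctr[2], ctr[3]]) cnt <- cnt + 1L
  }
  expect_equal(dens, cnt / mask_volume_um3(roi, ph$stack$voxel_spacing_um) * 1e9)
})

test_that("volumes scale with the voxel pitch but ratios do not", {
  ph <- generate_stack(small_spec(seed = 10))
  dis <- ph$truth$labels$aggregate > 0L
  neu <- ph$truth$labels$neuron > 0L
  ast <- ph$truth$labels$astrocyte > 0L
  p1 <- partition_aggregate_volume(dis, neu, ast, c(0.5, 0.5, 0.5))
  p2 <- partition_aggregate_volume(dis, neu, ast, c(1, 1, 1))
  expect_equal(unname(p2), unname(p1) * 8)
  pct1 <- reference_scaled_percentages(p1[1:3], p1[["total"]])
  pct2 <- reference_scaled_percentages(p2[1:3], p2[["total"]])
  expect_equal(pct1, pct2)
})

test_that("per-stack reports recover phantom truth end to end", {
  spec <- small_spec(seed = 14, shape = c(32L, 64L, 64L), n_aggregates = 30L)
  ph <- generate_stack(spec)
  dis <- as_dis <- get_channel(ph$stack, "disSOD1") >= 2000
  astro <- get_channel(ph$stack, "GFAP") >= 1000
  sl <- segment_slices(get_channel(ph$stack, "TH"), builtin_segmenter(1200))
  labs <- morph_cleanup(stitch_slices(sl, 0.25, spec$voxel_spacing_um), 8)
  rep <- quantify_stack("ph14", dis, labs, astro, ph$truth$rois,
                        spec$voxel_spacing_um)
  expect_equal(nrow(rep), 2L)
  full <- rep[rep$roi_name == "SNc+SNr", ]

  # invariants of the report row
  expect_equal(full$dis_in_neuron_um3 + full$dis_in_astro_um3 +
                 full$dis_other_um3, full$dis_total_um3)
  expect_equal(full$neuron_density_per_mm3,
               full$neuron_count / full$roi_volume_um3 * 1e9)

  # noiseless end-to-end recovery against the truth manifest
  truth <- ph$truth$totals
  expect_equal(full$dis_total_um3, truth$aggregate_volume_um3[["total"]],
               tolerance = 0.05)
  expect_equal(full$neuron_count, truth$neuron_count)
  expect_equal(full$astro_volume_um3, truth$astrocyte_volume_um3,
               tolerance = 0.15)
})
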