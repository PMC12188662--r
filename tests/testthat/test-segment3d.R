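test_that("iou matches the set-arithmetic definition and edge cases", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1] <- TRUE
  b <- matrix(FALSE, 4, 4); b[2:3, 1] <- TRUE
  expect_equal(iou(a, a), 1)                  # identical non-empty
  expect_equal(iou(a, !a & FALSE), 0)         # disjoint (b empty here)
  expect_equal(iou(a, b), 1 / 3)              # 2 px vs 2 px sharing 1 px
  empty <- matrix(FALSE, 4, 4)
  expect_equal(iou(empty, empty), 0)          # both empty -> defined as 0
  expect_error(iou(a, matrix(FALSE, 3, 4)), "shape")
})

test_that("slice segmentation honours the segmenter contract", {
  ph <- generate_stack(small_spec(seed = 2))
  th <- get_channel(ph$stack, "TH")
  # all-background channel -> all-empty labels
  bg <- array(0, dim(th))
  labs <- segment_slices(bg, builtin_segmenter(100))
  expect_true(all(vapply(labs, function(l) all(l == 0L), logical(1))))
  expect_length(labs, dim(th)[1])

  # noiseless phantom slice: one label per truth object cross-section
  labs <- segment_slices(th, builtin_segmenter(1200))
  for (z in seq_len(dim(th)[1])) {
    truth_slice <- ph$truth$labels$neuron[z, , ]
    n_truth <- length(unique(truth_slice[truth_slice > 0L]))
    n_pred <- length(unique(labs[[z]][labs[[z]] > 0L]))
    expect_equal(n_pred, n_truth)
  }

  # shape-violating and erroring adapters are wrapped with the slice index
  expect_error(segment_slices(th, function(s) matrix(0L, 2, 2)),
               "contract violated on slice 1")
  expect_error(segment_slices(th, function(s) stop("boom")),
               "failed on slice 1.*boom")
})

test_that("stitching links at IoU >= 0.25 and splits below", {
  sq <- function(y0, x0, w) {
    m <- matrix(0L, 20, 20)
    m[y0:(y0 + w - 1), x0:(x0 + w - 1)] <- 1L
    m
  }
  # identical squares: IoU 1 -> one 3D object spanning both slices
  lv <- stitch_slices(list(sq(3, 3, 6), sq(3, 3, 6)))
  expect_equal(count_instances(lv), 1L)

  # 6x6 squares offset so overlap 18 px, union 54 px: IoU = 1/3 >= 0.25
  lv2 <- stitch_slices(list(sq(3, 3, 6), sq(6, 3, 6)))
  expect_equal(count_instances(lv2), 1L)

  # overlap 12 px, union 60: IoU = 0.2 < 0.25 -> two objects
  lv3 <- stitch_slices(list(sq(3, 3, 6), sq(7, 3, 6)))
  expect_equal(count_instances(lv3), 2L)

  # exact threshold: construct IoU == 0.25 (overlap 12, union 48 needs
  # equality; use 4x6=24 px each, overlap 12, union 36 -> 1/3; instead take
  # overlap a/union b with a/b = 0.25: 6x6 squares sharing a 9-px corner:
  # union 63, 9/63 = 1/7 < 0.25 -> split)
  lv4 <- stitch_slices(list(sq(3, 3, 6), sq(8, 8, 6)))
  expect_equal(count_instances(lv4), 2L)

  expect_error(stitch_slices(list(sq(3, 3, 6)), iou_min = 1.5), "\\[0, 1\\]")
  expect_error(stitch_slices(list(sq(3, 3, 6), matrix(0L, 5, 5))), "shape")
})

test_that("a large cross-section can merge two chains (union-find linkage)", {
  m1 <- matrix(0L, 12, 12)
  m1[2:4, 2:4] <- 1L      # object A
  m1[8:10, 8:10] <- 2L    # object B
  big <- matrix(0L, 12, 12)
  big[2:10, 2:10] <- 1L   # spans both with IoU(A, big) = 9/81 < 0.25
  # raise overlap: use smaller big so IoU clears threshold for both
  big2 <- matrix(0L, 12, 12)
  big2[2:4, 2:10] <- 1L   # 3x9; IoU with A = 9/(9+27-9) = 1/3
  m2 <- matrix(0L, 12, 12)
  m2[2:4, 2:4] <- 1L
  m2[2:4, 8:10] <- 2L
  lv <- stitch_slices(list(m2, big2))
  expect_equal(count_instances(lv), 1L)  # both chains merge through big2
})

test_that("stitching is invariant to 2D label permutation and direction", {
  vol <- convex_objects_volume(3)
  labs <- slice_labels(vol)
  lv <- stitch_slices(labs)
  # permute local labels on every slice
  withr::with_seed(8, labs_perm <- lapply(labs, function(l) {
    k <- max(l)
    if (k == 0L) return(l)
    perm <- sample(k)
    out <- l; out[l > 0L] <- perm[l[l > 0L]]; out
  }))
  lv_perm <- stitch_slices(labs_perm)
  expect_true(labels_equivalent(lv$data, lv_perm$data))

  # reversing the z direction gives the mirrored labelling
  lv_rev <- stitch_slices(rev(labs))
  expect_true(labels_equivalent(lv$data[dim(vol)[1]:1, , ], lv_rev$data))
})

test_that("raising iou_min never decreases the number of 3D objects", {
  vol <- convex_objects_volume(4, n_objects = 5L)
  labs <- slice_labels(vol)
  counts <- vapply(c(0, 0.1, 0.25, 0.5, 0.75, 0.95),
                   function(t) count_instances(stitch_slices(labs, t)),
                   integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("stitched phantoms reproduce 3D 26-connected labeling exactly", {
  for (seed in 1:5) {
    vol <- convex_objects_volume(seed)
    lv <- stitch_slices(slice_labels(vol), 0.25)
    cc <- label_components(vol, 26L)
    expect_equal(count_instances(lv), count_instances(cc))
    expect_true(labels_equivalent(lv$data, cc))
  }
})

test_that("morphological cleanup fills holes and is idempotent up to relabel", {
  # solid sphere with one interior hole voxel
  vol <- array(FALSE, c(13, 13, 13))
  ctr <- c(7, 7, 7)
  for (z in 1:13) for (y in 1:13) for (x in 1:13) {
    if (sum((c(z, y, x) - ctr)^2) <= 16) vol[z, y, x] <- TRUE
  }
  vol_holed <- vol
  vol_holed[7, 7, 7] <- FALSE
  out <- morph_cleanup(array(as.integer(vol_holed), dim(vol_holed)))
  expect_equal(sum(out$data > 0L), sum(vol))  # hole refilled: +1 voxel
  expect_equal(count_instances(out), 1L)

  # empty volume stays empty
  empty <- morph_cleanup(array(0L, c(4, 4, 4)))
  expect_equal(count_instances(empty), 0L)

  # idempotence on phantom-derived labels
  ph <- generate_stack(small_spec(seed = 9))
  sl <- segment_slices(get_channel(ph$stack, "TH"), builtin_segmenter(1200))
  lv <- morph_cleanup(stitch_slices(sl, 0.25, ph$stack$voxel_spacing_um), 8)
  lv2 <- morph_cleanup(lv, 8)
  expect_true(labels_equivalent(lv$data, lv2$data))
})

test_that("instance counting and the builtin segmenter behave as documented", {
  expect_equal(count_instances(array(0L, c(2, 2, 2))), 0L)
  lab <- array(0L, c(2, 4, 4))
  lab[1, 1, 1] <- 3L
  lab[2, 3, 3] <- 7L
  expect_equal(count_instances(lab), 2L)  # labels {3, 7} present

  # noiseless phantom: full builtin path recovers the exact neuron count
  ph <- generate_stack(small_spec(seed = 12, n_neurons = 4L))
  sl <- segment_slices(get_channel(ph$stack, "TH"), builtin_segmenter(1200))
  lv <- morph_cleanup(stitch_slices(sl, 0.25, ph$stack$voxel_spacing_um), 8)
  expect_equal(count_instances(lv), 4L)
})
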