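test_that("display-window rescaling maps the window endpoints and clips", {
  v <- array(c(0, 115, 400, 700, 1200), c(1, 1, 5))
  out <- rescale_window(v, 115, 700)
  expect_equal(out[1, 1, 1], 0)          # below window clips to 0
  expect_equal(out[1, 1, 2], 0)          # low endpoint -> 0
  expect_equal(out[1, 1, 4], 65535)      # high endpoint -> full scale
  expect_equal(out[1, 1, 5], 65535)      # above window clips
  expect_error(rescale_window(v, 700, 115), "low < high")
  expect_error(rescale_window(v, 115, 115), "low < high")

  # identity window up to dtype scaling
  v2 <- array(runif(64, 0, 65535), c(4, 4, 4))
  expect_equal(rescale_window(v2, 0, 65535), v2)

  # random volume equals the per-voxel closed form
  withr::with_seed(11, {
    v3 <- array(runif(64, 0, 1000), c(4, 4, 4))
    lo <- 115; hi <- 700
    oracle <- array(vapply(as.numeric(v3), function(x) {
      min(max((x - lo) / (hi - lo), 0), 1) * 65535
    }, numeric(1)), dim(v3))
    expect_equal(rescale_window(v3, lo, hi), oracle)
  })
  # monotone non-decreasing
  xs <- sort(runif(50, 0, 1000))
  ys <- rescale_window(array(xs, c(1, 1, 50)), 115, 700)
  expect_true(all(diff(as.numeric(ys)) >= 0))
})

test_that("manual threshold uses the >= convention and validates its range", {
  withr::with_seed(5, {
    v <- array(sample.int(200, 125, replace = TRUE), c(5, 5, 5))
    t <- 77
    m <- manual_threshold(v, t)
    # brute-force voxel scan
    expect_equal(sum(m), sum(vapply(as.numeric(v), function(x) x >= t,
                                    logical(1))))
    expect_true(all(v[as_mask <- unclass(m)] >= t))
  })
  expect_true(all(manual_threshold(array(0, c(2, 2, 2)), 0)))
  expect_error(manual_threshold(array(1, c(2, 2, 2)), 65536), "range")
  expect_error(manual_threshold(array(1, c(2, 2, 2)), -5), "range")
  tr <- operation_trace(manual_threshold(array(1, c(2, 2, 2)), 1))
  expect_equal(tr[[1]]$op, "manual_threshold")
})

test_that("thresholding commutes with window rescaling when t co-transforms", {
  withr::with_seed(21, {
    v <- array(runif(250, 0, 1000), c(5, 5, 10))
    lo <- 115; hi <- 700
    for (t in c(150, 400, 699)) {
      t_mapped <- (t - lo) / (hi - lo) * 65535
      m_direct <- manual_threshold(v, t)
      m_window <- manual_threshold(rescale_window(v, lo, hi), t_mapped)
      expect_identical(unclass(m_direct)[v > lo & v < hi],
                       unclass(m_window)[v > lo & v < hi])
    }
  })
})

test_that("Yen threshold separates a two-level image and maximizes the criterion", {
  v <- array(rep(c(10, 200), each = 500), c(10, 10, 10))
  t <- yen_threshold(v)
  expect_gt(as.numeric(t), 10)
  expect_lt(as.numeric(t), 200)
  m <- manual_threshold(v, as.numeric(t))
  expect_equal(sum(m), 500)

  expect_error(yen_threshold(array(7, c(3, 3, 3))), "degenerate|constant")

  # exhaustive argmax oracle on random 8-bit-style volumes
  withr::with_seed(31, {
    for (rep in 1:6) {
      v <- array(c(round(rnorm(300, 60, 18)), round(rnorm(200, 170, 25))),
                 c(10, 10, 5))
      v <- pmin(pmax(v, 0), 255)
      got <- as.numeric(yen_threshold(v, n_bins = 256L))
      h <- oracle_histogram(as.numeric(v), 256L)
      expect_equal(got, oracle_yen(h$counts, h$centers))
    }
  })
})

test_that("masked Yen thresholding ignores voxels outside the mask", {
  withr::with_seed(13, {
    v <- array(c(round(rnorm(200, 50, 10)), round(rnorm(312, 180, 15))),
               c(8, 8, 8))
    roi <- array(FALSE, c(8, 8, 8))
    roi[1:4, , ] <- TRUE
    t1 <- yen_threshold(v, mask = roi)
    v2 <- v
    v2[!roi] <- 9999  # scrambling outside voxels must not change the result
    expect_equal(as.numeric(yen_threshold(v2, mask = roi)), as.numeric(t1))
  })
})

test_that("triangle thresholding is available as the logged alternative", {
  withr::with_seed(41, {
    v <- array(c(round(rnorm(900, 40, 10)), round(rnorm(100, 200, 10))),
               c(10, 10, 10))
    ty <- yen_threshold(v, method = "yen")
    tt <- yen_threshold(v, method = "triangle")
    expect_equal(attr(tt, "method"), "triangle")
    # both must separate the dominant background from the bright tail
    expect_gt(as.numeric(tt), 40)
    expect_gt(as.numeric(ty), 40)
  })
})

test_that("gaussian blur is the identity at sigma 0 and conserves intensity", {
  v <- array(runif(4 * 6 * 5), c(4, 6, 5))
  expect_identical(gaussian_blur(v, 0), v)
  expect_error(gaussian_blur(v, -1), ">= 0")

  # interior delta impulse: result is the separable kernel, unit sum
  imp <- array(0, c(21, 21, 21))
  imp[11, 11, 11] <- 1
  b <- gaussian_blur(imp, 1.2, c(1, 1, 1))
  expect_equal(sum(b), 1, tolerance = 1e-3)
  expect_equal(which.max(b), which.max(imp))
})

test_that("anisotropic spacing maps sigma_um to per-axis voxel sigmas", {
  # sigma 1 um on (1, 0.5, 0.5) um spacing = voxel sigmas (1, 2, 2)
  imp <- array(0, c(31, 31, 31))
  imp[16, 16, 16] <- 1
  b <- gaussian_blur(imp, 1, c(1, 0.5, 0.5))
  sd_axis <- function(a, axis) {
    w <- apply(a, axis, sum)
    sqrt(sum(((seq_along(w)) - 16)^2 * w))
  }
  expect_equal(sd_axis(b, 1), 1, tolerance = 0.01)
  expect_equal(sd_axis(b, 2), 2, tolerance = 0.01)
  expect_equal(sd_axis(b, 3), 2, tolerance = 0.01)

  # equals a direct separable 1-D convolution oracle on a random volume
  withr::with_seed(17, {
    v <- array(runif(13 * 11 * 9), c(13, 11, 9))
    got <- gaussian_blur(v, 1, c(1, 0.5, 0.5))
    kern <- function(sig) {
      r <- max(1L, ceiling(3 * sig)); x <- (-r):r
      k <- exp(-x^2 / (2 * sig^2)); k / sum(k)
    }
    conv_axis_oracle <- function(a, k, axis) {
      r <- (length(k) - 1L) / 2L
      out <- array(0, dim(a))
      d <- dim(a)
      for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
        acc <- 0
        for (o in -r:r) {
          idx <- c(i, j, l)
          idx[axis] <- min(max(idx[axis] + o, 1), d[axis])  # replicate edge
          acc <- acc + k[o + r + 1] * a[idx[1], idx[2], idx[3]]
        }
        out[i, j, l] <- acc
      }
      out
    }
    oracle <- conv_axis_oracle(v, kern(1), 1)
    oracle <- conv_axis_oracle(oracle, kern(2), 2)
    oracle <- conv_axis_oracle(oracle, kern(2), 3)
    expect_equal(got, oracle, tolerance = 1e-12)
  })
})

test_that("background subtraction is a clipped shift", {
  expect_true(all(subtract_background(array(10, c(2, 2, 2)), 25) == 0))
  v <- array(runif(27, 0, 300), c(3, 3, 3))
  expect_identical(subtract_background(v, 0), v)
  oracle <- array(pmax(as.numeric(v) - 25, 0), dim(v))
  expect_equal(subtract_background(v, 25), oracle)
  expect_error(subtract_background(v, -1), ">= 0")
})

test_that("size filtering removes components strictly below the physical cutoff", {
  # one isolated voxel at 0.5 um pitch is 0.125 um^3 -> removed at 1 um^3
  m <- array(FALSE, c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  out <- remove_small_objects(m, 1, c(0.5, 0.5, 0.5))
  expect_equal(sum(out), 0)

  # cutoff 0 is the identity
  expect_equal(as_vec <- sum(remove_small_objects(m, 0, c(0.5, 0.5, 0.5))), 1)

  # random blob field equals a brute-force component-volume filter
  withr::with_seed(23, {
    mm <- array(runif(16 * 20 * 20) < 0.25, c(16, 20, 20))
    cutoff <- 0.8
    sp <- c(0.5, 0.5, 0.5)
    got <- remove_small_objects(mm, cutoff, sp)
    lab <- label_components(mm, 26L)
    keep <- array(FALSE, dim(mm))
    for (id in seq_len(max(lab))) {
      vox <- lab == id
      if (sum(vox) * prod(sp) >= cutoff) keep <- keep | vox
    }
    expect_equal(unclass(got)[seq_along(keep)], as.logical(keep))
  })
})

test_that("the astrocyte channel pipeline records its operation trace", {
  ph <- generate_stack(small_spec(seed = 6, n_astrocytes = 3L, noise_sd = 20,
                                  blur_sigma_um = 0.25))
  gfap <- get_channel(ph$stack, "GFAP")
  m <- preprocess_astro_channel(gfap, ph$stack$voxel_spacing_um)
  ops <- vapply(operation_trace(m), `[[`, character(1), "op")
  expect_equal(ops, c("manual_threshold", "auto_threshold", "mask_smooth",
                      "remove_small_objects"))
  # on noisy, PSF-blurred rendering the auto-threshold admits part of the
  # blur halo, so the measured volume overshoots truth by a bounded margin
  vol <- mask_volume_um3(m, ph$stack$voxel_spacing_um)
  truth <- ph$truth$totals$astrocyte_volume_um3
  expect_gt(vol, truth * 0.7)
  expect_lt(vol, truth * 1.8)

  # on a noiseless, unblurred phantom the recovered volume is within 15%
  ph0 <- generate_stack(small_spec(seed = 6, n_astrocytes = 3L))
  m0 <- preprocess_astro_channel(get_channel(ph0$stack, "GFAP"),
                                 ph0$stack$voxel_spacing_um)
  expect_equal(mask_volume_um3(m0, ph0$stack$voxel_spacing_um),
               ph0$truth$totals$astrocyte_volume_um3, tolerance = 0.15)

  # the blur-before-threshold alternative is available and traced
  mi <- preprocess_astro_channel(gfap, ph$stack$voxel_spacing_um,
                                 smooth = "intensity")
  expect_true(any(vapply(operation_trace(mi), function(o)
    identical(o$smooth, "intensity"), logical(1))))
})
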