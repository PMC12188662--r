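test_that("phantom spec validation enforces the generator invariants", {
  expect_error(phantom_spec(aggregate_placement = c(0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(phantom_spec(voxel_spacing_um = c(0.5, 0, 0.5)), "positive")
  expect_error(phantom_spec(n_neurons = -1), ">= 0")
  expect_error(phantom_spec(shape = c(0, 10, 10)), "positive")
})

test_that("an empty phantom is all background with zero truth totals", {
  spec <- small_spec(n_neurons = 0L, n_astrocytes = 0L, n_aggregates = 0L)
  ph <- generate_stack(spec)
  expect_equal(ph$truth$totals$aggregate_volume_um3[["total"]], 0)
  expect_equal(ph$truth$totals$neuron_count, 0L)
  expect_equal(ph$truth$totals$astrocyte_volume_um3, 0)
  expect_equal(nrow(ph$truth$objects), 0L)
  # every channel is flat at its background level (noiseless rendering)
  for (k in seq_along(ph$stack$channel_names)) {
    lev <- spec$intensity_levels[[ph$stack$channel_names[k]]]
    expect_true(all(ph$stack$data[k, , , ] == lev[["bg"]]))
  }
})

test_that("truth manifest matches brute-force voxel membership of truth labels", {
  spec <- phantom_spec(shape = c(64L, 128L, 128L),
                       voxel_spacing_um = c(0.5, 0.5, 0.5),
                       n_neurons = 5L, n_astrocytes = 3L, n_aggregates = 40L,
                       aggregate_placement = c(0.1, 0.3, 0.6),
                       noise_sd = 0, blur_sigma_um = 0, seed = 7L)
  ph <- generate_stack(spec)
  tr <- ph$truth
  voxvol <- voxel_volume_um3(spec$voxel_spacing_um)
  agg <- tr$objects[tr$objects$class == "aggregate", ]
  expect_equal(nrow(agg), 40L)

  # recompute each aggregate's volume and host compartment from the label
  # volumes alone, one object at a time
  recomputed <- vapply(seq_len(nrow(agg)), function(i) {
    lab <- agg$label[i]
    vol <- sum(tr$labels$aggregate == lab) * voxvol
    ctr <- c(agg$centroid_z[i], agg$centroid_y[i], agg$centroid_x[i])
    host <- if (tr$labels$neuron[ctr[1], ctr[2], ctr[3]] > 0L) "neuron"
            else if (tr$labels$astrocyte[ctr[1], ctr[2], ctr[3]] > 0L) "astrocyte"
            else "other"
    c(vol = vol, host_matches = as.numeric(identical(host, agg$compartment[i])))
  }, numeric(2))
  expect_equal(unname(recomputed["vol", ]), agg$volume_um3)
  expect_true(all(recomputed["host_matches", ] == 1))

  # per-object volumes sum to the per-class compartment totals exactly
  by_comp <- tapply(agg$volume_um3, factor(agg$compartment,
                    levels = c("neuron", "astrocyte", "other")), sum)
  by_comp[is.na(by_comp)] <- 0
  expect_equal(as.numeric(by_comp),
               unname(tr$totals$aggregate_volume_um3[c("neuron", "astrocyte",
                                                       "other")]))
  expect_equal(sum(by_comp), tr$totals$aggregate_volume_um3[["total"]])
})

test_that("identical spec and seed give bit-identical phantoms", {
  spec <- small_spec(seed = 7, noise_sd = 25, blur_sigma_um = 0.25)
  expect_identical(generate_stack(spec), generate_stack(spec))
})

test_that("infeasible packing raises a placement error, not truncation", {
  spec <- phantom_spec(shape = c(6L, 10L, 10L), n_neurons = 40L,
                       n_astrocytes = 0L, n_aggregates = 0L, seed = 1)
  expect_error(generate_stack(spec), class = "voxquant_placement_error")
})

test_that("cohort group multipliers are realized in true aggregate volume", {
  base <- small_spec(seed = 1, shape = c(24L, 56L, 56L), n_aggregates = 25L)
  co <- generate_cohort(base, c(disease = 4, control = 1), n_per_group = 8L,
                        seed = 3L)
  means <- tapply(co$table$true_aggregate_volume_um3, co$table$group, mean)
  ratio <- means[["disease"]] / means[["control"]]
  expect_gt(ratio, 4 * 0.75)
  expect_lt(ratio, 4 * 1.25)

  # null effect: equal multipliers differ only by sampling noise
  co0 <- generate_cohort(base, c(a = 1, b = 1), n_per_group = 6L, seed = 9L)
  m0 <- tapply(co0$table$true_aggregate_volume_um3, co0$table$group, mean)
  expect_lt(abs(m0[["a"]] / m0[["b"]] - 1), 0.5)

  # determinism of the whole cohort
  co2 <- generate_cohort(base, c(disease = 4, control = 1), n_per_group = 8L,
                         seed = 3L)
  expect_identical(co$table, co2$table)
  expect_error(generate_cohort(base, c(a = 1), n_per_group = 0L), ">= 1")
  expect_error(generate_cohort(base, c(a = -2), n_per_group = 2L), "> 0")
})

test_that("neurochemistry tables are seeded, truncated and exact when noiseless", {
  gm <- list(g1 = c(10, 2, 3), g2 = c(8, 1, 2))
  t0 <- generate_neurochem_table(gm, noise_sd = 0, n_per_group = 4L, seed = 3L)
  expect_equal(t0$dopamine_ng_per_mg, rep(c(10, 8), each = 4))
  expect_equal(t0$dopac_ng_per_mg, rep(c(2, 1), each = 4))
  expect_false(any(t0$truncated))
  # noiseless table feeds an exact turnover downstream
  expect_equal(unique(dopamine_turnover(t0$dopamine_ng_per_mg[1:4],
                                        t0$dopac_ng_per_mg[1:4],
                                        t0$hva_ng_per_mg[1:4])), 0.5)
  t1 <- generate_neurochem_table(gm, noise_sd = 5, n_per_group = 10L, seed = 3L)
  expect_true(all(t1$dopamine_ng_per_mg >= 0))
  expect_identical(t1, generate_neurochem_table(gm, noise_sd = 5,
                                                n_per_group = 10L, seed = 3L))
  expect_error(generate_neurochem_table(list(g = c(-1, 2, 3))), ">= 0")
})
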