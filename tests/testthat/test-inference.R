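test_that("patch fusion averages with triangular centre weights", {
  v <- volume(array(0, c(20, 20, 20)), spacing = 1)
  M <- 8
  pr <- array(0, c(2, M, M, M)); pr[2, , , ] <- 0.7; pr[1, , , ] <- 0.3
  f1 <- fuse_patch_predictions(list(list(probs = pr, center_mm = c(9.5, 9.5, 9.5),
                                         spacing = 1)), v, 2, M)
  covered <- as.vector(f1$weight > 0)
  pm <- matrix(f1$probs, 2)
  expect_true(all(abs(pm[2, covered] - 0.7) < 1e-12))
  expect_true(all(pm[1, !covered] == 1))           # background outside coverage
  # identical overlapping patches fuse idempotently
  f2 <- fuse_patch_predictions(list(
    list(probs = pr, center_mm = c(9.5, 9.5, 9.5), spacing = 1),
    list(probs = pr, center_mm = c(9.5, 9.5, 9.5), spacing = 1)), v, 2, M)
  expect_equal(f2$probs, f1$probs, tolerance = 1e-12)
  # conflicting constant patches: hand-computed weighted mean on a 1D slice
  prB <- pr; prB[2, , , ] <- 0.2; prB[1, , , ] <- 0.8
  f3 <- fuse_patch_predictions(list(
    list(probs = pr, center_mm = c(8.5, 9.5, 9.5), spacing = 1),
    list(probs = prB, center_mm = c(10.5, 9.5, 9.5), spacing = 1)), v, 2, M)
  wA <- 1 - abs(9 - 8.5) / 4                        # voxel position x = 9
  wB <- 1 - abs(9 - 10.5) / 4
  expect_equal(matrix(f3$probs, 2)[2, 10 + 20 * (9 + 20 * 9)],
               (wA * 0.7 + wB * 0.2) / (wA + wB), tolerance = 1e-9)
})

test_that("oracle passthrough reconstructs the phantom through the full pipeline", {
  spec <- default_cmf_spec(c(64, 64, 64), seed = 3)
  ph <- generate_phantom(spec)
  pyr <- scale_pyramid_spec(depth = 2, matrix = 16)
  om <- oracle_stack(ph$labels, pyr, small = small_flags(spec))
  res <- predict_volume(om, ph$volume, inference_config(seed = 4))
  rep <- evaluate_segmentation(res$labels, ph$labels)
  expect_true(all(rep$dsc >= 0.99))
  # same seed, same tree, same output
  res2 <- predict_volume(om, ph$volume, inference_config(seed = 4))
  expect_identical(res$labels$data, res2$labels$data)
})

test_that("exhaustive tiling is seed-independent and exact for the oracle", {
  spec <- default_cmf_spec(c(48, 48, 48), seed = 8)
  ph <- generate_phantom(spec)
  pyr <- scale_pyramid_spec(depth = 2, matrix = 16)
  om <- oracle_stack(ph$labels, pyr, small = small_flags(spec))
  e1 <- predict_volume(om, ph$volume, inference_config(seed = 1, exhaustive = TRUE))
  e2 <- predict_volume(om, ph$volume, inference_config(seed = 99, exhaustive = TRUE))
  expect_identical(e1$labels$data, e2$labels$data)
  expect_true(all(evaluate_segmentation(e1$labels, ph$labels)$dsc >= 0.99))
})

test_that("an all-air volume yields an all-background label map", {
  pyr <- scale_pyramid_spec(depth = 2, matrix = 16)
  lab0 <- label_map(array(0L, c(48, 48, 48)), n_labels = 2, spacing = 1)
  om <- oracle_stack(lab0, pyr, group_labels = 1:2)
  air <- volume(array(-1024, c(48, 48, 48)), spacing = 1)
  res <- predict_volume(om, air, inference_config(seed = 1))
  expect_true(all(res$labels$data == 0L))
})

test_that("raising the promising threshold never increases visited patches", {
  spec <- default_cmf_spec(c(48, 48, 48), seed = 9)
  ph <- generate_phantom(spec)
  pyr <- scale_pyramid_spec(depth = 2, matrix = 16)
  om <- oracle_stack(ph$labels, pyr, small = small_flags(spec))
  n_low <- predict_volume(om, ph$volume,
                          inference_config(seed = 2, promising_threshold = 0.3))$n_patches
  n_high <- predict_volume(om, ph$volume,
                           inference_config(seed = 2, promising_threshold = 0.97))$n_patches
  expect_true(all(n_high <= n_low))
})

test_that("multi-group prediction merges label groups over a shared background", {
  spec <- default_cmf_spec(c(48, 48, 48), seed = 10)
  ph <- generate_phantom(spec)
  pyr <- scale_pyramid_spec(depth = 2, matrix = 16)
  sf <- small_flags(spec)
  g1 <- oracle_stack(ph$labels, pyr, group_labels = c(1, 2, 3), small = sf[1:3])
  lab2 <- ph$labels
  lab2$data[!(lab2$data %in% c(4L, 5L, 6L))] <- 0L
  g2 <- oracle_stack(lab2, pyr, group_labels = c(4, 5, 6), small = sf[4:6])
  lab1 <- ph$labels
  lab1$data[!(lab1$data %in% c(1L, 2L, 3L))] <- 0L
  g1$labels <- lab1
  res <- predict_volume(list(g1, g2), ph$volume, inference_config(seed = 5))
  rep <- evaluate_segmentation(res$labels, ph$labels)
  expect_true(all(rep$dsc >= 0.95))
})
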