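test_that("categorical loss equals direct per-voxel summation", {
  ms <- tiny_stack_model()                         # labels 1,2 large; 3 small
  set.seed(11)
  out <- array(rnorm(ms$out_channels * 6^3), c(ms$out_channels, 6, 6, 6))
  lab <- array(sample(0:3, 6^3, TRUE), c(6, 6, 6))
  direct <- 0
  for (i in seq_len(6^3)) {
    idx <- arrayInd(i, c(6, 6, 6))
    z <- out[1:3, idx[1], idx[2], idx[3]]
    t <- if (lab[i] %in% c(1, 2)) lab[i] + 1 else 1  # small label counts as bg
    direct <- direct + log(sum(exp(z))) - z[t]
  }
  expect_equal(large_label_loss(out, lab, ms), direct / 6^3, tolerance = 1e-10)
})

test_that("uniform logits give ln(number of softmax classes)", {
  ms <- tiny_stack_model()
  lab <- array(sample(0:3, 6^3, TRUE), c(6, 6, 6))
  out <- array(0, c(ms$out_channels, 6, 6, 6))
  expect_equal(large_label_loss(out, lab, ms), log(3), tolerance = 1e-12)
})

test_that("near-one-hot logits drive the categorical loss to zero", {
  ms <- tiny_stack_model()
  lab <- array(sample(c(0L, 1L, 2L), 6^3, TRUE), c(6, 6, 6))
  out <- array(0, c(ms$out_channels, 6, 6, 6))
  for (i in seq_len(6^3)) {
    idx <- arrayInd(i, c(6, 6, 6))
    out[if (lab[i] > 0) lab[i] + 1 else 1, idx[1], idx[2], idx[3]] <- 50
  }
  expect_lt(large_label_loss(out, lab, ms), 1e-10)
})

test_that("top-K loss equals the sort-based brute force", {
  ms <- tiny_stack_model()
  set.seed(12)
  out <- array(rnorm(ms$out_channels * 6^3), c(ms$out_channels, 6, 6, 6))
  lab <- array(sample(0:3, 6^3, TRUE), c(6, 6, 6))
  z <- out[4, , , ]                                # small label 3's channel
  t <- as.numeric(lab == 3)
  bce <- pmax(z, 0) - z * t + log1p(exp(-abs(z)))
  for (K in c(1, 10, 6^3)) {
    brute <- mean(sort(as.vector(bce), decreasing = TRUE)[seq_len(K)])
    expect_equal(small_label_topk_loss(out, lab, ms, K), brute, tolerance = 1e-12)
  }
  # K = M^3 reduces to the full-patch mean BCE
  expect_equal(small_label_topk_loss(out, lab, ms, 6^3), mean(bce), tolerance = 1e-12)
  expect_error(small_label_topk_loss(out, lab, ms, 0), "K must")
  expect_error(small_label_topk_loss(out, lab, ms, 6^3 + 1), "K must")
})

test_that("constant per-voxel loss is K-invariant", {
  ms <- tiny_stack_model()
  out <- array(0, c(ms$out_channels, 6, 6, 6))
  lab <- array(0L, c(6, 6, 6))
  for (K in c(1, 17, 100))
    expect_equal(small_label_topk_loss(out, lab, ms, K), log(2), tolerance = 1e-12)
})

test_that("top-K selection is invariant to voxel permutation", {
  ms <- tiny_stack_model()
  set.seed(13)
  out <- array(rnorm(ms$out_channels * 4^3), c(ms$out_channels, 4, 4, 4))
  lab <- array(sample(0:3, 4^3, TRUE), c(4, 4, 4))
  v0 <- small_label_topk_loss(out, lab, ms, 7)
  perm <- sample(4^3)
  outp <- array(matrix(out, ms$out_channels)[, perm], c(ms$out_channels, 4, 4, 4))
  labp <- array(as.vector(lab)[perm], c(4, 4, 4))
  expect_equal(small_label_topk_loss(outp, labp, ms, 7), v0, tolerance = 1e-12)
})

test_that("loss regime decomposes by label designation", {
  # all labels large: total reduces to the categorical term
  pyr <- scale_pyramid_spec(depth = 1, matrix = 8)
  all_large <- model_stack_init(pyr, c(1, 2, 3), small = rep(FALSE, 3),
                                features = c(4, 8), seed = 1)
  set.seed(14)
  out <- array(rnorm(all_large$out_channels * 5^3), c(all_large$out_channels, 5, 5, 5))
  lab <- array(sample(0:3, 5^3, TRUE), c(5, 5, 5))
  expect_equal(small_label_topk_loss(out, lab, all_large, 10), 0)
  # all labels small: categorical term sees only background
  all_small <- model_stack_init(pyr, c(1, 2, 3), small = rep(TRUE, 3),
                                features = c(4, 8), seed = 1)
  expect_equal(large_label_loss(array(0, dim(out)), lab, all_small), 0,
               tolerance = 1e-12)                  # ln(1) for the bg-only softmax
})

test_that("short toy training descends and is seed-reproducible", {
  spec <- phantom_spec(c(48, 48, 48), 1,
    list(structure_blueprint(1L, "ellipsoid", c(14, 18), c(900, 1100))),
    noise_sigma_hu = 10, seed = 21)
  ph <- generate_phantom(spec)
  pyr <- scale_pyramid_spec(depth = 2, matrix = 16)
  cfg <- train_config(patch_budget = 96, batch_size = 4, seed = 5,
                      small = FALSE, augment = NULL)
  p1 <- train_stack(list(ph), cfg, pyr)
  tr <- attr(p1, "loss_trace")
  expect_lt(mean(utils::tail(tr$loss, 3)), mean(utils::head(tr$loss, 3)))
  p2 <- train_stack(list(ph), cfg, pyr)
  expect_identical(p1$levels[[1]]$final$W, p2$levels[[1]]$final$W)
  expect_identical(attr(p2, "loss_trace")$loss, tr$loss)
})

test_that("non-contiguous label groups map foreign labels to background", {
  pyr <- scale_pyramid_spec(depth = 1, matrix = 8)
  ms <- model_stack_init(pyr, c(1, 2, 3, 6), small = rep(FALSE, 4),
                         features = c(4, 8), seed = 1)
  lab <- array(c(0L, 1L, 4L, 5L, 6L, 2L, 3L, 0L), c(2, 2, 2))
  out <- array(0, c(ms$out_channels, 2, 2, 2))
  # labels 4 and 5 are not in the group: they count as background; the
  # softmax set has 5 classes (bg + 4 large)
  expect_equal(large_label_loss(out, lab, ms), log(5), tolerance = 1e-12)
  # a perfect prediction distinguishing group labels only
  for (i in seq_len(8)) {
    idx <- arrayInd(i, c(2, 2, 2))
    chn <- match(lab[i], c(1, 2, 3, 6))
    out[if (is.na(chn)) 1 else chn + 1, idx[1], idx[2], idx[3]] <- 60
  }
  expect_lt(large_label_loss(out, lab, ms), 1e-10)
})
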