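test_that("all four metrics match exhaustive brute force on random masks", {
  set.seed(20)
  spacings <- list(c(1, 1, 1), c(0.5, 0.5, 0.7), c(2, 1, 1.5), c(0.8, 1.2, 1))
  worst <- c(dsc = 0, sdsc = 0, hd = 0, assd = 0)
  for (trial in 1:50) {
    sp <- spacings[[1 + trial %% 4]]
    A <- random_blob_mask()
    B <- random_blob_mask()
    if (!any(A) || !any(B)) next
    bf <- bf_metrics(A, B, sp)
    worst["dsc"] <- max(worst["dsc"], abs(dsc(A, B) - bf$dsc))
    worst["sdsc"] <- max(worst["sdsc"], abs(surface_dsc(A, B, 1, sp) - bf$surface_dsc))
    worst["hd"] <- max(worst["hd"], abs(hd95(A, B, 95, sp) - bf$hd95))
    worst["assd"] <- max(worst["assd"], abs(assd(A, B, sp) - bf$assd))
  }
  expect_lt(worst["dsc"], 1e-12)
  expect_lt(worst["sdsc"], 1e-12)
  expect_lt(worst["hd"], 1e-9)
  expect_lt(worst["assd"], 1e-9)
})

test_that("worked metric cases behave as the definitions demand", {
  A <- cube_mask(c(12, 12, 12), c(4, 4, 4), 4)
  Ashift <- cube_mask(c(12, 12, 12), c(5, 4, 4), 4)
  # a 1-voxel displacement at 1 mm spacing lies within the 1 mm tolerance
  expect_equal(surface_dsc(A, Ashift, 1, c(1, 1, 1)), 1.0)
  # identical masks: perfect overlap, zero distances
  expect_equal(dsc(A, A), 1)
  expect_equal(surface_dsc(A, A), 1)
  expect_equal(hd95(A, A), 0)
  expect_equal(assd(A, A), 0)
  # two single-voxel masks 3 voxels apart
  P <- array(FALSE, c(10, 10, 10)); P[2, 2, 2] <- TRUE
  Q <- array(FALSE, c(10, 10, 10)); Q[5, 2, 2] <- TRUE
  expect_equal(hd95(P, Q), 3)
  expect_equal(assd(P, Q), 3)
  expect_equal(dsc(P, Q), 0)
  expect_equal(surface_dsc(P, Q, 1), 0)
  # nested boxes: 2x2x2 inside 2x2x4
  A2 <- cube_mask(c(8, 8, 8), c(1, 1, 1), 2)
  B2 <- array(FALSE, c(8, 8, 8)); B2[1:2, 1:2, 1:4] <- TRUE
  expect_equal(dsc(A2, B2), 2 * 8 / (8 + 16))
})

test_that("empty masks follow the declared conventions", {
  E <- array(FALSE, c(6, 6, 6))
  A <- cube_mask(c(6, 6, 6), c(2, 2, 2), 2)
  expect_equal(dsc(E, E), 1)
  expect_equal(dsc(A, E), 0)
  expect_equal(surface_dsc(E, E), 1)
  expect_equal(surface_dsc(A, E), 0)
  expect_warning(h <- hd95(A, E), "empty")
  expect_true(is.na(h))
  expect_warning(a <- assd(A, E), "empty")
  expect_true(is.na(a))
})

test_that("metrics are symmetric and translation invariant", {
  set.seed(21)
  A <- random_blob_mask(c(20, 20, 20))
  B <- random_blob_mask(c(20, 20, 20))
  sp <- c(1, 0.8, 1.2)
  expect_equal(assd(A, B, sp), assd(B, A, sp))
  expect_equal(hd95(A, B, 95, sp), hd95(B, A, 95, sp))
  expect_equal(dsc(A, B), dsc(B, A))
  # shift both masks by one voxel inside a larger grid
  emb <- function(m, off) {
    out <- array(FALSE, c(26, 26, 26))
    out[off + 1:20, off + 1:20, off + 1:20] <- m
    out
  }
  expect_equal(assd(emb(A, 1), emb(B, 1), sp), assd(emb(A, 4), emb(B, 4), sp),
               tolerance = 1e-12)
  # surface dsc is monotone in the tolerance
  expect_lte(surface_dsc(A, B, 0, sp), surface_dsc(A, B, 1, sp))
})

test_that("per-label evaluation composes the single-mask metrics", {
  set.seed(22)
  mk <- function() {
    arr <- array(0L, c(16, 16, 16))
    arr[3:6, 3:6, 3:6] <- 1L
    arr[10:14, 3:7, 9:12] <- 2L
    arr[9:11, 11:13, 3:4] <- 3L
    arr
  }
  ref <- label_map(mk(), spacing = c(1, 1, 1))
  pred_arr <- mk()
  pred_arr[pred_arr == 3L] <- 0L                    # drop one label entirely
  pred_arr[4:7, 3:6, 3:6] <- 1L                     # shift label 1 by one voxel
  pred <- label_map(pred_arr, n_labels = 3, spacing = c(1, 1, 1))
  rep <- suppressWarnings(evaluate_segmentation(pred, ref))
  expect_equal(nrow(rep), 3)
  for (id in 1:2) {
    expect_equal(rep$dsc[id], dsc(pred$data == id, ref$data == id))
    expect_equal(rep$hd95_mm[id], hd95(pred$data == id, ref$data == id))
    expect_equal(rep$assd_mm[id], assd(pred$data == id, ref$data == id))
  }
  expect_equal(rep$dsc[3], 0)
  expect_true(is.na(rep$hd95_mm[3]) && is.na(rep$assd_mm[3]))
  expect_equal(rep$n_pred[3], 0)
  # self comparison is perfect
  self <- evaluate_segmentation(ref, ref)
  expect_true(all(self$dsc == 1) && all(self$surface_dsc == 1) &&
              all(self$hd95_mm == 0) && all(self$assd_mm == 0))
})
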