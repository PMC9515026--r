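test_that("channel contract holds across depths and label counts", {
  for (n_lab in c(1, 3, 5)) {
    for (D in c(1, 2, 3)) {
      pyr <- scale_pyramid_spec(depth = D, matrix = 8)
      ms <- model_stack_init(pyr, seq_len(n_lab), features = c(4, 8, 8), seed = 1)
      expect_equal(ms$out_channels, n_lab + 1 + 8)
      expect_equal(ms$levels[[1]]$spec$in_channels, 11L)
      if (D > 1)
        for (i in 2:D)
          expect_equal(ms$levels[[i]]$spec$in_channels, 11L + ms$out_channels)
    }
  }
})

test_that("a zeroed classifier head yields uniform softmax and 0.5 sigmoids", {
  ms <- tiny_stack_model()
  for (i in seq_along(ms$levels)) {
    ms$levels[[i]]$final$W[] <- 0
    ms$levels[[i]]$final$b[] <- 0
  }
  v <- volume(array(0, c(40, 40, 40)), spacing = 1)
  sc <- compute_scales(ms$pyramid, c(40, 40, 40))
  st <- extract_stack(v, c(19.5, 19.5, 19.5), sc, matrix = 8)
  outs <- forward_stack(ms, st)
  expect_true(all(abs(outs[[1]][seq_len(ms$n_logits), , , ]) < 1e-12))
  p <- logits_to_probs(outs[[1]], ms)
  expect_equal(p[1:3, 1, 1, 1], rep(1 / 3, 3))     # bg + 2 large labels
  expect_equal(p[4, 1, 1, 1], 0.5)                 # small label sigmoid(0)
})

test_that("softmax probabilities normalise and sigmoids stay in range", {
  ms <- tiny_stack_model()
  set.seed(4)
  out <- array(rnorm(ms$out_channels * 5^3, 0, 3), c(ms$out_channels, 5, 5, 5))
  p <- logits_to_probs(out, ms)
  sums <- apply(p[1:3, , , , drop = FALSE], c(2, 3, 4), sum)
  expect_lt(max(abs(sums - 1)), 1e-12)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("forwarded logits are the central parent crop, trilinearly upsampled", {
  M <- 8
  po <- array(0, c(12, M, M, M))
  po[5, 4, 4, 4] <- 1                              # impulse at 0-based (3,3,3)
  rs <- resample_logits(po, c(0, 0, 0), 2, c(0, 0, 0), 1, M)
  w <- rs[5, , , ]
  # parent voxel 3 maps to child coordinate (3 - 3.5)/0.5 + 3.5 = 2.5:
  # the impulse must land between child voxels 2 and 3 (0-based)
  pk <- which(w == max(w), arr.ind = TRUE)
  expect_true(all(pk %in% c(3, 4)))
  # each parent voxel covers (1/ratio)^3 child voxels; trilinear weights of
  # an interior impulse sum to that factor
  expect_equal(sum(w), 8, tolerance = 1e-9)
  # other channels untouched
  expect_true(all(rs[-5, , , ] == 0))
})

test_that("single-level stacks consume exactly the window channels", {
  pyr <- scale_pyramid_spec(depth = 1, matrix = 8)
  ms <- model_stack_init(pyr, c(1, 2), features = c(4, 8), seed = 2)
  v <- volume(array(100, c(20, 20, 20)), spacing = 1)
  st <- extract_stack(v, c(9.5, 9.5, 9.5), compute_scales(pyr, c(20, 20, 20)),
                      matrix = 8)
  outs <- forward_stack(ms, st)
  expect_length(outs, 1)
  expect_identical(dim(outs[[1]]), c(ms$out_channels, 8L, 8L, 8L))
})

test_that("stack backward matches finite differences through the forwarding path", {
  pyr <- scale_pyramid_spec(depth = 2, matrix = 4, finest_mm = 1, coverage = 0.9)
  ms <- model_stack_init(pyr, c(1, 2), small = c(FALSE, TRUE),
                         features = c(2, 3), seed = 3)
  set.seed(4)
  for (i in 1:2)
    ms$levels[[i]]$final$W <- matrix(rnorm(length(ms$levels[[i]]$final$W), 0, 0.3),
                                     ms$out_channels)
  v <- volume(array(round(rnorm(20^3, 0, 400)), c(20, 20, 20)), spacing = 1)
  lab <- label_map(array(sample(0:2, 20^3, TRUE), c(20, 20, 20)), spacing = 1)
  sc <- compute_scales(pyr, c(20, 20, 20))
  sts <- list(extract_stack(v, c(9.5, 9.5, 9.5), sc, matrix = 4),
              extract_stack(v, c(8.5, 9.5, 10.5), sc, matrix = 4))
  lss <- list(extract_label_stack(lab, c(9.5, 9.5, 9.5), sc, matrix = 4),
              extract_label_stack(lab, c(8.5, 9.5, 10.5), sc, matrix = 4))
  K <- 3
  loss_of <- function(params) {
    fw <- patchpyramid:::forward_stack_batch(params, sts)
    tot <- 0
    for (i in 1:2) {
      labi <- vapply(lss, function(s) as.integer(s$levels[[i]]$data), integer(4^3))
      tot <- tot + patchpyramid:::large_loss_grad(fw$outputs[[i]], as.integer(labi),
                                                  params, want_grad = FALSE)$loss
      for (b in 1:2) {
        zb <- matrix(fw$outputs[[i]][, , , , b], dim(fw$outputs[[i]])[1])
        tot <- tot + patchpyramid:::topk_loss_grad_patch(zb, labi[, b], params, K,
                                                          want_grad = FALSE)$loss / 2
      }
    }
    tot
  }
  fw <- patchpyramid:::forward_stack_batch(ms, sts, keep_cache = TRUE)
  d_outputs <- vector("list", 2)
  for (i in 1:2) {
    labi <- vapply(lss, function(s) as.integer(s$levels[[i]]$data), integer(4^3))
    lg <- patchpyramid:::large_loss_grad(fw$outputs[[i]], as.integer(labi), ms)
    dout <- lg$dout
    dm <- matrix(dout, dim(dout)[1])
    for (b in 1:2) {
      zb <- matrix(fw$outputs[[i]][, , , , b], dim(dout)[1])
      tk <- patchpyramid:::topk_loss_grad_patch(zb, labi[, b], ms, K)
      cols <- (b - 1) * 4^3 + seq_len(4^3)
      dm[, cols] <- dm[, cols] + tk$dz / 2
    }
    d_outputs[[i]] <- array(dm, dim(dout))
  }
  grads <- patchpyramid:::backward_stack_batch(ms, fw, d_outputs)
  eps <- 1e-5
  # coarse-level weight gradient includes the route through logit forwarding
  set.seed(8)
  iw <- sample(length(ms$levels[[1]]$enc[[1]]$conv1$W), 3)
  fdv <- vapply(iw, function(i) {
    m1 <- ms; m1$levels[[1]]$enc[[1]]$conv1$W[i] <- m1$levels[[1]]$enc[[1]]$conv1$W[i] + eps
    m2 <- ms; m2$levels[[1]]$enc[[1]]$conv1$W[i] <- m2$levels[[1]]$enc[[1]]$conv1$W[i] - eps
    (loss_of(m1) - loss_of(m2)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(fdv - grads[[1]]$enc[[1]]$conv1$W[iw])), 1e-6)
})
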