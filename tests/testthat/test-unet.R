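# Finite-difference verification of the hand-written forward/backward pass
# on a miniature network (2 feature stages, 4^3 patches) so the checks run
# in seconds while exercising every layer type.

test_that("backward pass matches finite differences for every layer type", {
  sp <- unet_spec(3, 4, features = c(2, 3), matrix = 4)
  pars <- unet_init(sp, seed = 1)
  set.seed(2)
  pars$final$W <- matrix(rnorm(8, 0, 0.3), 4, 2)   # exercise the head too
  x <- array(rnorm(3 * 4^3 * 2), c(3, 4, 4, 4, 2))
  fw <- unet_forward(pars, x, keep_cache = TRUE)
  G <- array(rnorm(length(fw$y)), dim(fw$y))
  bw <- unet_backward(pars, fw$cache, G)
  eps <- 1e-6
  loss_x <- function(xx) sum(unet_forward(pars, xx)$y * G)
  ii <- sample(length(x), 5)
  fdx <- vapply(ii, function(i) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    (loss_x(x1) - loss_x(x2)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(fdx - bw$dx[ii])), 1e-4)

  check_par <- function(get, set, gval, n = 4) {
    p0 <- get(pars)
    iw <- sample(length(p0), min(n, length(p0)))
    fdv <- vapply(iw, function(i) {
      p1 <- pars; v <- get(p1); v[i] <- v[i] + eps; p1 <- set(p1, v)
      p2 <- pars; v2 <- get(p2); v2[i] <- v2[i] - eps; p2 <- set(p2, v2)
      (sum(unet_forward(p1, x)$y * G) - sum(unet_forward(p2, x)$y * G)) / (2 * eps)
    }, numeric(1))
    max(abs(fdv - gval[iw]))
  }
  errs <- c(
    check_par(function(p) p$enc[[1]]$conv1$W,
              function(p, v) { p$enc[[1]]$conv1$W <- v; p }, bw$grads$enc[[1]]$conv1$W),
    check_par(function(p) p$enc[[1]]$conv1$gamma,
              function(p, v) { p$enc[[1]]$conv1$gamma <- v; p }, bw$grads$enc[[1]]$conv1$gamma, 2),
    check_par(function(p) p$enc[[2]]$conv2$beta,
              function(p, v) { p$enc[[2]]$conv2$beta <- v; p }, bw$grads$enc[[2]]$conv2$beta, 2),
    check_par(function(p) p$dec[[1]]$up$W,
              function(p, v) { p$dec[[1]]$up$W <- v; p }, bw$grads$dec[[1]]$up$W),
    check_par(function(p) p$dec[[1]]$conv2$W,
              function(p, v) { p$dec[[1]]$conv2$W <- v; p }, bw$grads$dec[[1]]$conv2$W),
    check_par(function(p) p$final$W,
              function(p, v) { p$final$W <- matrix(v, 4, 2); p }, bw$grads$final$W)
  )
  expect_lt(max(errs), 1e-4)
})

test_that("parameter count is deterministic, monotone and matches the build", {
  sp <- unet_spec(11, 14, features = c(8, 16, 16, 32, 64), matrix = 32)
  expect_identical(count_parameters(sp), count_parameters(sp))
  sp2 <- unet_spec(11, 14, features = 2 * c(8, 16, 16, 32, 64), matrix = 32)
  expect_gt(count_parameters(sp2), count_parameters(sp))
  # the realised parameter arrays sum to the closed-form count
  spc <- unet_spec(3, 4, features = c(2, 3), matrix = 4)
  built <- unet_init(spc, seed = 1)
  n_built <- sum(rapply(built[c("enc", "dec", "final")], length, how = "unlist"))
  expect_identical(as.integer(n_built), as.integer(count_parameters(spc)))
  # frozen regression value for the default per-scale architecture
  expect_identical(count_parameters(sp), 389838L)
})

test_that("forward pass is deterministic and shape-stable", {
  sp <- unet_spec(3, 4, features = c(2, 3), matrix = 8)
  pars <- unet_init(sp, seed = 3)
  x <- array(rnorm(3 * 8^3), c(3, 8, 8, 8, 1))
  y1 <- unet_forward(pars, x)$y
  y2 <- unet_forward(pars, x)$y
  expect_identical(y1, y2)
  expect_identical(dim(y1), c(4L, 8L, 8L, 8L, 1L))
})
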