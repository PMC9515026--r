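# Per-scale U-Net: 5 encoder feature stages (default widths 8,16,16,32,64),
# two 3^3 convolutions per stage each followed by scale-only RMS
# normalisation and ReLU, 2^3 max-pooling between encoder stages, 2^3
# transposed convolutions in the decoder, skip connections at matching
# depths, and a linear 1^3 output convolution. The normalisation keeps
# activations well-scaled regardless of how sparse the window-channel input
# is, without destroying the per-patch mean that encodes which tissue a
# uniform patch lies in. Normalised convolutions carry no separate bias;
# the learned per-channel scale and offset take that role.
#
# Forward and backward passes are written out explicitly against the
# compiled kernels; parameters are plain R arrays, so training is exactly
# reproducible under a fixed RNG seed.

#' Specify a per-scale U-Net
#'
#' @param in_channels Input channels (window channels, plus forwarded logits
#'   at non-coarsest scales).
#' @param out_channels Output channels (`n` label logits + 8 carry channels).
#' @param features Encoder feature widths, one per stage (default
#'   `c(8, 16, 16, 32, 64)`).
#' @param matrix Patch matrix size M; must halve cleanly through all pooling
#'   stages.
#' @return A `pp_unet_spec`.
#' @export
unet_spec <- function(in_channels, out_channels, features = c(8, 16, 16, 32, 64),
                      matrix = 32L) {
  S <- length(features)
  assert_that(S >= 2, "need at least 2 feature stages")
  sizes <- matrix / 2^(seq_len(S) - 1)
  assert_that(all(sizes >= 1) && all(sizes == floor(sizes)),
              "matrix %d not divisible through %d pooling stages", matrix, S - 1)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 features = as.integer(features), matrix = as.integer(matrix)),
            class = "pp_unet_spec")
}

#' Closed-form parameter count of a U-Net spec
#'
#' Counts the weights of every convolution implied by the spec plus the
#' normalisation scales/offsets; changes iff the architecture changes,
#' guarding the wiring contract.
#'
#' @param spec A [unet_spec()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec) {
  f <- spec$features
  S <- length(f)
  n <- 0
  cin <- spec$in_channels
  norm_conv <- function(cin, cout) cout * cin * 27 + 2 * cout  # W + gamma + beta
  for (k in seq_len(S)) {
    n <- n + norm_conv(cin, f[k]) + norm_conv(f[k], f[k])
    cin <- f[k]
  }
  for (k in seq_len(S - 1)) {   # decoder stage k joins features f[k]
    n <- n + f[k] * (f[k + 1] * 8 + 1)                     # transposed conv
    n <- n + norm_conv(2 * f[k], f[k]) + norm_conv(f[k], f[k])
  }
  as.integer(n + spec$out_channels * (f[1] + 1))           # linear output conv
}

he_mat <- function(nrow, ncol) matrix(rnorm(nrow * ncol, 0, sqrt(2 / ncol)), nrow, ncol)

norm_conv_init <- function(cout, cin) {
  list(W = he_mat(cout, cin * 27), gamma = rep(1, cout), beta = numeric(cout))
}

#' Initialise U-Net parameters
#'
#' He-initialised convolution weights; normalisation scales start at 1,
#' offsets at 0.
#'
#' @param spec A [unet_spec()].
#' @param seed Seed (`NULL`: current RNG stream).
#' @return A `pp_unet_params` list.
#' @export
unet_init <- function(spec, seed = NULL) {
  with_seed(seed, {
    f <- spec$features
    S <- length(f)
    enc <- list()
    cin <- spec$in_channels
    for (k in seq_len(S)) {
      enc[[k]] <- list(conv1 = norm_conv_init(f[k], cin),
                       conv2 = norm_conv_init(f[k], f[k]))
      cin <- f[k]
    }
    dec <- list()
    for (k in seq_len(S - 1)) {
      dec[[k]] <- list(up = list(W = he_mat(f[k], f[k + 1] * 8), b = numeric(f[k])),
                       conv1 = norm_conv_init(f[k], 2 * f[k]),
                       conv2 = norm_conv_init(f[k], f[k]))
    }
    # near-zero classifier head: class probabilities start (almost) uniform,
    # so the optimiser budget is spent on signal rather than on undoing a
    # random initial labelling
    final <- list(W = matrix(rnorm(spec$out_channels * f[1], 0, 0.01),
                             spec$out_channels, f[1]),
                  b = numeric(spec$out_channels))
    structure(list(spec = spec, enc = enc, dec = dec, final = final),
              class = "pp_unet_params")
  })
}

up_fwd <- function(x, p) cpp_upconv3d_fwd(x, p$W, p$b, dim(x))

# conv (no bias) -> RMS normalisation -> affine -> ReLU, with backward
# cache; the im2col matrix from the forward pass is cached for the backward
# GEMMs. The normalisation is scale-only (divide by the per-channel,
# per-sample root mean square): it controls activation magnitudes at any
# depth without subtracting the patch mean -- mean-centering would map a
# patch lying wholly inside one tissue to the same (zero) features as any
# other uniform patch, erasing exactly the absolute window-identity signal
# the channel-split input carries.
block_fwd <- function(x, p) {
  fw <- cpp_conv3d_fwd_cache(x, p$W, numeric(nrow(p$W)), dim(x))
  z <- fw$Y
  d <- dim(z)
  mom <- cpp_chan_moments(z, d)
  istd <- 1 / sqrt(mom$m2 + 1e-5)
  zero <- 0 * istd
  ia <- cpp_inorm_apply(z, d, zero, istd, p$gamma, p$beta)
  mask <- ia$y > 0
  list(y = ia$y * mask,
       cache = list(col = fw$col, xdim = dim(x), xhat = ia$xhat, istd = istd,
                    mask = mask, d = d))
}

block_bwd <- function(dy, p, ck) {
  d <- ck$d
  dy <- dy * ck$mask
  dgamma <- rowSums(matrix(dy * ck$xhat, d[1]))
  dbeta <- rowSums(matrix(dy, d[1]))
  dxhat <- dy * p$gamma              # recycles along the channel axis
  m2 <- cpp_chan_moments(dxhat * ck$xhat, d)$mu
  dz <- cpp_inorm_bwd(dxhat, ck$xhat, d, 0 * m2, m2, istd = ck$istd)
  bw <- cpp_conv3d_bwd_col(ck$col, dz, p$W, ck$xdim)
  list(grads = list(W = bw$dW, gamma = dgamma, beta = dbeta), dx = bw$dX)
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[-1]))
  out[seq_len(da[1]), , , , ] <- a
  out[da[1] + seq_len(db[1]), , , , ] <- b
  out
}

#' Run a U-Net forward pass
#'
#' @param params A `pp_unet_params`.
#' @param x Input array `(in_channels, M, M, M, B)`.
#' @param keep_cache Keep intermediate activations for [unet_backward()].
#' @return List with `y` `(out_channels, M, M, M, B)` and (optionally) `cache`.
#' @export
unet_forward <- function(params, x, keep_cache = FALSE) {
  S <- length(params$enc)
  cache <- list(enc = vector("list", S), dec = vector("list", S - 1))
  skips <- vector("list", S)
  h <- x
  for (k in seq_len(S)) {
    b1 <- block_fwd(h, params$enc[[k]]$conv1)
    b2 <- block_fwd(b1$y, params$enc[[k]]$conv2)
    skips[[k]] <- b2$y
    if (keep_cache) cache$enc[[k]] <- list(c1 = b1$cache, c2 = b2$cache)
    if (k < S) {
      mp <- cpp_maxpool3d_fwd(b2$y, dim(b2$y))
      h <- mp$Y
      if (keep_cache) {
        cache$enc[[k]]$poolarg <- mp$arg
        cache$enc[[k]]$pooldim <- dim(b2$y)
      }
    } else h <- b2$y
  }
  for (k in rev(seq_len(S - 1))) {
    u <- up_fwd(h, params$dec[[k]]$up)
    xc <- concat_ch(skips[[k]], u)
    b1 <- block_fwd(xc, params$dec[[k]]$conv1)
    b2 <- block_fwd(b1$y, params$dec[[k]]$conv2)
    if (keep_cache) cache$dec[[k]] <- list(xup = h, c1 = b1$cache, c2 = b2$cache)
    h <- b2$y
  }
  dh <- dim(h)
  hm <- matrix(h, dh[1])
  y <- params$final$W %*% hm + params$final$b
  y <- array(y, c(nrow(params$final$W), dh[-1]))
  if (keep_cache) cache$hfinal <- h
  list(y = y, cache = if (keep_cache) cache else NULL)
}

#' Backpropagate through a U-Net
#'
#' @param params A `pp_unet_params`.
#' @param cache Cache from `unet_forward(..., keep_cache = TRUE)`.
#' @param dy Gradient of the loss w.r.t. the output `(out_channels, ..., B)`.
#' @return List with `grads` (same shape as `params`) and `dx` (gradient
#'   w.r.t. the input, needed to route loss into coarser scales).
#' @export
unet_backward <- function(params, cache, dy) {
  S <- length(params$enc)
  grads <- list(enc = vector("list", S), dec = vector("list", S - 1))
  ddy <- dim(dy)
  dym <- matrix(dy, ddy[1])
  h <- cache$hfinal
  hm <- matrix(h, dim(h)[1])
  gfinal <- list(W = dym %*% t(hm), b = rowSums(dym))
  dh <- array(t(params$final$W) %*% dym, dim(h))
  dskips <- vector("list", S)
  for (k in seq_len(S - 1)) {   # decoder stages back in reverse of forward
    ck <- cache$dec[[k]]
    b2 <- block_bwd(dh, params$dec[[k]]$conv2, ck$c2)
    b1 <- block_bwd(b2$dx, params$dec[[k]]$conv1, ck$c1)
    nskip <- ck$c1$xdim[1] / 2
    dskips[[k]] <- b1$dx[seq_len(nskip), , , , , drop = FALSE]
    dup <- b1$dx[nskip + seq_len(nskip), , , , , drop = FALSE]
    bwu <- cpp_upconv3d_bwd(ck$xup, dup, params$dec[[k]]$up$W, dim(ck$xup))
    grads$dec[[k]] <- list(up = list(W = bwu$dW, b = bwu$db),
                           conv1 = b1$grads, conv2 = b2$grads)
    dh <- bwu$dX
  }
  dx <- NULL
  for (k in rev(seq_len(S))) {
    ek <- cache$enc[[k]]
    dtop <- if (k == S) dh else {
      cpp_maxpool3d_bwd(dh, ek$poolarg, ek$pooldim) + dskips[[k]]
    }
    b2 <- block_bwd(dtop, params$enc[[k]]$conv2, ek$c2)
    b1 <- block_bwd(b2$dx, params$enc[[k]]$conv1, ek$c1)
    grads$enc[[k]] <- list(conv1 = b1$grads, conv2 = b2$grads)
    if (k > 1) dh <- b1$dx else dx <- b1$dx
  }
  grads$final <- gfinal
  list(grads = grads, dx = dx)
}
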