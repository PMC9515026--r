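# Shared fixtures and independent brute-force oracles used across tests.
# The oracles deliberately avoid the package's own computational paths
# (distance transforms, im2col convolutions): surfaces via explicit
# neighbour checks on a padded array, distances via exhaustive pairwise
# scans, losses via direct per-voxel summation.

# random multi-sphere binary mask on a cubic grid
random_blob_mask <- function(shape = c(24, 24, 24), n_blobs = 2, rmin = 2, rmax = 6) {
  co <- as.matrix(expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                              z = seq_len(shape[3])))
  m <- rep(FALSE, nrow(co))
  for (k in seq_len(n_blobs)) {
    c0 <- runif(3, 4, shape - 4)
    r <- runif(1, rmin, rmax)
    m <- m | (rowSums(sweep(co, 2, c0)^2) <= r^2)
  }
  array(m, shape)
}

# surface voxels via neighbour counting on a zero-padded copy
bf_surface <- function(m) {
  d <- dim(m)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
        pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
        pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  m & !nb
}

# exhaustive directed surface distances (mm)
bf_directed_dists <- function(sa, sb, spacing) {
  A <- which(sa, arr.ind = TRUE)
  B <- which(sb, arr.ind = TRUE)
  vapply(seq_len(nrow(A)), function(i) {
    sqrt(min((spacing[1] * (B[, 1] - A[i, 1]))^2 +
             (spacing[2] * (B[, 2] - A[i, 2]))^2 +
             (spacing[3] * (B[, 3] - A[i, 3]))^2))
  }, numeric(1))
}

bf_metrics <- function(A, B, spacing, tol = 1, pct = 95) {
  sa <- bf_surface(A); sb <- bf_surface(B)
  da <- bf_directed_dists(sa, sb, spacing)
  db <- bf_directed_dists(sb, sa, spacing)
  list(dsc = 2 * sum(A & B) / (sum(A) + sum(B)),
       surface_dsc = (mean(da <= tol + 1e-9) + mean(db <= tol + 1e-9)) / 2,
       hd95 = unname(stats::quantile(c(da, db), pct / 100, type = 7)),
       assd = mean(c(da, db)))
}

# a small axis-aligned cube mask
cube_mask <- function(shape, lo, side) {
  m <- array(FALSE, shape)
  m[lo[1]:(lo[1] + side - 1), lo[2]:(lo[2] + side - 1), lo[3]:(lo[3] + side - 1)] <- TRUE
  m
}

# tiny two-level model stack for wiring tests (3-stage features, M = 8)
tiny_stack_model <- function(group_labels = c(1, 2, 3),
                             small = c(FALSE, FALSE, TRUE), seed = 7) {
  pyr <- scale_pyramid_spec(depth = 2, matrix = 8, finest_mm = 1, coverage = 0.8)
  model_stack_init(pyr, group_labels, small, features = c(4, 8, 8), seed = seed)
}
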