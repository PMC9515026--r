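# Loss regime: labels that are large in volume are trained with ordinary
# softmax + categorical cross-entropy (jointly with background); labels that
# are volumetrically small use a binary cross-entropy top-K loss — for each
# small label, only the K voxels with the largest per-voxel loss enter the
# average, which keeps the gradient focused on the few informative voxels
# instead of being swamped by easy background.

# map a label patch to softmax-target channel indices (within the softmax
# channel set); small-label voxels count as background for the softmax term
softmax_targets <- function(lab_vals, params) {
  ch <- channel_sets(params)
  # softmax-set position for each label id (0 = small or foreign: background)
  pos <- integer(max(params$group_labels, 1L))
  large_ids <- params$group_labels[!params$small]
  large_ch <- match(large_ids, params$group_labels) + 1L   # channel index
  pos[large_ids] <- match(large_ch, ch$softmax)
  t <- rep(1L, length(lab_vals))           # background position
  fg <- which(lab_vals > 0L & lab_vals <= length(pos))
  mapped <- pos[lab_vals[fg]]
  t[fg[mapped > 0L]] <- mapped[mapped > 0L]
  t
}

# internal batched softmax cross-entropy; returns loss and d(logits)
large_loss_grad <- function(out, lab_vals, params, want_grad = TRUE) {
  d <- dim(out)
  nvox <- prod(d[-1])
  ch <- channel_sets(params)
  z <- matrix(out, d[1])[ch$softmax, , drop = FALSE]
  t <- softmax_targets(lab_vals, params)
  zmax <- apply(z, 2, max)
  zs <- sweep(z, 2, zmax, "-")
  lse <- log(colSums(exp(zs))) + zmax
  loss <- mean(lse - z[cbind(t, seq_len(nvox))])
  if (!want_grad) return(list(loss = loss))
  p <- sweep(exp(zs), 2, colSums(exp(zs)), "/")
  p[cbind(t, seq_len(nvox))] <- p[cbind(t, seq_len(nvox))] - 1
  dz <- p / nvox
  dout <- array(0, d)
  dm <- matrix(dout, d[1])
  dm[ch$softmax, ] <- dz
  list(loss = loss, dout = array(dm, d))
}

# internal per-patch top-K binary cross-entropy; out (C, M^3) matrix view
topk_loss_grad_patch <- function(zmat, lab_vals, params, K, want_grad = TRUE) {
  ch <- channel_sets(params)
  small_ids <- params$group_labels[params$small]
  loss <- 0
  dz <- if (want_grad) matrix(0, nrow(zmat), ncol(zmat)) else NULL
  for (j in seq_along(small_ids)) {
    cidx <- ch$sigmoid[j]
    z <- zmat[cidx, ]
    t <- as.numeric(lab_vals == small_ids[j])
    # numerically stable BCE with logits
    bce <- pmax(z, 0) - z * t + log1p(exp(-abs(z)))
    sel <- order(bce, decreasing = TRUE)[seq_len(K)]
    loss <- loss + mean(bce[sel])
    if (want_grad) {
      sig <- 1 / (1 + exp(-z[sel]))
      dz[cidx, sel] <- (sig - t[sel]) / K
    }
  }
  list(loss = loss, dz = dz)
}

#' Categorical cross-entropy over large labels
#'
#' Mean softmax cross-entropy over all voxels of one level's output patch.
#' Voxels carrying a small-flagged label count as background here; those
#' labels are trained by [small_label_topk_loss()] instead.
#'
#' @param out Level output array `(out_channels, M, M, M)`.
#' @param lab Integer label patch `(M, M, M)` (values in the stack's group).
#' @param params The `pp_model_stack`.
#' @return Scalar loss.
#' @export
large_label_loss <- function(out, lab, params) {
  large_loss_grad(out, as.integer(lab), params, want_grad = FALSE)$loss
}

#' Top-K binary cross-entropy over small labels
#'
#' For each small-flagged label: per-voxel binary cross-entropy of that
#' label's sigmoid channel against its binary mask, averaged over the K
#' voxels with the largest loss; summed over small labels. `K = M^3`
#' reduces to the full-patch mean binary cross-entropy.
#'
#' @inheritParams large_label_loss
#' @param K Number of voxels kept per label (1 <= K <= M^3).
#' @return Scalar loss (0 if the stack has no small labels).
#' @export
small_label_topk_loss <- function(out, lab, params, K) {
  d <- dim(out)
  nvox <- prod(d[-1])
  assert_that(K >= 1 && K <= nvox, "K must be in [1, %d]", nvox)
  zmat <- matrix(out, d[1])
  topk_loss_grad_patch(zmat, as.integer(lab), params, as.integer(K),
                       want_grad = FALSE)$loss
}
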