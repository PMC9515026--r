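# Cross-scale wiring: one U-Net per pyramid level. The coarsest level
# consumes the 11 window channels of its patch; every finer level consumes
# its own window channels concatenated with the previous level's raw output
# logits, resampled from the central region of the parent patch that the
# child's extent occupies (trilinear, on logits, not probabilities). The
# first n output channels are label logits (channel 1 is background) used
# for per-level losses; the remaining 8 carry channels receive no loss and
# no activation and simply provide learned context to the next scale.

#' Initialise a model stack for one label group
#'
#' @param pyramid A [scale_pyramid_spec()].
#' @param group_labels Integer label ids segmented by this stack (ascending).
#' @param small Logical per group label: trained under the top-K
#'   binary cross-entropy regime instead of the joint softmax.
#' @param bank A [window_bank()] supplying the input channels.
#' @param features Encoder feature widths of every per-level U-Net.
#' @param seed Seed for weight initialisation.
#' @return A `pp_model_stack` with D independent per-level parameter sets.
#' @export
model_stack_init <- function(pyramid, group_labels, small = NULL,
                             bank = default_bank(), features = c(8, 16, 16, 32, 64),
                             seed = NULL) {
  assert_that(inherits(pyramid, "pp_pyramid_spec"), "pyramid must be a pp_pyramid_spec")
  group_labels <- sort(as.integer(group_labels))
  small <- small %||% rep(FALSE, length(group_labels))
  assert_that(length(small) == length(group_labels),
              "small flags must match group_labels")
  n_logits <- length(group_labels) + 1L           # background + labels
  out_channels <- n_logits + 8L
  specs <- lapply(seq_len(pyramid$depth), function(i) {
    cin <- bank$n_channels + if (i == 1L) 0L else out_channels
    unet_spec(cin, out_channels, features = features, matrix = pyramid$matrix)
  })
  with_seed(seed, {
    levels <- lapply(specs, unet_init)
    structure(list(pyramid = pyramid, group_labels = group_labels,
                   small = as.logical(small), bank = bank,
                   n_logits = n_logits, out_channels = out_channels,
                   features = features, levels = levels),
              class = "pp_model_stack")
  })
}

# channel indices of the softmax (background + large) and sigmoid (small) sets
channel_sets <- function(params) {
  lab_ch <- seq_along(params$group_labels) + 1L
  list(softmax = c(1L, lab_ch[!params$small]), sigmoid = lab_ch[params$small])
}

# central-crop + trilinear coordinates: child voxel j of a co-centred patch
# with spacing ratio r sits at parent voxel (M-1)/2 + (j - (M-1)/2) * r
center_crop_coords <- function(M, ratio) {
  patch_offsets(M) * ratio + (M - 1) / 2
}

#' Resample parent logits onto a child patch grid
#'
#' The child's physical extent is mapped into the parent patch's voxel
#' coordinates and the parent output is sampled there trilinearly (zero fill
#' outside the parent). For co-centred training stacks this is the central
#' `(s_child/s_parent * M)^3` crop upsampled to M^3.
#'
#' @param parent_out Parent output `(C, M, M, M)` for one patch.
#' @param parent_center,parent_spacing Parent patch geometry.
#' @param child_center,child_spacing Child patch geometry.
#' @param M Patch matrix size.
#' @return Array `(C, M, M, M)` of forwarded logits.
#' @export
resample_logits <- function(parent_out, parent_center, parent_spacing,
                            child_center, child_spacing, M) {
  off <- patch_offsets(M) * child_spacing
  pts <- off + child_center
  vox <- (pts - parent_center) / parent_spacing + (M - 1) / 2
  vals <- cpp_trilinear_gather(parent_out, dim(parent_out), vox, 0)
  array(vals, c(dim(parent_out)[1], M, M, M))
}

#' Forward pass through the whole stack for one patch stack
#'
#' @param params A `pp_model_stack`.
#' @param stack A `pp_patch_stack` from [extract_stack()] with depth D.
#' @return List of D output arrays `(out_channels, M, M, M)`.
#' @export
forward_stack <- function(params, stack) {
  fw <- forward_stack_batch(params, list(stack))
  lapply(fw$outputs, function(o) array(o[, , , , 1], dim(o)[1:4]))
}

# batched forward over a list of co-centred stacks (shared scale list);
# keep_cache retains what backward_stack_batch needs
forward_stack_batch <- function(params, stacks, keep_cache = FALSE) {
  D <- params$pyramid$depth
  M <- params$pyramid$matrix
  B <- length(stacks)
  assert_that(length(stacks[[1]]$levels) == D,
              "stack depth %d does not match pyramid depth %d",
              length(stacks[[1]]$levels), D)
  outputs <- vector("list", D)
  caches <- vector("list", D)
  inputs <- vector("list", D)
  crop_coords <- vector("list", D)
  for (i in seq_len(D)) {
    xin <- array(0, c(dim_level_in(params, i), M, M, M, B))
    nb <- params$bank$n_channels
    for (b in seq_len(B))
      xin[seq_len(nb), , , , b] <- split_channels(stacks[[b]]$levels[[i]]$data, params$bank)
    if (i > 1L) {
      r <- stacks[[1]]$levels[[i]]$spacing / stacks[[1]]$levels[[i - 1]]$spacing
      crop_coords[[i]] <- center_crop_coords(M, r)
      prev <- outputs[[i - 1]]
      for (b in seq_len(B)) {
        po <- array(prev[, , , , b], dim(prev)[1:4])
        vals <- cpp_trilinear_gather(po, dim(po), crop_coords[[i]], 0)
        xin[nb + seq_len(params$out_channels), , , , b] <- vals
      }
    }
    fw <- unet_forward(params$levels[[i]], xin, keep_cache = keep_cache)
    outputs[[i]] <- fw$y
    caches[[i]] <- fw$cache
    if (keep_cache) inputs[[i]] <- NULL  # caches hold what backward needs
  }
  list(outputs = outputs, caches = caches, crop_coords = crop_coords)
}

dim_level_in <- function(params, i) {
  params$bank$n_channels + if (i == 1L) 0L else params$out_channels
}

# backward over the batched stack: d_outputs is a list of D gradients
# (out_channels, M, M, M, B); gradients flow both through each level's own
# loss and through the forwarded-logit channels into the parent level
backward_stack_batch <- function(params, fw, d_outputs) {
  D <- params$pyramid$depth
  M <- params$pyramid$matrix
  nb <- params$bank$n_channels
  grads <- vector("list", D)
  dout <- d_outputs
  for (i in rev(seq_len(D))) {
    bw <- unet_backward(params$levels[[i]], fw$caches[[i]], dout[[i]])
    grads[[i]] <- bw$grads
    if (i > 1L) {
      B <- dim(bw$dx)[5]
      for (b in seq_len(B)) {
        dfwd <- matrix(bw$dx[nb + seq_len(params$out_channels), , , , b],
                       params$out_channels)
        sc <- cpp_trilinear_scatter(dfwd, c(params$out_channels, M, M, M),
                                    fw$crop_coords[[i]])
        dout[[i - 1]][, , , , b] <- dout[[i - 1]][, , , , b] + sc
      }
    }
  }
  grads
}

#' Convert stack output logits to per-class probabilities
#'
#' Background and large labels are jointly softmax-normalised; each small
#' label is independently sigmoid-mapped. Carry channels are dropped.
#'
#' @param out Output array `(out_channels, ...)` from one level.
#' @param params The `pp_model_stack` that produced it.
#' @return Array `(n_logits, ...)`: row 1 background, row 1+j the j-th group
#'   label.
#' @export
logits_to_probs <- function(out, params) {
  d <- dim(out)
  ch <- channel_sets(params)
  z <- matrix(out, d[1])[seq_len(params$n_logits), , drop = FALSE]
  p <- matrix(0, params$n_logits, ncol(z))
  zs <- z[ch$softmax, , drop = FALSE]
  zs <- sweep(zs, 2, apply(zs, 2, max), "-")
  es <- exp(zs)
  p[ch$softmax, ] <- sweep(es, 2, colSums(es), "/")
  if (length(ch$sigmoid))
    p[ch$sigmoid, ] <- 1 / (1 + exp(-z[ch$sigmoid, , drop = FALSE]))
  array(p, c(params$n_logits, d[-1]))
}
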