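# Full-volume prediction by descending the pyramid: the coarsest level is
# tiled over the whole volume; every "promising" patch (one whose own
# predicted foreground probability exceeds a threshold anywhere) spawns a
# few child patches at the next level, centred at foreground-probability-
# weighted random positions within the parent's extent. Rounds of descent
# repeat until every voxel the coarse level flagged as probable foreground
# is covered by at least one finest-level patch (or a patch cap is hit), and
# overlapping finest-level probabilities are fused by centre-weighted
# averaging. Regions never visited at the finest level stay background.

#' Inference configuration
#'
#' @param branching Children spawned per promising patch per round (default 3).
#' @param promising_threshold Minimum max-foreground probability for descent
#'   (default 0.5).
#' @param max_patches_per_level Safety cap on patches evaluated per level.
#' @param seed Seed for the random child placement.
#' @param exhaustive Tile every level deterministically instead of random
#'   descent (seed-independent; used for regression testing).
#' @param max_rounds Maximum descent rounds before giving up on coverage.
#' @return A `pp_inference_config`.
#' @export
inference_config <- function(branching = 3L, promising_threshold = 0.5,
                             max_patches_per_level = 4000L, seed = 1L,
                             exhaustive = FALSE, max_rounds = 60L) {
  assert_that(branching >= 1, "branching must be >= 1")
  assert_that(promising_threshold >= 0 && promising_threshold <= 1,
              "promising_threshold must be in [0, 1]")
  structure(list(branching = as.integer(branching),
                 promising_threshold = promising_threshold,
                 max_patches_per_level = as.integer(max_patches_per_level),
                 seed = as.integer(seed), exhaustive = isTRUE(exhaustive),
                 max_rounds = as.integer(max_rounds)),
            class = "pp_inference_config")
}

#' Ground-truth passthrough model
#'
#' A stand-in for a trained stack that emits saturated logits derived from a
#' reference label map at any patch geometry. Used to test the inference
#' plumbing (tiling, descent, forwarding, fusion) independently of training.
#'
#' @param labels A [label_map()] providing the ground truth.
#' @param pyramid A [scale_pyramid_spec()].
#' @param group_labels Label ids (default: all foreground labels present).
#' @param small Logical small-flag per group label.
#' @param magnitude Logit magnitude (default 12, i.e. probabilities ~1).
#' @return A `pp_oracle_stack` usable wherever a trained stack is.
#' @export
oracle_stack <- function(labels, pyramid, group_labels = NULL, small = NULL,
                         magnitude = 12) {
  group_labels <- sort(as.integer(group_labels %||%
    setdiff(unique(as.integer(labels$data)), 0L)))
  small <- small %||% rep(FALSE, length(group_labels))
  structure(list(pyramid = pyramid, group_labels = group_labels,
                 small = as.logical(small), bank = default_bank(),
                 n_logits = length(group_labels) + 1L,
                 out_channels = length(group_labels) + 9L,
                 labels = labels, magnitude = magnitude),
            class = c("pp_oracle_stack", "pp_model_stack"))
}

# batched level forward during inference: imgs is (M^3 x B) HU matrix,
# fwds NULL or (out_channels, M, M, M, B); centers B x 3 (needed by oracle)
level_forward <- function(model, level_i, imgs, fwds, centers, spacing) {
  UseMethod("level_forward")
}

#' @export
level_forward.pp_oracle_stack <- function(model, level_i, imgs, fwds, centers, spacing) {
  M <- model$pyramid$matrix
  B <- ncol(imgs)
  out <- array(0, c(model$out_channels, M, M, M, B))
  ch <- channel_sets(model)
  arr <- array(as.double(model$labels$data), c(1L, dim(model$labels$data)))
  for (b in seq_len(B)) {
    pts <- patch_offsets(M) * spacing + centers[b, ]
    vox <- (pts - model$labels$origin) / model$labels$spacing
    lv <- as.integer(cpp_nearest_gather(arr, c(1L, dim(model$labels$data)), vox, 0)[1, ])
    z <- matrix(-model$magnitude, model$n_logits, M^3)
    tgt <- match(lv, c(0L, model$group_labels))
    z[cbind(tgt, seq_len(M^3))] <- model$magnitude
    out[seq_len(model$n_logits), , , , b] <- z
  }
  out
}

#' @export
level_forward.pp_model_stack <- function(model, level_i, imgs, fwds, centers, spacing) {
  M <- model$pyramid$matrix
  B <- ncol(imgs)
  nb <- model$bank$n_channels
  cin <- dim_level_in(model, level_i)
  xin <- array(0, c(cin, M, M, M, B))
  for (b in seq_len(B))
    xin[seq_len(nb), , , , b] <- split_channels(imgs[, b], model$bank)
  if (level_i > 1L) xin[nb + seq_len(model$out_channels), , , , ] <- fwds
  unet_forward(model$levels[[level_i]], xin)$y
}

# per-patch max foreground probability grid (M^3 vector) and overall max
fg_prob <- function(model, out_patch) {
  p <- logits_to_probs(out_patch, model)
  pm <- matrix(p, dim(p)[1])
  apply(pm[-1, , drop = FALSE], 2, max)
}

# evenly spaced centres covering [0, ext] with patch span `span`
centers_axis <- function(ext, span) {
  if (span >= ext) return(ext / 2)
  n <- ceiling(ext / span)
  seq(span / 2, ext - span / 2, length.out = n)
}

# map a patch onto volume voxels: returns volume voxel indices (3 x N,
# 1-based), continuous patch coords (3 x N, 0-based) for those voxels
patch_footprint <- function(vol, center, spacing, M) {
  half <- M * spacing / 2
  idx <- vector("list", 3)
  for (a in 1:3) {
    pos_lo <- center[a] - half + 1e-9
    pos_hi <- center[a] + half - 1e-9
    i0 <- max(1L, as.integer(ceiling((pos_lo - vol$origin[a]) / vol$spacing[a])) + 1L)
    i1 <- min(dim(vol$data)[a], as.integer(floor((pos_hi - vol$origin[a]) / vol$spacing[a])) + 1L)
    if (i1 < i0) return(NULL)
    idx[[a]] <- i0:i1
  }
  n <- vapply(idx, length, integer(1))
  vx <- rbind(rep(idx[[1]], times = n[2] * n[3]),
              rep(rep(idx[[2]], each = n[1]), times = n[3]),
              rep(idx[[3]], each = n[1] * n[2]))
  pos <- (vx - 1) * vol$spacing + vol$origin         # 3 x N physical
  pc <- (pos - center) / spacing + (M - 1) / 2       # patch coords, 0-based
  list(vox = vx, pc = pc, dims = n, ranges = idx)
}

#' Fuse finest-level patch probabilities into volume space
#'
#' Per voxel, the weighted average of all covering patches' class
#' probabilities, with a separable triangular centre-weight profile (centre
#' weight 1 falling linearly to 1/M at the patch border). Voxels with no
#' coverage get background probability 1.
#'
#' @param patches List of `list(probs = (n_classes, M, M, M), center_mm =,
#'   spacing =)` entries.
#' @param vol A [volume()] (or label map) defining the output geometry.
#' @param n_classes Number of probability classes (background first).
#' @param matrix Patch matrix size M.
#' @return List with `probs` array `(n_classes, dim(vol))` and `weight`
#'   array `dim(vol)` of accumulated coverage weights.
#' @export
fuse_patch_predictions <- function(patches, vol, n_classes, matrix) {
  shp <- dim(vol$data)
  acc <- array(0, c(n_classes, shp))
  wgt <- array(0, shp)
  for (p in patches) {
    fp <- patch_footprint(vol, p$center_mm, p$spacing, matrix)
    if (is.null(fp)) next
    res <- fuse_one(acc, wgt, p$probs, fp, matrix)
    acc <- res$acc; wgt <- res$wgt
  }
  probs <- acc
  pm <- matrix(probs, n_classes)
  w <- as.vector(wgt)
  cov <- w > 0
  pm[, cov] <- sweep(pm[, cov, drop = FALSE], 2, w[cov], "/")
  pm[1, !cov] <- 1
  list(probs = array(pm, c(n_classes, shp)), weight = wgt)
}

fuse_one <- function(acc, wgt, probs, fp, M) {
  pcr <- round(fp$pc)
  pcr[pcr < 0] <- 0; pcr[pcr > M - 1] <- M - 1
  # triangular centre weights from the continuous patch coordinates
  w <- (1 - abs(fp$pc[1, ] - (M - 1) / 2) / (M / 2)) *
       (1 - abs(fp$pc[2, ] - (M - 1) / 2) / (M / 2)) *
       (1 - abs(fp$pc[3, ] - (M - 1) / 2) / (M / 2))
  w <- pmax(w, 1e-6)
  pm <- matrix(probs, dim(probs)[1])
  pidx <- 1L + pcr[1, ] + M * (pcr[2, ] + M * pcr[3, ])
  vals <- pm[, pidx, drop = FALSE]
  am <- matrix(acc, dim(acc)[1])
  vlin <- 1L + (fp$vox[1, ] - 1L) +
    dim(wgt)[1] * ((fp$vox[2, ] - 1L) + dim(wgt)[2] * (fp$vox[3, ] - 1L))
  am[, vlin] <- am[, vlin] + sweep(vals, 2, w, "*")
  wgt[vlin] <- wgt[vlin] + w
  list(acc = array(am, dim(acc)), wgt = wgt)
}

#' Predict a full-volume segmentation
#'
#' @param model A trained `pp_model_stack`, an [oracle_stack()], or a list of
#'   such (one per label group).
#' @param vol A [volume()]; resampled internally to the pyramid's finest
#'   spacing if necessary.
#' @param cfg An [inference_config()].
#' @return List with `labels` (a [label_map()]), `probs` (per-class
#'   probability array `(n_logits, dim)`, or a list of them for multiple
#'   groups) and `n_patches` (patches evaluated per level).
#' @export
predict_volume <- function(model, vol, cfg = inference_config()) {
  groups <- if (inherits(model, "pp_model_stack")) list(model) else model
  pyr <- groups[[1]]$pyramid
  if (any(abs(vol$spacing - pyr$finest_mm) > 1e-9))
    vol <- resample_isotropic(vol, pyr$finest_mm)
  results <- vector("list", length(groups))
  for (gi in seq_along(groups))
    results[[gi]] <- predict_volume_group(groups[[gi]], vol,
                                          cfg, subseed(cfg$seed, "descent", gi))
  shp <- dim(vol$data)
  if (length(groups) == 1L) {
    r <- results[[1]]
    lab <- assign_labels_single(r$probs, groups[[1]])
    return(list(labels = label_map(array(lab, shp), n_labels = max(groups[[1]]$group_labels),
                                   spacing = vol$spacing, origin = vol$origin),
                probs = r$probs, n_patches = r$n_patches))
  }
  # multi-group merge: argmax over all groups' label probabilities with a
  # single shared background = 1 - max foreground; ties -> lowest label id
  all_ids <- unlist(lapply(groups, function(g) g$group_labels))
  nvox <- prod(shp)
  fgmat <- matrix(0, length(all_ids), nvox)
  row <- 1L
  for (gi in seq_along(groups)) {
    pm <- matrix(results[[gi]]$probs, groups[[gi]]$n_logits)
    nlab <- length(groups[[gi]]$group_labels)
    fgmat[row:(row + nlab - 1L), ] <- pm[-1, , drop = FALSE]
    row <- row + nlab
  }
  best <- max.col(t(fgmat), ties.method = "first")
  bestp <- fgmat[cbind(best, seq_len(nvox))]
  lab <- ifelse(bestp > 0.5, all_ids[best], 0L)
  list(labels = label_map(array(as.integer(lab), shp), n_labels = max(all_ids),
                          spacing = vol$spacing, origin = vol$origin),
       probs = lapply(results, `[[`, "probs"),
       n_patches = lapply(results, `[[`, "n_patches"))
}

# single-group label rule: argmax over background and every label's
# probability (softmax for large labels, sigmoid for small ones); ties go
# to the earlier row, i.e. background first, then ascending label id
assign_labels_single <- function(probs, model) {
  pm <- matrix(probs, model$n_logits)
  pick <- max.col(t(pm), ties.method = "first")
  as.integer(c(0L, model$group_labels)[pick])
}

predict_volume_group <- function(model, vol, cfg, seed) {
  with_seed(seed, {
    pyr <- model$pyramid
    M <- pyr$matrix
    D <- pyr$depth
    shp <- dim(vol$data)
    ext <- grid_extent_mm(vol)
    scales <- compute_scales(pyr, ext)
    spans <- M * scales
    arr <- array(as.double(vol$data), c(1L, shp))

    extract_imgs <- function(centers, spacing) {
      vapply(seq_len(nrow(centers)), function(b) {
        pts <- patch_offsets(M) * spacing + centers[b, ]
        vox <- (pts - vol$origin) / vol$spacing
        cpp_trilinear_gather(arr, c(1L, shp), vox, -1024)[1, ]
      }, numeric(M^3))
    }

    run_level <- function(level_i, centers, parents, level_prev) {
      imgs <- extract_imgs(centers, scales[level_i])
      fwds <- NULL
      if (level_i > 1L) {
        fwds <- array(0, c(model$out_channels, M, M, M, nrow(centers)))
        for (b in seq_len(nrow(centers))) {
          pp <- level_prev$outputs[[parents[b]]]
          fwds[, , , , b] <- resample_logits(pp, level_prev$centers[parents[b], ],
                                             scales[level_i - 1], centers[b, ],
                                             scales[level_i], M)
        }
      }
      out <- level_forward(model, level_i, imgs, fwds, centers, scales[level_i])
      outputs <- lapply(seq_len(nrow(centers)), function(b)
        array(out[, , , , b], dim(out)[1:4]))
      fg <- lapply(outputs, function(o) fg_prob(model, o))
      list(centers = centers, outputs = outputs, fg = fg)
    }

    # coarsest level: deterministic tiling covering the volume
    cax <- lapply(1:3, function(a) vol$origin[a] - vol$spacing[a] / 2 +
                    centers_axis(ext[a], spans[1]))
    c0 <- as.matrix(expand.grid(cax[[1]], cax[[2]], cax[[3]]))
    colnames(c0) <- NULL
    lev <- vector("list", D)
    lev[[1]] <- run_level(1L, c0, NULL, NULL)
    n_patches <- integer(D)
    n_patches[1] <- nrow(c0)

    thr <- cfg$promising_threshold
    finest_patches <- list()
    acc <- array(0, c(model$n_logits, shp))
    wgt <- array(0, shp)

    # target mask: volume voxels the coarse level considers probable
    # foreground (descent must cover these at the finest level)
    target <- array(FALSE, shp)
    for (k in seq_along(lev[[1]]$outputs)) {
      if (max(lev[[1]]$fg[[k]]) < thr) next
      fp <- patch_footprint(vol, lev[[1]]$centers[k, ], scales[1], M)
      if (is.null(fp)) next
      pcr <- round(fp$pc); pcr[pcr < 0] <- 0; pcr[pcr > M - 1] <- M - 1
      pidx <- 1L + pcr[1, ] + M * (pcr[2, ] + M * pcr[3, ])
      hot <- lev[[1]]$fg[[k]][pidx] >= thr
      vlin <- 1L + (fp$vox[1, ] - 1L) +
        shp[1] * ((fp$vox[2, ] - 1L) + shp[2] * (fp$vox[3, ] - 1L))
      target[vlin[hot]] <- TRUE
    }
    covered <- array(FALSE, shp)
    # snap a finest-level centre so patch voxel positions coincide with
    # volume voxel positions: centre must sit at origin + (k + h)*spacing
    # with h the fractional part of (M-1)/2 (0.5 for even M)
    h_frac <- ((M - 1) / 2) %% 1
    snap <- function(ctr)
      vol$origin + (round((ctr - vol$origin) / vol$spacing - h_frac) + h_frac) * vol$spacing

    if (cfg$exhaustive) {
      for (i in 2:D) {
        cax <- lapply(1:3, function(a) vol$origin[a] - vol$spacing[a] / 2 +
                        centers_axis(ext[a], spans[i]))
        ci <- as.matrix(expand.grid(cax[[1]], cax[[2]], cax[[3]]))
        colnames(ci) <- NULL
        if (i == D) ci <- t(apply(ci, 1, snap))
        # parent: nearest previous-level centre
        parents <- vapply(seq_len(nrow(ci)), function(b) {
          d2 <- rowSums(sweep(lev[[i - 1]]$centers, 2, ci[b, ])^2)
          which.min(d2)
        }, integer(1))
        lev[[i]] <- run_level(i, ci, parents, lev[[i - 1]])
        n_patches[i] <- nrow(ci)
      }
      for (k in seq_along(lev[[D]]$outputs)) {
        pr <- logits_to_probs(lev[[D]]$outputs[[k]], model)
        fp <- patch_footprint(vol, lev[[D]]$centers[k, ], scales[D], M)
        if (is.null(fp)) next
        res <- fuse_one(acc, wgt, pr, fp, M)
        acc <- res$acc; wgt <- res$wgt
      }
    } else if (D >= 2 && any(target)) {
      for (round_i in seq_len(cfg$max_rounds)) {
        prev <- lev[[1]]
        for (i in 2:D) {
          # spawn children from promising parents overlapping uncovered target
          cand_centers <- NULL
          cand_parents <- integer(0)
          for (k in seq_along(prev$outputs)) {
            if (max(prev$fg[[k]]) < thr) next
            fp <- patch_footprint(vol, prev$centers[k, ], scales[i - 1], M)
            if (is.null(fp)) next
            vlin <- 1L + (fp$vox[1, ] - 1L) +
              shp[1] * ((fp$vox[2, ] - 1L) + shp[2] * (fp$vox[3, ] - 1L))
            need <- target[vlin] & !covered[vlin]
            if (!any(need)) next
            pcr <- round(fp$pc); pcr[pcr < 0] <- 0; pcr[pcr > M - 1] <- M - 1
            pidx <- 1L + pcr[1, ] + M * (pcr[2, ] + M * pcr[3, ])
            w <- prev$fg[[k]][pidx] * need
            if (sum(w) <= 0) next
            pickn <- min(cfg$branching, sum(w > 0))
            sel <- sample.int(length(w), pickn, prob = w)
            ctrs <- t(vapply(sel, function(s) {
              pos <- c((fp$vox[1, s] - 1) * vol$spacing[1] + vol$origin[1],
                       (fp$vox[2, s] - 1) * vol$spacing[2] + vol$origin[2],
                       (fp$vox[3, s] - 1) * vol$spacing[3] + vol$origin[3])
              if (i == D) snap(pos) else pos
            }, numeric(3)))
            cand_centers <- rbind(cand_centers, ctrs)
            cand_parents <- c(cand_parents, rep(k, pickn))
          }
          if (is.null(cand_centers) || n_patches[i] >= cfg$max_patches_per_level) {
            prev <- NULL
            break
          }
          room <- cfg$max_patches_per_level - n_patches[i]
          if (nrow(cand_centers) > room) {
            cand_centers <- cand_centers[seq_len(room), , drop = FALSE]
            cand_parents <- cand_parents[seq_len(room)]
          }
          lv <- run_level(i, cand_centers, cand_parents, prev)
          n_patches[i] <- n_patches[i] + nrow(cand_centers)
          if (i == D) {
            for (k in seq_along(lv$outputs)) {
              pr <- logits_to_probs(lv$outputs[[k]], model)
              fp <- patch_footprint(vol, lv$centers[k, ], scales[D], M)
              if (is.null(fp)) next
              res <- fuse_one(acc, wgt, pr, fp, M)
              acc <- res$acc; wgt <- res$wgt
              vlin <- 1L + (fp$vox[1, ] - 1L) +
                shp[1] * ((fp$vox[2, ] - 1L) + shp[2] * (fp$vox[3, ] - 1L))
              covered[vlin] <- TRUE
            }
          }
          prev <- lv
        }
        if (is.null(prev)) break
        if (!any(target & !covered)) break
        if (n_patches[D] >= cfg$max_patches_per_level) break
      }
    } else if (D == 1L) {
      # degenerate single-level pyramid: the tiling is already the finest level
      for (k in seq_along(lev[[1]]$outputs)) {
        pr <- logits_to_probs(lev[[1]]$outputs[[k]], model)
        fp <- patch_footprint(vol, lev[[1]]$centers[k, ], scales[1], M)
        if (is.null(fp)) next
        res <- fuse_one(acc, wgt, pr, fp, M)
        acc <- res$acc; wgt <- res$wgt
      }
    }

    pm <- matrix(acc, model$n_logits)
    w <- as.vector(wgt)
    cov <- w > 0
    pm[, cov] <- sweep(pm[, cov, drop = FALSE], 2, w[cov], "/")
    pm[, !cov] <- 0
    pm[1, !cov] <- 1
    list(probs = array(pm, c(model$n_logits, shp)), n_patches = n_patches)
  })
}
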