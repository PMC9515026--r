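# Nested-patch pyramid geometry and patch sampling.
#
# All levels share one physical centre and one fixed voxel matrix M^3; the
# physical patch size decreases from a coarsest level spanning a stated
# fraction of the image down to the finest spacing, with the intermediate
# spacings exponentially (geometrically) interpolated.

#' Specify a scale pyramid
#'
#' @param depth Number of levels D (default 4).
#' @param matrix Voxels per axis M of every patch (default 32).
#' @param finest_mm Spacing of the finest level in mm (default 1).
#' @param coverage Fraction of the smallest image-axis extent spanned by the
#'   coarsest patch (default 0.8).
#' @return A `pp_pyramid_spec`.
#' @export
scale_pyramid_spec <- function(depth = 4L, matrix = 32L, finest_mm = 1.0, coverage = 0.8) {
  assert_that(depth >= 1, "depth must be >= 1")
  assert_that(matrix >= 2, "matrix must be >= 2")
  assert_that(finest_mm > 0, "finest_mm must be positive")
  assert_that(coverage > 0 && coverage <= 1, "coverage must be in (0, 1]")
  structure(list(depth = as.integer(depth), matrix = as.integer(matrix),
                 finest_mm = as.numeric(finest_mm), coverage = as.numeric(coverage)),
            class = "pp_pyramid_spec")
}

#' Per-level spacings of the pyramid for a given image extent
#'
#' The coarsest spacing is `coverage * min(extent) / matrix`; the finest is
#' `finest_mm`; intermediate spacings interpolate geometrically:
#' `s_i = s_0 * (finest/s_0)^(i/(D-1))`.
#'
#' @param spec A [scale_pyramid_spec()].
#' @param image_extent_mm Physical image extent per axis in mm (length 3, or
#'   a scalar).
#' @return Numeric vector of D spacings (mm), strictly decreasing for D > 1.
#' @export
compute_scales <- function(spec, image_extent_mm) {
  assert_that(inherits(spec, "pp_pyramid_spec"), "spec must be a pp_pyramid_spec")
  ext <- min(image_extent_mm)
  if (spec$depth == 1L) return(spec$finest_mm)
  s0 <- spec$coverage * ext / spec$matrix
  if (s0 <= spec$finest_mm)
    stopf(paste("degenerate pyramid: coarsest spacing %.3f mm <= finest %.3f mm;",
                "image too small for the requested coverage/depth"),
          s0, spec$finest_mm)
  i <- seq(0, spec$depth - 1)
  s0 * (spec$finest_mm / s0)^(i / (spec$depth - 1))
}

#' Specify random patch augmentation
#'
#' One transform is drawn per patch stack and shared across all levels and
#' the paired label stack: isotropic scaling by up to `max_scale_frac`, then
#' rotation about a uniformly random axis by up to `max_rotation_deg`, then a
#' flip of the left-right axis with probability 1/2.
#'
#' @param max_rotation_deg Maximum rotation angle in degrees (default 10).
#' @param flip_axis Index of the left-right axis flipped with probability 0.5
#'   (default 1); `0` disables flipping.
#' @param max_scale_frac Maximum relative scaling (default 0.2).
#' @return A `pp_augment_spec`.
#' @export
augment_spec <- function(max_rotation_deg = 10, flip_axis = 1L, max_scale_frac = 0.2) {
  assert_that(max_rotation_deg >= 0 && max_rotation_deg < 90,
              "max_rotation_deg must be in [0, 90)")
  assert_that(max_scale_frac >= 0 && max_scale_frac < 1,
              "max_scale_frac must be in [0, 1)")
  structure(list(max_rotation_deg = max_rotation_deg, flip_axis = as.integer(flip_axis),
                 max_scale_frac = max_scale_frac),
            class = "pp_augment_spec")
}

# axis-angle rotation matrix
rotation_matrix <- function(axis, angle_rad) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

# Draw one joint augmentation transform (3x3 matrix applied to patch-grid
# offsets in mm). Identity when aug is NULL.
sample_transform <- function(aug) {
  if (is.null(aug)) return(diag(3))
  s <- 1 + runif(1, -aug$max_scale_frac, aug$max_scale_frac)
  R <- rotation_matrix(rand_unit(), runif(1, 0, aug$max_rotation_deg) * pi / 180)
  Tm <- R %*% (s * diag(3))
  if (aug$flip_axis >= 1 && runif(1) < 0.5) Tm[aug$flip_axis, ] <- -Tm[aug$flip_axis, ]
  Tm
}

# 3 x M^3 matrix of centred patch-grid offsets (voxel units, spacing 1)
patch_offsets <- function(M) {
  o <- seq_len(M) - 1 - (M - 1) / 2
  rbind(rep(o, times = M * M),
        rep(rep(o, each = M), times = M),
        rep(o, each = M * M))
}

#' Extract a nested patch stack from a volume
#'
#' Each level resamples an M^3 grid of spacing `scales[i]` centred on
#' `center_mm`, after applying one jointly sampled augmentation transform to
#' all levels. Out-of-bounds positions read -1024 HU. With `augment = NULL`
#' and an aligned centre, the finest level equals a plain crop.
#'
#' @param vol A [volume()].
#' @param center_mm Physical centre (mm, length 3); must lie inside the volume.
#' @param scales Per-level spacings from [compute_scales()].
#' @param matrix Patch matrix size M.
#' @param augment A [augment_spec()] or `NULL` for no augmentation.
#' @param seed Seed for the transform draw (`NULL`: use current RNG stream).
#' @param transform Optionally a fixed 3x3 transform (overrides sampling).
#' @return A `pp_patch_stack`: levels (each with `data` M^3 array and
#'   `spacing`), the shared centre and the realised transform.
#' @export
extract_stack <- function(vol, center_mm, scales, matrix = 32L, augment = NULL,
                          seed = NULL, transform = NULL) {
  assert_stack_pre(vol, center_mm)
  Tm <- transform %||% with_seed(seed, sample_transform(augment))
  levels <- lapply(scales, function(s) {
    vals <- sample_patch(vol, center_mm, s, matrix, Tm, interp = "trilinear", fill = -1024)
    list(data = array(vals, rep(matrix, 3)), spacing = s)
  })
  structure(list(center_mm = center_mm, levels = levels, matrix = as.integer(matrix),
                 transform = Tm), class = "pp_patch_stack")
}

#' Extract the label stack paired with an image stack
#'
#' Nearest-neighbour sampling under the identical transform as the image
#' stack, so image and label grids stay in register. Out-of-bounds positions
#' read background (0).
#'
#' @param lab A [label_map()].
#' @inheritParams extract_stack
#' @param transform The 3x3 transform realised by the paired image stack
#'   (`stack$transform`), or `NULL` for identity.
#' @return A `pp_patch_stack` of integer grids.
#' @export
extract_label_stack <- function(lab, center_mm, scales, matrix = 32L, transform = NULL) {
  assert_stack_pre(lab, center_mm)
  Tm <- transform %||% diag(3)
  levels <- lapply(scales, function(s) {
    vals <- sample_patch(lab, center_mm, s, matrix, Tm, interp = "nearest", fill = 0)
    list(data = array(as.integer(vals), rep(matrix, 3)), spacing = s)
  })
  structure(list(center_mm = center_mm, levels = levels, matrix = as.integer(matrix),
                 transform = Tm), class = "pp_patch_stack")
}

assert_stack_pre <- function(v, center_mm) {
  lo <- v$origin - v$spacing / 2
  hi <- v$origin + grid_extent_mm(v) - v$spacing / 2
  assert_that(all(center_mm >= lo) && all(center_mm <= hi),
              "patch centre (%s) lies outside the volume",
              paste(format(center_mm), collapse = ", "))
}

sample_patch <- function(v, center_mm, spacing, M, Tm, interp, fill) {
  off <- patch_offsets(M) * spacing          # mm offsets
  pts <- (Tm %*% off) + center_mm            # world mm
  vox <- (pts - v$origin) / v$spacing        # 0-based voxel coords
  arr <- array(as.double(v$data), c(1L, dim(v$data)))
  dims <- c(1L, dim(v$data))
  if (interp == "trilinear") cpp_trilinear_gather(arr, dims, vox, fill)[1, ]
  else cpp_nearest_gather(arr, dims, vox, fill)[1, ]
}

#' Sample label-biased training patch centres
#'
#' A fraction of centres is guaranteed to hit foreground: a foreground voxel
#' is drawn (uniformly over labels present, then uniformly over that label's
#' voxels, which balances volumetrically small labels into the training
#' stream) and jittered within one finest-patch half-extent. The remaining
#' centres are uniform over the volume.
#'
#' @param lab A [label_map()].
#' @param n_samples Number of centres.
#' @param patch_mm Physical span of the finest patch (matrix * finest
#'   spacing) in mm.
#' @param label_hit_fraction Fraction of centres whose finest patch must
#'   contain foreground (default 0.8).
#' @param seed Seed (`NULL`: current stream).
#' @param balance `"label"` (default) balances the guaranteed hits across
#'   labels; `"voxel"` draws them uniformly over all foreground voxels.
#' @return `n_samples` x 3 matrix of physical centres (mm).
#' @export
sample_training_centers <- function(lab, n_samples, patch_mm,
                                    label_hit_fraction = 0.8, seed = NULL,
                                    balance = c("label", "voxel")) {
  balance <- match.arg(balance)
  assert_that(label_hit_fraction >= 0 && label_hit_fraction <= 1,
              "label_hit_fraction must be in [0, 1]")
  fg_idx <- which(lab$data > 0L)
  if (label_hit_fraction > 0 && length(fg_idx) == 0)
    stopf("label map has no foreground but label_hit_fraction > 0")
  with_seed(seed, {
    n_hit <- rbinom(1, n_samples, label_hit_fraction)
    ext <- grid_extent_mm(lab)
    shp <- dim(lab$data)
    centers <- matrix(0, n_samples, 3)
    if (n_hit > 0) {
      if (balance == "label") {
        by_label <- split(fg_idx, lab$data[fg_idx])
        picks <- vapply(seq_len(n_hit), function(i) {
          g <- by_label[[sample.int(length(by_label), 1)]]
          g[sample.int(length(g), 1)]
        }, numeric(1))
      } else {
        picks <- fg_idx[sample.int(length(fg_idx), n_hit, replace = TRUE)]
      }
      pos <- t(vox_index_to_mm(picks, shp, lab$spacing, lab$origin))
      h <- pmax(patch_mm / 2 - lab$spacing / 2, 0)
      jit <- cbind(runif(n_hit, -h[1], h[1]), runif(n_hit, -h[2], h[2]),
                   runif(n_hit, -h[3], h[3]))
      cand <- pos + jit
      # clamping toward the volume keeps the picked voxel inside the patch
      lo <- lab$origin
      hi <- lab$origin + (shp - 1) * lab$spacing
      centers[seq_len(n_hit), ] <- pmin(pmax(cand, rep(lo, each = n_hit)),
                                        rep(hi, each = n_hit))
    }
    if (n_hit < n_samples) {
      m <- n_samples - n_hit
      u <- cbind(runif(m, 0, ext[1] - lab$spacing[1]),
                 runif(m, 0, ext[2] - lab$spacing[2]),
                 runif(m, 0, ext[3] - lab$spacing[3]))
      centers[(n_hit + 1):n_samples, ] <- sweep(u, 2, lab$origin, "+")
    }
    centers[sample.int(n_samples), , drop = FALSE]
  })
}

# linear 1-based voxel indices -> 3 x n matrix of physical mm positions
vox_index_to_mm <- function(idx, shp, spacing, origin) {
  i0 <- idx - 1
  x <- i0 %% shp[1]
  y <- (i0 %/% shp[1]) %% shp[2]
  z <- i0 %/% (shp[1] * shp[2])
  rbind(origin[1] + x * spacing[1], origin[2] + y * spacing[2], origin[3] + z * spacing[3])
}
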