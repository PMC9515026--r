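# Volumes and label maps on axis-aligned isotropic-convention grids.
#
# Geometry convention (used by every module): node-centred voxels; voxel
# (i, j, k) (1-based in R) sits at physical position
#   origin + (i - 1, j - 1, k - 1) * spacing   [mm]
# and the grid's physical extent per axis is shape * spacing (half-open).

#' Construct a CT volume
#'
#' A `pp_volume` is a 3D scalar grid of Hounsfield units together with its
#' voxel spacing and physical origin. Axis order is fixed (x fastest); only
#' axis-aligned geometries are represented.
#'
#' @param data 3D numeric array of intensities in HU.
#' @param spacing Per-axis voxel size in mm (length 3, or a scalar recycled).
#' @param origin Physical position of voxel (1,1,1) in mm (length 3).
#' @return An object of class `pp_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- squeeze3(data)
  spacing <- rep(as.numeric(spacing), length.out = 3)
  origin <- rep(as.numeric(origin), length.out = 3)
  assert_that(length(dim(data)) == 3, "volume data must have exactly 3 axes")
  assert_that(all(is.finite(spacing)) && all(spacing > 0),
              "voxel spacing must be positive and finite")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "pp_volume")
}

#' Construct a label map
#'
#' Integer grid on the same geometry as its paired volume; 0 is background,
#' 1..`n_labels` are foreground classes.
#'
#' @param data 3D array of integer label codes.
#' @param n_labels Number of foreground classes; defaults to `max(data)`.
#' @inheritParams volume
#' @return An object of class `pp_labelmap`.
#' @export
label_map <- function(data, n_labels = NULL, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- squeeze3(data)
  storage.mode(data) <- "integer"
  n_labels <- as.integer(n_labels %||% max(0L, max(data)))
  assert_that(length(dim(data)) == 3, "label map data must have exactly 3 axes")
  assert_that(min(data) >= 0L && max(data) <= n_labels,
              "label values must lie in [0, n_labels]")
  spacing <- rep(as.numeric(spacing), length.out = 3)
  origin <- rep(as.numeric(origin), length.out = 3)
  assert_that(all(is.finite(spacing)) && all(spacing > 0),
              "voxel spacing must be positive and finite")
  structure(list(data = data, n_labels = n_labels, spacing = spacing, origin = origin),
            class = "pp_labelmap")
}

squeeze3 <- function(data) {
  d <- dim(data)
  if (is.null(d)) stopf("grid data must be an array")
  if (length(d) > 3) {
    if (any(d[-(1:3)] != 1)) stopf("image has %d non-degenerate axes; need 3", sum(d > 1))
    dim(data) <- d[1:3]
  }
  data
}

#' @export
print.pp_volume <- function(x, ...) {
  cat(sprintf("<pp_volume> %s voxels, spacing %s mm, origin %s mm, HU range [%g, %g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.pp_labelmap <- function(x, ...) {
  cat(sprintf("<pp_labelmap> %s voxels, %d labels, spacing %s mm\n",
              paste(dim(x$data), collapse = "x"), x$n_labels,
              paste(format(x$spacing), collapse = ", ")))
  invisible(x)
}

grid_extent_mm <- function(v) dim(v$data) * v$spacing

phys_to_vox0 <- function(v, p) (p - v$origin) / v$spacing  # 0-based voxel coords

#' Read a volume from a NIfTI file
#'
#' Spacing and origin are taken from the header. Trailing degenerate axes
#' (length 1) are squeezed. Orientations beyond axis-aligned scaling are
#' normalised to axis-aligned with a warning: the pipeline assumes
#' axis-aligned grids throughout.
#'
#' @param path Path to a `.nii` / `.nii.gz` file with 3 spatial dimensions.
#' @return A [volume()].
#' @export
read_volume <- function(path) {
  hdr <- read_nifti_raw(path)
  volume(hdr$data, spacing = hdr$spacing, origin = hdr$origin)
}

#' Read a label map from a NIfTI file
#'
#' @inheritParams read_volume
#' @param n_labels Foreground class count; defaults to the maximum on-disk value.
#' @return A [label_map()].
#' @export
read_label_map <- function(path, n_labels = NULL) {
  hdr <- read_nifti_raw(path)
  label_map(round(hdr$data), n_labels = n_labels, spacing = hdr$spacing, origin = hdr$origin)
}

read_nifti_raw <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  img <- RNifti::readNifti(path)
  data <- as.array(img)
  data <- array(as.vector(data), dim(data))  # drop niftiImage attributes
  d <- dim(data)
  if (length(d) < 3) stopf("image in %s has %d dimensions; need 3", path, length(d))
  data <- squeeze3(data)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) stopf("non-finite or non-positive spacing in %s", path)
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- c(0, 0, 0)
  if (!inherits(xf, "try-error") && is.matrix(xf)) {
    rot <- xf[1:3, 1:3]
    offdiag <- rot - diag(diag(rot))
    if (max(abs(offdiag)) > 1e-4 * max(abs(diag(rot)))) {
      warning(sprintf("oblique orientation in %s normalised to axis-aligned", path))
    }
    origin <- xf[1:3, 4]
    if (any(diag(rot) < 0)) origin <- ifelse(diag(rot) < 0, -origin, origin)
  }
  list(data = data, spacing = sp, origin = as.numeric(origin))
}

#' Write a volume or label map to a NIfTI file
#'
#' Label maps are stored with an integer on-disk type; volumes as float.
#' The header encodes spacing and origin in an axis-aligned affine.
#'
#' @param v A [volume()] or [label_map()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(v, path) {
  assert_that(inherits(v, "pp_volume") || inherits(v, "pp_labelmap"),
              "write_volume expects a pp_volume or pp_labelmap")
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  aff <- diag(c(v$spacing, 1))
  aff[1:3, 4] <- v$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  dtype <- if (inherits(v, "pp_labelmap")) "int16" else "float"
  ok <- try(RNifti::writeNifti(img, path, datatype = dtype), silent = TRUE)
  if (inherits(ok, "try-error")) stopf("failed to write %s: %s", path, attr(ok, "condition")$message)
  invisible(path)
}

#' Resample a volume or label map to an isotropic grid
#'
#' Volumes use trilinear interpolation; label maps nearest-neighbour, so label
#' values are never invented. The physical extent is preserved to within one
#' voxel. Positions sampled outside the input grid are filled with -1024 HU
#' (air) for volumes and 0 (background) for label maps.
#'
#' @param v A [volume()] or [label_map()].
#' @param target_mm Isotropic output voxel size in mm (> 0).
#' @return The same kind of object on a `target_mm` isotropic grid.
#' @export
resample_isotropic <- function(v, target_mm) {
  assert_that(is.numeric(target_mm) && length(target_mm) == 1 && target_mm > 0,
              "target_mm must be a positive scalar")
  in_dim <- dim(v$data)
  if (all(abs(v$spacing - target_mm) < 1e-12)) return(v)
  out_dim <- pmax(1L, as.integer(round(in_dim * v$spacing / target_mm)))
  # output voxel i (0-based) lies at origin + i*target; map into input voxel units
  coords <- grid_coords0(out_dim) * target_mm
  vox <- coords / v$spacing  # input 0-based voxel coordinates (shared origin)
  is_lab <- inherits(v, "pp_labelmap")
  arr <- array(as.double(v$data), c(1L, in_dim))
  vals <- if (is_lab) {
    cpp_nearest_gather(arr, c(1L, in_dim), vox, 0)
  } else {
    cpp_trilinear_gather(arr, c(1L, in_dim), vox, -1024)
  }
  out <- array(vals[1, ], out_dim)
  if (is_lab) label_map(out, n_labels = v$n_labels, spacing = rep(target_mm, 3), origin = v$origin)
  else volume(out, spacing = rep(target_mm, 3), origin = v$origin)
}

# 3 x N matrix of 0-based grid coordinates for an output shape, x fastest
grid_coords0 <- function(shape) {
  ix <- seq_len(shape[1]) - 1
  iy <- seq_len(shape[2]) - 1
  iz <- seq_len(shape[3]) - 1
  rbind(rep(ix, times = shape[2] * shape[3]),
        rep(rep(iy, each = shape[1]), times = shape[3]),
        rep(iz, each = shape[1] * shape[2]))
}
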