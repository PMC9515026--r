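# Synthetic CT phantom generator.
#
# Emulates the structure taxonomy of a craniomaxillofacial head CT at desk
# scale: a large high-attenuation shell (bone analog), a thin bony plate
# (septum analog), an air cavity inside the shell (sinus analog), a thin
# soft-tissue tube piercing the bone wall (canal analog), a millimetric blob
# embedded in the wall (foramen analog) and a soft-tissue ellipsoid. Each
# phantom is a (volume, label map) pair on the same grid.

#' Describe one synthetic structure class
#'
#' @param label_id Integer label code (>= 1).
#' @param shape_kind One of `"ellipsoid"`, `"shell"`, `"plate"`, `"tube"`,
#'   `"blob"`, `"cavity"`.
#' @param size_range_mm Min/max characteristic diameter in mm.
#' @param hu_range Min/max mean intensity in HU (within \[-1024, 3071\]).
#' @param count_range Min/max instances per phantom.
#' @param small_flag Whether the label is trained under the top-K
#'   binary cross-entropy regime (volumetrically small structures).
#' @param thickness_range_mm Wall/plate thickness range (shells and plates).
#' @param length_range_mm Axis length range (tubes).
#' @param host Label id of a shell this structure is placed inside of
#'   (cavities, plates, interior soft tissue).
#' @param through Label id of a shell whose wall this structure pierces
#'   (tubes) or is embedded in (blobs).
#' @return A `pp_blueprint` list.
#' @export
structure_blueprint <- function(label_id, shape_kind, size_range_mm, hu_range,
                                count_range = c(1, 1), small_flag = FALSE,
                                thickness_range_mm = NULL, length_range_mm = NULL,
                                host = NULL, through = NULL) {
  shape_kind <- match.arg(shape_kind, c("ellipsoid", "shell", "plate", "tube", "blob", "cavity"))
  assert_that(label_id >= 1, "label_id must be >= 1")
  assert_that(all(size_range_mm > 0) && size_range_mm[1] <= size_range_mm[2],
              "size range must be positive with min <= max")
  assert_that(all(hu_range >= -1024) && all(hu_range <= 3071) && hu_range[1] <= hu_range[2],
              "hu_range must lie within [-1024, 3071]")
  structure(list(label_id = as.integer(label_id), shape_kind = shape_kind,
                 size_range_mm = as.numeric(size_range_mm), hu_range = as.numeric(hu_range),
                 count_range = as.integer(count_range), small_flag = isTRUE(small_flag),
                 thickness_range_mm = thickness_range_mm, length_range_mm = length_range_mm,
                 host = host, through = through),
            class = "pp_blueprint")
}

#' Specify a synthetic phantom
#'
#' @param grid_shape Three positive integers (voxels per axis).
#' @param spacing_mm Isotropic voxel size in mm.
#' @param blueprints List of [structure_blueprint()]s; label ids must be
#'   unique and contiguous from 1. List order is rasterisation precedence:
#'   a voxel keeps the first foreground label assigned to it.
#' @param noise_sigma_hu Standard deviation of additive Gaussian HU noise.
#' @param background_hu Background intensity (default -1024, air).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A `pp_phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape, spacing_mm = 1, blueprints,
                         noise_sigma_hu = 0, background_hu = -1024, seed = 1L) {
  grid_shape <- rep(as.integer(grid_shape), length.out = 3)
  assert_that(all(grid_shape >= 1), "grid_shape must be positive")
  assert_that(spacing_mm > 0, "spacing_mm must be positive")
  assert_that(noise_sigma_hu >= 0, "noise_sigma_hu must be >= 0")
  ids <- sort(vapply(blueprints, function(b) b$label_id, integer(1)))
  assert_that(identical(ids, seq_along(blueprints)),
              "blueprint label ids must be unique and contiguous from 1")
  extent <- min(grid_shape) * spacing_mm
  for (b in blueprints)
    assert_that(max(b$size_range_mm) <= extent,
                "blueprint %d cannot fit in the grid (max size %.1f mm > extent %.1f mm)",
                b$label_id, max(b$size_range_mm), extent)
  structure(list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
                 blueprints = blueprints, noise_sigma_hu = as.numeric(noise_sigma_hu),
                 background_hu = as.numeric(background_hu), seed = as.integer(seed)),
            class = "pp_phantom_spec")
}

#' Default craniomaxillofacial-style phantom specification
#'
#' Six labels spanning the taxonomy used throughout the package:
#' 1 bone shell, 2 thin bony plate, 3 air cavity inside the shell,
#' 4 thin soft-tissue tube through the bone wall (canal analog, small),
#' 5 millimetric blob embedded in the wall (foramen analog, small),
#' 6 soft-tissue ellipsoid. Canals and foramina are placed in the bone wall
#' because that is where their real counterparts live; it also gives them the
#' bone-against-soft-tissue contrast that makes them segmentable at all.
#'
#' @param grid_shape Voxels per axis (default 96^3).
#' @param spacing_mm Isotropic voxel size (default 1 mm).
#' @param seed Seed stored in the spec.
#' @param noise_sigma_hu HU noise level (default 20, a typical soft-kernel
#'   reconstruction noise).
#' @return A [phantom_spec()].
#' @export
default_cmf_spec <- function(grid_shape = c(96, 96, 96), spacing_mm = 1, seed = 1L,
                             noise_sigma_hu = 20) {
  ext <- min(rep(grid_shape, length.out = 3)) * spacing_mm
  # interior structures scale with the grid so the anatomy stays placeable;
  # canal/foramen calibres stay absolute -- they are millimetric by definition
  bp <- list(
    structure_blueprint(1L, "shell", c(0.60, 0.80) * ext, c(700, 1300),
                        thickness_range_mm = pmax(c(0.052, 0.083) * ext, 2)),
    structure_blueprint(2L, "plate", c(0.23, 0.33) * ext, c(700, 1300),
                        thickness_range_mm = c(1, 2), host = 1L),
    structure_blueprint(3L, "cavity", c(0.10, 0.19) * ext, c(-1000, -950), host = 1L),
    structure_blueprint(4L, "tube", c(2, 4), c(20, 70), small_flag = TRUE,
                        length_range_mm = c(0.21, 0.31) * ext, through = 1L),
    structure_blueprint(5L, "blob", c(2, 3), c(20, 70), small_flag = TRUE, through = 1L),
    structure_blueprint(6L, "ellipsoid", c(0.16, 0.26) * ext, c(0, 80), host = 1L)
  )
  # rasterisation precedence: fine structures first so they carve the bone
  # wall; shell last. Label ids stay as declared above.
  order <- c(4, 5, 2, 3, 6, 1)
  phantom_spec(grid_shape, spacing_mm, bp[order],
               noise_sigma_hu = noise_sigma_hu, seed = seed)
}

#' Generate a phantom volume and label map
#'
#' Deterministic given `spec$seed`. Structures are placed with bounded
#' retries; instances that cannot be placed inside the grid raise an error.
#' Intensities are the instance's mean HU (drawn uniformly from the
#' blueprint's `hu_range`) plus i.i.d. Gaussian noise, rounded to integers.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` ([volume()]) and `labels`
#'   ([label_map()]).
#' @export
generate_phantom <- function(spec) {
  assert_that(inherits(spec, "pp_phantom_spec"), "spec must be a pp_phantom_spec")
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  # geometry is resolved first (shells before their dependents), then
  # rasterised in blueprint list order with first-label-wins precedence;
  # if a mandatory label is fully swallowed by an earlier one, the whole
  # phantom is redrawn (still deterministic: the RNG stream just continues)
  for (attempt in 1:5) {
    out <- try(generate_phantom_once(spec), silent = TRUE)
    if (!inherits(out, "try-error")) return(out)
  }
  stop(attr(out, "condition"))
}

generate_phantom_once <- function(spec) {
  shp <- spec$grid_shape
  sp <- spec$spacing_mm
  ext <- shp * sp
  lab <- array(0L, shp)
  vol <- array(spec$background_hu, shp)
  # physical coordinate arrays (mm), voxel (1,1,1) at 0
  ax <- lapply(1:3, function(a) (seq_len(shp[a]) - 1) * sp)
  shell_geom <- list()

  draw_geometry <- function(b) {
    d <- runif(1, b$size_range_mm[1], b$size_range_mm[2])
    g <- list(kind = b$shape_kind, diameter = d)
    host <- if (!is.null(b$host)) shell_geom[[as.character(b$host)]] else NULL
    wall <- if (!is.null(b$through)) shell_geom[[as.character(b$through)]] else NULL
    center_in_interior <- function(margin) {
      if (!is.null(host)) {
        rad <- (host$diameter / 2 - host$thickness) - margin
        rad <- max(rad, 0)
        dir <- rand_unit()
        host$center + dir * runif(1, 0, rad)
      } else {
        runif(3, margin, ext - margin)
      }
    }
    point_on_wall <- function(wl) {
      dir <- rand_unit()
      rad_dir <- 1 / sqrt(sum((dir / wl$semi)^2))  # ellipsoid radius along dir
      wl$center + dir * (rad_dir - wl$thickness / 2)
    }
    switch(b$shape_kind,
      shell = {
        g$thickness <- runif(1, b$thickness_range_mm[1] %||% (0.08 * d),
                             b$thickness_range_mm[2] %||% (0.12 * d))
        margin <- d / 2 + sp
        assert_that(all(ext - 2 * margin > 0), "shell too large for grid")
        g$center <- runif(3, margin, ext - margin)
        g$semi <- rep(d / 2, 3) * runif(3, 0.9, 1.0)
      },
      ellipsoid = {
        g$center <- center_in_interior(d / 2)
        g$semi <- rep(d / 2, 3) * runif(3, 0.8, 1.0)
      },
      cavity = {
        g$center <- center_in_interior(d / 2)
        g$semi <- rep(d / 2, 3) * runif(3, 0.8, 1.0)
      },
      blob = {
        g$center <- if (!is.null(wall)) point_on_wall(wall) else center_in_interior(d / 2)
        g$semi <- rep(d / 2, 3)
      },
      plate = {
        g$thickness <- runif(1, b$thickness_range_mm[1] %||% 1, b$thickness_range_mm[2] %||% 2)
        g$center <- center_in_interior(d / 4)
        g$normal <- rand_unit()
      },
      tube = {
        g$radius <- d / 2
        g$length <- runif(1, b$length_range_mm[1] %||% (0.3 * min(ext)),
                          b$length_range_mm[2] %||% (0.5 * min(ext)))
        g$axis <- rand_unit()
        g$center <- if (!is.null(wall)) point_on_wall(wall) else center_in_interior(g$length / 4)
      })
    g
  }

  bbox_of <- function(g) {
    r <- switch(g$kind,
      shell = rep(max(g$semi), 3), ellipsoid = rep(max(g$semi), 3),
      cavity = rep(max(g$semi), 3), blob = rep(max(g$semi), 3),
      plate = abs(g$normal) * g$thickness / 2 +
        sqrt(pmax(1 - g$normal^2, 0)) * g$diameter / 2,
      tube = abs(g$axis) * g$length / 2 + sqrt(pmax(1 - g$axis^2, 0)) * g$radius)
    if (g$kind == "tube") r <- r + 0.5  # rasterisation slack
    list(lo = g$center - r, hi = g$center + r)
  }

  inside_grid <- function(g) {
    bb <- bbox_of(g)
    all(bb$lo >= -sp / 2) && all(bb$hi <= ext - sp / 2)
  }

  rasterize <- function(g) {
    bb <- bbox_of(g)
    i0 <- pmax(1L, as.integer(floor(bb$lo / sp)) + 1L)
    i1 <- pmin(shp, as.integer(ceiling(bb$hi / sp)) + 1L)
    xs <- ax[[1]][i0[1]:i1[1]]; ys <- ax[[2]][i0[2]:i1[2]]; zs <- ax[[3]][i0[3]:i1[3]]
    nx <- length(xs); ny <- length(ys); nz <- length(zs)
    X <- array(xs, c(nx, ny, nz))
    Y <- array(rep(ys, each = nx), c(nx, ny, nz))
    Z <- array(rep(zs, each = nx * ny), c(nx, ny, nz))
    dx <- X - g$center[1]; dy <- Y - g$center[2]; dz <- Z - g$center[3]
    mask <- switch(g$kind,
      ellipsoid = ,
      cavity = ,
      blob = (dx / g$semi[1])^2 + (dy / g$semi[2])^2 + (dz / g$semi[3])^2 <= 1,
      shell = {
        so <- g$semi; si <- pmax(g$semi - g$thickness, 0.1)
        ro <- (dx / so[1])^2 + (dy / so[2])^2 + (dz / so[3])^2
        ri <- (dx / si[1])^2 + (dy / si[2])^2 + (dz / si[3])^2
        ro <= 1 & ri > 1
      },
      plate = {
        n <- g$normal
        along <- dx * n[1] + dy * n[2] + dz * n[3]
        r2 <- dx^2 + dy^2 + dz^2 - along^2
        abs(along) <= g$thickness / 2 & r2 <= (g$diameter / 2)^2
      },
      tube = {
        a <- g$axis
        along <- dx * a[1] + dy * a[2] + dz * a[3]
        r2 <- dx^2 + dy^2 + dz^2 - along^2
        r2 <= g$radius^2 & abs(along) <= g$length / 2
      })
    list(i0 = i0, i1 = i1, mask = mask)
  }

  bounding_radius <- function(g) max(bbox_of(g)$hi - g$center)

  # phase 1: resolve geometry; shells first so hosted structures can refer
  # to them, everything else in list order with separation retries
  ord <- order(!vapply(spec$blueprints, function(b) b$shape_kind == "shell", logical(1)))
  instances <- list()
  placed_interior <- list()
  for (bi in ord) {
    b <- spec$blueprints[[bi]]
    count <- if (b$count_range[1] == b$count_range[2]) b$count_range[1]
             else sample(b$count_range[1]:b$count_range[2], 1)
    for (inst in seq_len(count)) {
      placed <- FALSE
      for (try_i in 1:100) {
        g <- draw_geometry(b)
        if (!inside_grid(g)) next
        if (b$shape_kind %in% c("plate", "cavity", "ellipsoid") && length(placed_interior)) {
          sepOK <- all(vapply(placed_interior, function(p) {
            sqrt(sum((p$center - g$center)^2)) >= 0.5 * (bounding_radius(p) + bounding_radius(g))
          }, logical(1)))
          if (!sepOK) next
        }
        instances[[length(instances) + 1L]] <- list(blueprint = bi, geom = g)
        if (b$shape_kind == "shell") shell_geom[[as.character(b$label_id)]] <- g
        if (b$shape_kind %in% c("plate", "cavity", "ellipsoid"))
          placed_interior[[length(placed_interior) + 1L]] <- g
        placed <- TRUE
        break
      }
      if (!placed)
        stopf("could not place blueprint %d (instance %d) after bounded retries",
              b$label_id, inst)
    }
  }

  # phase 2: rasterise in blueprint list order; first foreground label wins
  inst_order <- order(vapply(instances, function(x) x$blueprint, integer(1)))
  for (ii in inst_order) {
    b <- spec$blueprints[[instances[[ii]]$blueprint]]
    ras <- rasterize(instances[[ii]]$geom)
    sub <- lab[ras$i0[1]:ras$i1[1], ras$i0[2]:ras$i1[2], ras$i0[3]:ras$i1[3]]
    write_mask <- ras$mask & sub == 0L
    hu_mean <- runif(1, b$hu_range[1], b$hu_range[2])
    sub[write_mask] <- b$label_id
    lab[ras$i0[1]:ras$i1[1], ras$i0[2]:ras$i1[2], ras$i0[3]:ras$i1[3]] <- sub
    vsub <- vol[ras$i0[1]:ras$i1[1], ras$i0[2]:ras$i1[2], ras$i0[3]:ras$i1[3]]
    vsub[write_mask] <- hu_mean
    vol[ras$i0[1]:ras$i1[1], ras$i0[2]:ras$i1[2], ras$i0[3]:ras$i1[3]] <- vsub
  }
  present <- sort(unique(as.integer(lab[lab > 0L])))
  mandatory <- vapply(spec$blueprints[vapply(spec$blueprints, function(b) b$count_range[1] >= 1L, logical(1))],
                      function(b) b$label_id, integer(1))
  if (!all(mandatory %in% present))
    stopf("label(s) %s fully swallowed during rasterisation",
          paste(setdiff(mandatory, present), collapse = ", "))
  if (spec$noise_sigma_hu > 0)
    vol <- vol + rnorm(length(vol), 0, spec$noise_sigma_hu)
  vol <- round(vol)
  n_lab <- length(spec$blueprints)
  list(volume = volume(vol, spacing = rep(sp, 3)),
       labels = label_map(lab, n_labels = n_lab, spacing = rep(sp, 3)))
}

rand_unit <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

#' Small/large designations declared by a phantom spec
#' @param spec A [phantom_spec()].
#' @return Named logical vector over label ids in ascending order.
#' @export
small_flags <- function(spec) {
  ids <- vapply(spec$blueprints, function(b) b$label_id, integer(1))
  fl <- vapply(spec$blueprints, function(b) b$small_flag, logical(1))
  fl[order(ids)]
}
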