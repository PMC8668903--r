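## Synthetic tumour scenes with known ground truth.
##
## The generator stands in for undeposited SBF-SEM stacks: ellipsoidal tumour
## cells with concentric nuclei and small spherical mitochondria, an optional
## tubular capillary, and three axis-orientation models (isotropic,
## plane-aligned, hotspot-convergent). Every drawn quantity is recorded as
## ground truth so each analysis stage can be tested as parameter recovery.

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

unit3 <- function(v) v / sqrt(sum(v^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

# any unit vector perpendicular to u
perp_unit <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit3(cross3(u, ref))
}

# wrap an angle in degrees into (-90, 90] (axes are unsigned, period 180)
wrap_axial <- function(theta) theta - 180 * round(theta / 180)

point_segment_distance <- function(p, a, b) {
  ab <- b - a
  denom <- sum(ab^2)
  t <- if (denom == 0) 0 else min(max(sum((p - a) * ab) / denom, 0), 1)
  sqrt(sum((p - (a + t * ab))^2))
}

#' Axis-orientation models for synthetic scenes
#'
#' `orientation_isotropic()` draws cell main axes uniformly on the sphere.
#' `orientation_plane(normal, sigma_deg)` draws axes in the plane with the
#' given normal, tilted out of plane by a wrapped-normal angle (sd
#' `sigma_deg`); the tilt equals the inclination angle, so the expected share
#' of inclinations below any cutoff has a closed form.
#' `orientation_hotspot(point, fraction, sigma_deg)` aims a fixed fraction of
#' cells (rounded; the first cells generated) at a common point, perturbing
#' the aim direction by a wrapped-normal angle; the remaining cells are
#' isotropic. `point = NULL` aims at the volume centre.
#'
#' @param normal plane normal (any length; normalized internally).
#' @param sigma_deg angular sd in degrees (>= 0).
#' @param point hotspot point `c(x, y, z)` in micrometres, or NULL.
#' @param fraction fraction of cells aimed at the hotspot, in (0, 1].
#' @return An orientation-model object used by [scene_config()].
#' @export
orientation_isotropic <- function() {
  structure(list(type = "isotropic"), class = "orientation_model")
}

#' @rdname orientation_isotropic
#' @export
orientation_plane <- function(normal = c(0, 0, 1), sigma_deg = 10) {
  stopifnot(sigma_deg >= 0)
  structure(list(type = "plane_aligned", normal = unit3(normal),
                 sigma_deg = sigma_deg),
            class = "orientation_model")
}

#' @rdname orientation_isotropic
#' @export
orientation_hotspot <- function(point = NULL, fraction = 0.4, sigma_deg = 5) {
  stopifnot(sigma_deg >= 0, fraction > 0, fraction <= 1)
  structure(list(type = "hotspot", point = point, fraction = fraction,
                 sigma_deg = sigma_deg),
            class = "orientation_model")
}

#' Capillary specification for synthetic scenes
#'
#' A straight tube between two endpoints, standing in for the blood
#' capillary irrigating the tissue.
#'
#' @param p0,p1 endpoints in micrometres.
#' @param radius_um tube radius in micrometres.
#' @return A `capillary_spec` object.
#' @export
capillary_spec <- function(p0, p1, radius_um = 2) {
  stopifnot(length(p0) == 3, length(p1) == 3, radius_um > 0)
  structure(list(p0 = as.numeric(p0), p1 = as.numeric(p1),
                 radius_um = radius_um),
            class = "capillary_spec")
}

#' Synthetic scene configuration
#'
#' Desk-scale defaults: a 256 x 256 x 64 grid at 150 x 150 x 300 nm spacing
#' (38.4 x 38.4 x 19.2 um of tissue). Physical formulas are scale-free, so
#' this stands in for acquisition-scale stacks at a tractable size. Cells are
#' ellipsoids with aspect ratio drawn from [1.5, 3] (so the major axis is
#' well defined and the PCA axis has an exact analytic oracle); the nucleus
#' is a concentric ellipsoid holding `nucleus_volume_fraction` of the cell
#' volume (default 0.32, the composition observed in hepatoblastoma tissue);
#' mitochondria are small spheres confined to the cytoplasm (desk-scale
#' count 20-40 per cell; real cells carry an order of magnitude more).
#'
#' @param dims grid dimensions `c(nx, ny, nz)`.
#' @param spacing a [voxel_spacing()] in nm.
#' @param n_cells number of cells to place (>= 0).
#' @param cell_radius_mean,cell_radius_sd volume-equivalent cell radius
#'   distribution, micrometres.
#' @param nucleus_volume_fraction nucleus/cell volume ratio in (0, 1).
#' @param mito_per_cell integer range `c(lo, hi)` of mitochondria per cell.
#' @param mito_radius_um range of mitochondrion radii, micrometres.
#' @param orientation an orientation model, see [orientation_isotropic()].
#' @param capillary a [capillary_spec()] or NULL.
#' @param size_distance_beta slope of mean cell radius versus normalized
#'   capillary distance: the mean radius at the farthest point of the volume
#'   is `(1 - beta)` times the mean at the capillary wall. Positive values
#'   give the near-capillary size advantage seen in tumour tissue.
#' @param interior_only when TRUE, cell centres are sampled at least one
#'   major semi-axis away from every stack face, so all generated cells are
#'   complete (a field of view fully containing the sampled cells); when
#'   FALSE (default) centres are uniform over the volume and boundary cells
#'   are marked incomplete in the truth.
#' @param seed integer seed; identical configs generate identical scenes.
#' @param max_attempts rejection-sampling attempts per cell before erroring.
#' @return A `scene_config` object.
#' @export
scene_config <- function(dims = c(256, 256, 64),
                         spacing = voxel_spacing(150, 150, 300),
                         n_cells = 40,
                         cell_radius_mean = 3,
                         cell_radius_sd = 0.4,
                         nucleus_volume_fraction = 0.32,
                         mito_per_cell = c(20, 40),
                         mito_radius_um = c(0.25, 0.45),
                         orientation = orientation_isotropic(),
                         capillary = NULL,
                         size_distance_beta = 0,
                         interior_only = FALSE,
                         seed = 1,
                         max_attempts = 1000) {
  stopifnot(length(dims) == 3, all(dims >= 1),
            inherits(spacing, "voxel_spacing"),
            n_cells >= 0,
            cell_radius_mean > 0, cell_radius_sd >= 0,
            nucleus_volume_fraction > 0, nucleus_volume_fraction < 1,
            length(mito_per_cell) == 2, all(mito_per_cell >= 0),
            inherits(orientation, "orientation_model"),
            is.null(capillary) || inherits(capillary, "capillary_spec"),
            size_distance_beta >= 0, size_distance_beta < 1,
            is.logical(interior_only),
            max_attempts >= 1)
  structure(list(dims = as.integer(dims), spacing = spacing,
                 n_cells = as.integer(n_cells),
                 cell_radius_mean = cell_radius_mean,
                 cell_radius_sd = cell_radius_sd,
                 nucleus_volume_fraction = nucleus_volume_fraction,
                 mito_per_cell = as.integer(mito_per_cell),
                 mito_radius_um = mito_radius_um,
                 orientation = orientation,
                 capillary = capillary,
                 size_distance_beta = size_distance_beta,
                 interior_only = interior_only,
                 seed = as.integer(seed),
                 max_attempts = as.integer(max_attempts)),
            class = "scene_config")
}

# index range of voxels whose centres may fall within [lo, hi] um on an axis
index_range <- function(lo, hi, step_um, n) {
  i0 <- max(1L, as.integer(floor(lo / step_um + 0.5)))
  i1 <- min(n, as.integer(ceiling(hi / step_um + 0.5)))
  if (i0 > i1) integer(0) else i0:i1
}

# voxel-centre coordinate arrays over an index box (micrometres)
box_coords <- function(rx, ry, rz, sp_um) {
  xs <- (rx - 0.5) * sp_um[1]
  ys <- (ry - 0.5) * sp_um[2]
  zs <- (rz - 0.5) * sp_um[3]
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  list(
    x = array(rep(xs, times = ny * nz), dim = c(nx, ny, nz)),
    y = array(rep(rep(ys, each = nx), times = nz), dim = c(nx, ny, nz)),
    z = array(rep(zs, each = nx * ny), dim = c(nx, ny, nz))
  )
}

# draw the main-axis direction for one cell under the configured model
draw_axis <- function(model, centre, aimed, hotspot_point) {
  if (model$type == "isotropic") return(random_unit_vector())
  if (model$type == "plane_aligned") {
    n <- model$normal
    e1 <- perp_unit(n)
    e2 <- cross3(n, e1)
    phi <- stats::runif(1, 0, 2 * pi)
    theta <- wrap_axial(stats::rnorm(1, 0, model$sigma_deg)) * pi / 180
    return(cos(theta) * (cos(phi) * e1 + sin(phi) * e2) + sin(theta) * n)
  }
  # hotspot model
  if (!aimed) return(random_unit_vector())
  d0 <- unit3(hotspot_point - centre)
  psi <- wrap_axial(stats::rnorm(1, 0, model$sigma_deg)) * pi / 180
  w <- unit3(cross3(d0, random_unit_vector()))
  cos(psi) * d0 + sin(psi) * w
}

#' Generate a synthetic tumour scene
#'
#' Places `n_cells` ellipsoidal cells by sequential rejection sampling
#' (bounding-sphere separation guarantees voxel-wise disjointness from other
#' cells and the capillary), voxelizes cells, concentric nuclei, cytoplasmic
#' mitochondria and the capillary into one flat label volume, and records
#' complete ground truth. Identical configs (including the seed) give
#' bit-identical scenes.
#'
#' @param config a [scene_config()].
#' @return A `synthetic_scene`: list with `labels` (a [label_volume()]),
#'   `segments` (a [segment_table()]), `truth` (one row per cell: labels,
#'   true centre, semi-axes, unit major axis, polarized flag, true
#'   capillary distance, completeness of cell and nucleus) and `model`
#'   (scene-level truth: plane normal or hotspot point, capillary geometry).
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, generate_scene_impl(config))
}

generate_scene_impl <- function(config) {
  dims <- config$dims
  sp_um <- unname(unclass(config$spacing)) * 1e-3   # nm -> um
  ext <- dims * sp_um                               # physical extent, um
  labels <- array(0L, dim = dims)
  segs <- data.frame(label_id = integer(), class = character(),
                     parent_id = integer(), notes = character(),
                     stringsAsFactors = FALSE)
  model <- config$orientation
  cap <- config$capillary

  hotspot_point <- NULL
  if (model$type == "hotspot") {
    hotspot_point <- if (is.null(model$point)) ext / 2 else model$point
  }

  next_id <- 1L
  # capillary gets the first label so cell ids do not depend on its presence
  cap_id <- NA_integer_
  if (!is.null(cap)) {
    cap_id <- next_id
    next_id <- next_id + 1L
    lo <- pmin(cap$p0, cap$p1) - cap$radius_um
    hi <- pmax(cap$p0, cap$p1) + cap$radius_um
    rx <- index_range(lo[1], hi[1], sp_um[1], dims[1])
    ry <- index_range(lo[2], hi[2], sp_um[2], dims[2])
    rz <- index_range(lo[3], hi[3], sp_um[3], dims[3])
    if (length(rx) && length(ry) && length(rz)) {
      co <- box_coords(rx, ry, rz, sp_um)
      ab <- cap$p1 - cap$p0
      denom <- sum(ab^2)
      px <- co$x - cap$p0[1]; py <- co$y - cap$p0[2]; pz <- co$z - cap$p0[3]
      t <- if (denom == 0) 0 else
        pmin(pmax((px * ab[1] + py * ab[2] + pz * ab[3]) / denom, 0), 1)
      d2 <- (px - t * ab[1])^2 + (py - t * ab[2])^2 + (pz - t * ab[3])^2
      sub <- labels[rx, ry, rz, drop = FALSE]
      sub[d2 <= cap$radius_um^2] <- cap_id
      labels[rx, ry, rz] <- sub
    }
    segs <- rbind(segs, data.frame(label_id = cap_id, class = "capillary",
                                   parent_id = NA_integer_, notes = "",
                                   stringsAsFactors = FALSE))
  }

  # distance normalization for the size-distance gradient: farthest corner
  d_max <- NA_real_
  if (!is.null(cap)) {
    corners <- as.matrix(expand.grid(c(0, ext[1]), c(0, ext[2]), c(0, ext[3])))
    d_max <- max(apply(corners, 1, function(p)
      point_segment_distance(p, cap$p0, cap$p1))) - cap$radius_um
    d_max <- max(d_max, 1e-6)
  }

  n_aim <- if (model$type == "hotspot") {
    as.integer(round(model$fraction * config$n_cells))
  } else 0L

  cells <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    placed <- FALSE
    for (attempt in seq_len(config$max_attempts)) {
      centre <- stats::runif(3) * ext
      dist_cap <- NA_real_
      if (!is.null(cap)) {
        dist_cap <- point_segment_distance(centre, cap$p0, cap$p1) -
          cap$radius_um
      }
      base_r <- config$cell_radius_mean
      if (!is.null(cap) && config$size_distance_beta > 0) {
        base_r <- base_r *
          (1 - config$size_distance_beta * max(dist_cap, 0) / d_max)
      }
      r <- stats::rnorm(1, base_r, config$cell_radius_sd)
      r <- max(r, 0.3 * config$cell_radius_mean)
      q <- stats::runif(1, 1.5, 3)
      semi <- c(r * q^(2 / 3), r * q^(-1 / 3), r * q^(-1 / 3))
      aimed <- i <= n_aim
      axis <- draw_axis(model, centre, aimed, hotspot_point)
      # bounding-sphere separation from accepted cells and the capillary
      ok <- TRUE
      if (config$interior_only &&
          (any(centre < semi[1]) || any(centre > ext - semi[1]))) ok <- FALSE
      if (!is.null(cap) && dist_cap < semi[1]) ok <- FALSE
      if (ok) {
        for (cl in cells) {
          if (is.null(cl)) next
          if (sqrt(sum((centre - cl$centre)^2)) <= semi[1] + cl$semi[1]) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) {
        cells[[i]] <- list(centre = centre, semi = semi, axis = axis,
                           aimed = aimed, dist_cap = dist_cap)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(paste0("could not place cell %d after %d attempts; ",
                          "reduce n_cells or enlarge dims"),
                   i, config$max_attempts))
    }
  }

  nuc_scale <- config$nucleus_volume_fraction^(1 / 3)
  truth <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    cl <- cells[[i]]
    cell_id <- next_id
    nuc_id <- next_id + 1L
    next_id <- next_id + 2L
    u <- unit3(cl$axis)
    w1 <- perp_unit(u)
    w2 <- cross3(u, w1)
    R <- cbind(u, w1, w2)
    a <- cl$semi[1]; b <- cl$semi[2]; cc <- cl$semi[3]

    rx <- index_range(cl$centre[1] - a, cl$centre[1] + a, sp_um[1], dims[1])
    ry <- index_range(cl$centre[2] - a, cl$centre[2] + a, sp_um[2], dims[2])
    rz <- index_range(cl$centre[3] - a, cl$centre[3] + a, sp_um[3], dims[3])
    mito_ids <- integer(0)
    if (length(rx) && length(ry) && length(rz)) {
      co <- box_coords(rx, ry, rz, sp_um)
      px <- co$x - cl$centre[1]
      py <- co$y - cl$centre[2]
      pz <- co$z - cl$centre[3]
      qu <- px * R[1, 1] + py * R[2, 1] + pz * R[3, 1]
      qv <- px * R[1, 2] + py * R[2, 2] + pz * R[3, 2]
      qw <- px * R[1, 3] + py * R[2, 3] + pz * R[3, 3]
      cell_in <- (qu / a)^2 + (qv / b)^2 + (qw / cc)^2 <= 1
      nuc_in <- (qu / (nuc_scale * a))^2 + (qv / (nuc_scale * b))^2 +
        (qw / (nuc_scale * cc))^2 <= 1
      sub <- labels[rx, ry, rz, drop = FALSE]
      sub[cell_in & sub == 0L] <- cell_id
      sub[nuc_in & sub == cell_id] <- nuc_id
      labels[rx, ry, rz] <- sub

      # mitochondria: spheres painted only over this cell's cytoplasm voxels
      n_mito <- if (config$mito_per_cell[2] > 0) {
        if (config$mito_per_cell[1] == config$mito_per_cell[2]) {
          config$mito_per_cell[1]
        } else {
          sample(config$mito_per_cell[1]:config$mito_per_cell[2], 1)
        }
      } else 0L
      for (k in seq_len(n_mito)) {
        rho <- stats::runif(1, nuc_scale + 0.03, 0.92)
        dirn <- random_unit_vector()
        mc <- cl$centre + as.vector(R %*% (rho * dirn * c(a, b, cc)))
        mr <- stats::runif(1, config$mito_radius_um[1], config$mito_radius_um[2])
        mrx <- index_range(mc[1] - mr, mc[1] + mr, sp_um[1], dims[1])
        mry <- index_range(mc[2] - mr, mc[2] + mr, sp_um[2], dims[2])
        mrz <- index_range(mc[3] - mr, mc[3] + mr, sp_um[3], dims[3])
        if (!length(mrx) || !length(mry) || !length(mrz)) next
        mco <- box_coords(mrx, mry, mrz, sp_um)
        sph <- (mco$x - mc[1])^2 + (mco$y - mc[2])^2 + (mco$z - mc[3])^2 <=
          mr^2
        msub <- labels[mrx, mry, mrz, drop = FALSE]
        sel <- sph & msub == cell_id
        if (!any(sel)) next
        mid <- next_id
        next_id <- next_id + 1L
        msub[sel] <- mid
        labels[mrx, mry, mrz] <- msub
        mito_ids <- c(mito_ids, mid)
      }
    }

    segs <- rbind(segs, data.frame(
      label_id = c(cell_id, nuc_id, mito_ids),
      class = c("cell", "nucleus", rep("mitochondrion", length(mito_ids))),
      parent_id = c(NA_integer_, cell_id, rep(cell_id, length(mito_ids))),
      notes = "", stringsAsFactors = FALSE))

    truth[[i]] <- data.frame(
      cell_label = cell_id, nucleus_label = nuc_id,
      centre_x_um = cl$centre[1], centre_y_um = cl$centre[2],
      centre_z_um = cl$centre[3],
      semi_a_um = a, semi_b_um = b, semi_c_um = cc,
      axis_x = u[1], axis_y = u[2], axis_z = u[3],
      polarized = cl$aimed && model$type == "hotspot",
      dist_capillary_um = cl$dist_cap,
      stringsAsFactors = FALSE)
  }
  truth <- if (config$n_cells > 0) do.call(rbind, truth) else
    data.frame(cell_label = integer(), nucleus_label = integer(),
               centre_x_um = numeric(), centre_y_um = numeric(),
               centre_z_um = numeric(), semi_a_um = numeric(),
               semi_b_um = numeric(), semi_c_um = numeric(),
               axis_x = numeric(), axis_y = numeric(), axis_z = numeric(),
               polarized = logical(), dist_capillary_um = numeric())

  vol <- label_volume(labels, config$spacing)

  # completeness from the voxelized masks: no voxel on any of the 6 faces.
  # Only face voxels can violate it, so collect the label set on the faces.
  face_ids <- unique(c(labels[1, , ], labels[dims[1], , ],
                       labels[, 1, ], labels[, dims[2], ],
                       labels[, , 1], labels[, , dims[3]]))
  if (nrow(truth)) {
    truth$cell_complete <- FALSE
    truth$nucleus_complete <- FALSE
    for (i in seq_len(nrow(truth))) {
      fam <- c(truth$cell_label[i], truth$nucleus_label[i],
               segs$label_id[!is.na(segs$parent_id) &
                               segs$parent_id == truth$cell_label[i]])
      truth$cell_complete[i] <- !any(fam %in% face_ids)
      truth$nucleus_complete[i] <- !(truth$nucleus_label[i] %in% face_ids)
    }
  } else {
    truth$cell_complete <- logical(0)
    truth$nucleus_complete <- logical(0)
  }

  structure(list(
    labels = vol,
    segments = segment_table(segs),
    truth = truth,
    model = list(
      type = model$type,
      plane_normal = if (model$type == "plane_aligned") model$normal else NULL,
      sigma_deg = if (model$type != "isotropic") model$sigma_deg else NULL,
      hotspot_point = hotspot_point,
      capillary = cap,
      capillary_label = cap_id,
      extent_um = ext
    ),
    config = config
  ), class = "synthetic_scene")
}

# TRUE when any TRUE voxel lies on one of the six stack faces
mask_touches_boundary <- function(mask) {
  d <- dim(mask)
  any(mask[1, , ]) || any(mask[d[1], , ]) ||
    any(mask[, 1, ]) || any(mask[, d[2], ]) ||
    any(mask[, , 1]) || any(mask[, , d[3]])
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic scene: %d cells, %d labelled structures, model '%s'\n",
              nrow(x$truth), nrow(x$segments), x$model$type))
  print(x$labels)
  invisible(x)
}

#' Render an EM-like intensity stack from a synthetic scene
#'
#' Composes per-class base grey levels, blockwise texture inside labelled
#' structures (so slices carry trackable detail for optical flow), optional
#' per-slice integer translation jitter, and Gaussian noise, then clips to
#' 0..255. No attempt is made to model real EM contrast physics; the output
#' is a geometry-faithful, texture-bearing stand-in.
#'
#' @param scene a `synthetic_scene`.
#' @param noise_sd Gaussian noise sd in grey levels.
#' @param jitter_px maximum per-slice translation, integer pixels; each slice
#'   receives an offset drawn uniformly from `-jitter_px..jitter_px` per
#'   axis, recorded in the `"jitter"` attribute of the result.
#' @param seed seed for texture, jitter and noise (geometry is unaffected).
#' @return An [intensity_stack()] with attribute `"jitter"` (data.frame
#'   `iz, ox, oy` of applied offsets).
#' @export
render_em_like <- function(scene, noise_sd = 8, jitter_px = 0, seed = 1) {
  stopifnot(inherits(scene, "synthetic_scene"), noise_sd >= 0, jitter_px >= 0)
  with_seed(seed, render_em_like_impl(scene, noise_sd, jitter_px))
}

class_grey <- c(background = 40, capillary = 70, cell = 120, nucleus = 90,
                mitochondrion = 200, cytoplasm = 120, immune_cell = 110,
                red_blood_cell = 160)

render_em_like_impl <- function(scene, noise_sd, jitter_px) {
  labels <- scene$labels$labels
  dims <- dim(labels)
  segs <- scene$segments
  lut <- rep(class_grey[["background"]], max(c(0L, segs$label_id)) + 1L)
  if (nrow(segs)) lut[segs$label_id + 1L] <- class_grey[segs$class]
  img <- array(lut[labels + 1L], dim = dims)

  # blockwise texture (4 px blocks) inside labelled structures
  block <- 4L
  cd <- pmax(1L, ceiling(dims / block))
  coarse <- array(stats::rnorm(prod(cd), 0, 12), dim = cd)
  ux <- coarse[pmin(cd[1], (seq_len(dims[1]) - 1L) %/% block + 1L),
               pmin(cd[2], (seq_len(dims[2]) - 1L) %/% block + 1L),
               pmin(cd[3], (seq_len(dims[3]) - 1L) %/% block + 1L),
               drop = FALSE]
  img[labels > 0L] <- img[labels > 0L] + ux[labels > 0L]

  jit <- data.frame(iz = seq_len(dims[3]) - 1L, ox = 0L, oy = 0L)
  if (jitter_px > 0) {
    jit$ox <- sample(-jitter_px:jitter_px, dims[3], replace = TRUE)
    jit$oy <- sample(-jitter_px:jitter_px, dims[3], replace = TRUE)
    bg <- class_grey[["background"]]
    for (iz in seq_len(dims[3])) {
      ox <- jit$ox[iz]; oy <- jit$oy[iz]
      if (ox == 0 && oy == 0) next
      sl <- matrix(bg, dims[1], dims[2])
      sx <- seq_len(dims[1]) - ox
      sy <- seq_len(dims[2]) - oy
      vx <- sx >= 1 & sx <= dims[1]
      vy <- sy >= 1 & sy <= dims[2]
      sl[vx, vy] <- img[sx[vx], sy[vy], iz]
      img[, , iz] <- sl
    }
  }

  if (noise_sd > 0) {
    img <- img + array(stats::rnorm(prod(dims), 0, noise_sd), dim = dims)
  }
  img <- round_half_up(pmin(pmax(img, 0), 255))
  out <- intensity_stack(img, scene$labels$spacing)
  attr(out, "jitter") <- jit
  out
}

#' Keep labels only on every k-th slice
#'
#' Emulates the sparse manual annotation protocol (labels drawn on 1 slice
#' out of `stride`, default 10): slices with 0-based index divisible by
#' `stride` keep their labels, all others are cleared to background.
#'
#' @param labels a [label_volume()].
#' @param stride annotation stride (>= 2).
#' @return A [label_volume()] with the sparse annotation.
#' @export
sparse_annotation <- function(labels, stride = 10L) {
  stopifnot(inherits(labels, "label_volume"))
  if (stride < 2) stop("stride must be at least 2")
  out <- labels$labels
  iz0 <- seq_len(dim(out)[3]) - 1L
  out[, , iz0 %% stride != 0L] <- 0L
  label_volume(out, labels$spacing)
}
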