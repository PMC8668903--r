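## Capillary-distance analysis and rank statistics.

#' Anisotropic Euclidean distance map to a capillary mask
#'
#' Exact Euclidean distance between voxel centres, honouring the anisotropic
#' spacing (separable lower-envelope transform along each axis). Distances
#' are in micrometres; capillary voxels are at 0.
#'
#' @param capillary_mask logical 3D array, nonempty.
#' @param spacing a [voxel_spacing()].
#' @return A `distance_map`: list with `values` (3D array, um) and
#'   `spacing`.
#' @export
capillary_distance_map <- function(capillary_mask, spacing) {
  check_array3d(capillary_mask, "capillary_mask")
  if (!any(capillary_mask)) stop("empty capillary mask")
  d <- edt3d_cpp(as.vector(capillary_mask), dim(capillary_mask),
                 unclass(spacing) * 1e-3)
  structure(list(values = array(d, dim = dim(capillary_mask)),
                 spacing = spacing),
            class = "distance_map")
}

#' Distance of a structure to the capillary
#'
#' Primary measure: minimum of the distance map over the structure's voxels
#' (surface-to-surface proximity). The distance evaluated at the voxel
#' containing the structure's centroid is reported alongside as a
#' sensitivity check. A structure overlapping the capillary support gives 0
#' with a warning (valid scenes keep them disjoint).
#'
#' @param mask logical 3D array, nonempty.
#' @param dmap a [capillary_distance_map()] on the same grid.
#' @return list `(min_um, centroid_um)`.
#' @export
structure_distance <- function(mask, dmap) {
  stopifnot(inherits(dmap, "distance_map"))
  if (!any(mask)) stop("empty structure mask")
  if (!all(dim(mask) == dim(dmap$values))) stop("grid mismatch")
  dmin <- min(dmap$values[mask])
  if (dmin == 0) warning("structure overlaps the capillary support")
  idx <- which(mask, arr.ind = TRUE)
  cen <- voxel_centres_um(dim(mask), dmap$spacing)
  ctr <- c(mean(cen$x[idx[, 1]]), mean(cen$y[idx[, 2]]), mean(cen$z[idx[, 3]]))
  sp_um <- unclass(dmap$spacing) * 1e-3
  ci <- pmin(pmax(round(ctr / sp_um + 0.5), 1), dim(mask))
  list(min_um = dmin, centroid_um = dmap$values[ci[1], ci[2], ci[3]])
}

# all permutations of 1..n as an n!-row matrix (n <= 9)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- vector("list", n)
  items <- seq_len(n)
  for (i in items) {
    rest <- items[-i]
    out[[i]] <- cbind(rep.int(i, nrow(sub)),
                      matrix(rest[sub], nrow(sub), n - 1))
  }
  do.call(rbind, out)
}

#' Spearman rank correlation with the published significance rule
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties). The
#' two-sided p-value uses the exact permutation distribution of rho for
#' n <= 9 (all n! orderings; `P(|rho_perm| >= |rho_obs|)`) and the
#' t-approximation `t = rho sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of
#' freedom otherwise. Significance is declared at p < 0.05, with no
#' multiple-testing correction, as in the original analysis.
#'
#' @param x,y numeric vectors of equal length, n >= 3, neither constant.
#' @param names optional pair of variable names carried into the result.
#' @return A `correlation_result` data.frame row: `var_x`, `var_y`, `n`,
#'   `rho`, `p_value`, `significant`.
#' @export
spearman_test <- function(x, y, names = c("x", "y")) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("undefined correlation: constant input")
  }
  rx <- rank(x)  # mid-ranks for ties
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- all_permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rho_perm <- as.vector(matrix(ryc[perms], nrow(perms)) %*% rxc) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
  }
  out <- data.frame(var_x = names[1], var_y = names[2], n = n,
                    rho = rho, p_value = p, significant = p < 0.05)
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' Assemble the per-cell report and correlation summary
#'
#' Joins morphometry, composition, orientation, polarity and capillary
#' distance into one row per complete cell, and computes the published
#' correlation panel: all six volume-volume pairs among cell, cytoplasm,
#' nucleus and mitochondrial network, plus capillary distance against each
#' of cell, cytoplasm, nucleus, mitochondria and the nucleocytoplasmic
#' ratio.
#'
#' @param composition data.frame from [derive_composition()] rows (one per
#'   cell, with `cell_id`).
#' @param measurements measurement table from [measure_all()] (used for
#'   centroids and flags).
#' @param inclinations optional named numeric vector of inclination angles
#'   (names = cell ids).
#' @param polarized_ids optional integer vector of polarized cell ids.
#' @param distances optional data.frame `cell_id, distance_to_capillary_um,
#'   centroid_distance_um`.
#' @return list with `cells` (the joined per-cell table) and `correlations`
#'   (stacked [spearman_test()] rows; distance correlations only when
#'   distances are supplied).
#' @export
build_report <- function(composition, measurements, inclinations = NULL,
                         polarized_ids = NULL, distances = NULL) {
  cells <- composition
  mcells <- measurements[measurements$class == "cell", , drop = FALSE]
  m <- match(cells$cell_id, mcells$label_id)
  cells$centroid_x_um <- mcells$centroid_x_um[m]
  cells$centroid_y_um <- mcells$centroid_y_um[m]
  cells$centroid_z_um <- mcells$centroid_z_um[m]
  cells$complete <- mcells$complete[m]
  cells$complete_nucleus <- mcells$complete_nucleus[m]
  cells$inclination_deg <- if (!is.null(inclinations)) {
    as.numeric(inclinations[as.character(cells$cell_id)])
  } else NA_real_
  cells$polarized <- if (!is.null(polarized_ids)) {
    cells$cell_id %in% polarized_ids
  } else NA
  if (!is.null(distances)) {
    dm <- match(cells$cell_id, distances$cell_id)
    cells$distance_to_capillary_um <- distances$distance_to_capillary_um[dm]
    cells$centroid_distance_um <- distances$centroid_distance_um[dm]
  } else {
    cells$distance_to_capillary_um <- NA_real_
    cells$centroid_distance_um <- NA_real_
  }

  vols <- c(cell = "cell_volume_um3", cytoplasm = "cytoplasm_volume_um3",
            nucleus = "nucleus_volume_um3", mito = "mito_total_volume_um3")
  cors <- list()
  cmb <- utils::combn(names(vols), 2)
  for (k in seq_len(ncol(cmb))) {
    a <- cmb[1, k]; b <- cmb[2, k]
    cors[[length(cors) + 1]] <-
      spearman_test(cells[[vols[a]]], cells[[vols[b]]],
                    names = c(paste0(a, "_volume"), paste0(b, "_volume")))
  }
  if (!is.null(distances)) {
    dvars <- c(vols, nc_ratio = "nucleocytoplasmic_ratio")
    for (a in names(dvars)) {
      cors[[length(cors) + 1]] <-
        spearman_test(cells$distance_to_capillary_um, cells[[dvars[a]]],
                      names = c("distance_to_capillary", a))
    }
  }
  list(cells = cells, correlations = do.call(rbind, cors))
}

#' End-to-end analysis of a segmented volume
#'
#' Runs the full downstream pipeline on a label volume and segment table:
#' morphometry and completeness, per-cell composition, principal axes and
#' the alignment plane (fit on cells with a complete nucleus; nucleus and
#' capillary axes are scored against the plane but never enter the fit),
#' virtual-ray polarity, capillary distances and the correlation report.
#'
#' @param volume a [label_volume()].
#' @param segments a [segment_table()].
#' @param ray a [ray_params()] (polarity is skipped when fewer than 3
#'   usable axes exist).
#' @param complete_mode completeness filter handed to [select_complete()]
#'   for the volumetric/distance report (the plane fit always uses the
#'   complete-nucleus criterion).
#' @return list: `measurements`, `cells` (per-cell report),
#'   `correlations`, `plane`, `axes`, `nucleus_inclinations`,
#'   `capillary_inclination_deg`, `polarity`, `histogram`.
#' @export
analyze_scene <- function(volume, segments, ray = ray_params(),
                          complete_mode = "cell_and_nucleus") {
  measurements <- measure_all(volume, segments)
  dims <- volume$dims
  spacing <- volume$spacing

  # orientation: cells with a complete nucleus
  orient_cells <- select_complete(measurements, segments,
                                  mode = "complete_nucleus")
  axes <- lapply(orient_cells$label_id, function(id) {
    principal_axis(structure_mask(volume, id, segments, TRUE), spacing, id)
  })
  plane <- NULL
  hist <- NULL
  nuc_inc <- NULL
  cap_inc <- NA_real_
  if (length(axes) >= 3) {
    plane <- fit_alignment_plane(axes)
    names(plane$inclination_deg) <- as.character(orient_cells$label_id)
    hist <- angle_histogram(plane$inclination_deg)
    nuc_ids <- segments$label_id[segments$class == "nucleus" &
                                   segments$parent_id %in% orient_cells$label_id]
    nuc_inc <- vapply(nuc_ids, function(id) {
      inclination_angle(principal_axis(structure_mask(volume, id), spacing, id),
                        plane)
    }, numeric(1))
    names(nuc_inc) <- as.character(nuc_ids)
    cap_ids <- segments$label_id[segments$class == "capillary"]
    if (length(cap_ids)) {
      cap_mask <- array(volume$labels %in% cap_ids, dim = dims)
      cap_inc <- inclination_angle(principal_axis(cap_mask, spacing), plane)
    }
  }

  polarity <- NULL
  if (length(axes) >= 3) {
    polarity <- run_polarity(axes, ray, dims, spacing)
  }

  # distances to the capillary for the reported cells
  report_cells <- select_complete(measurements, segments, mode = complete_mode)
  distances <- NULL
  cap_ids <- segments$label_id[segments$class == "capillary"]
  if (length(cap_ids) && nrow(report_cells)) {
    cap_mask <- array(volume$labels %in% cap_ids, dim = dims)
    dmap <- capillary_distance_map(cap_mask, spacing)
    dist_rows <- lapply(report_cells$label_id, function(id) {
      sd_ <- structure_distance(structure_mask(volume, id, segments, TRUE),
                                dmap)
      data.frame(cell_id = id, distance_to_capillary_um = sd_$min_um,
                 centroid_distance_um = sd_$centroid_um)
    })
    distances <- do.call(rbind, dist_rows)
  }

  composition <- do.call(rbind, lapply(report_cells$label_id, function(id) {
    cell <- structure_mask(volume, id, segments, TRUE)
    nuc_id <- segments$label_id[segments$class == "nucleus" &
                                  !is.na(segments$parent_id) &
                                  segments$parent_id == id]
    nuc <- array(volume$labels %in% nuc_id, dim = dims)
    mito_id <- segments$label_id[segments$class == "mitochondrion" &
                                   !is.na(segments$parent_id) &
                                   segments$parent_id == id]
    mito <- if (length(mito_id)) {
      array(volume$labels %in% mito_id, dim = dims)
    } else NULL
    derive_composition(cell, nuc, mito, spacing, cell_id = id)
  }))

  report <- NULL
  if (!is.null(composition) && nrow(composition) >= 3) {
    report <- build_report(composition, measurements,
                           inclinations = plane$inclination_deg,
                           polarized_ids = polarity$polarized_ids,
                           distances = distances)
  }

  list(measurements = measurements,
       cells = if (!is.null(report)) report$cells else composition,
       correlations = if (!is.null(report)) report$correlations else NULL,
       plane = plane,
       axes = axes,
       nucleus_inclinations = nuc_inc,
       capillary_inclination_deg = cap_inc,
       polarity = polarity,
       histogram = hist)
}
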