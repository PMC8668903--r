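## Virtual-ray convergence (polarity) analysis.
##
## Every cell emits a virtual ray: the infinite line through its centroid
## along its main axis, in both directions, extending to the volume
## boundary. Each voxel within the ray radius of the line receives an
## intensity given by a radial falloff profile (1 on the axis, 0 at the
## radius). Summing footprints over cells gives the accumulation map; the
## largest connected suprathreshold region is the convergence hot spot, and
## a cell is polarized when its ray reaches that region.

#' Virtual-ray parameters
#'
#' @param radius_um ray radius in micrometres (default 15, the published
#'   value for acquisition-scale stacks; scale it with the scene for smaller
#'   volumes).
#' @param threshold hot-spot threshold on accumulated intensity, a.u.
#'   (default 3.5; with the default per-cell-max-1 footprint the map reads
#'   as a weighted count of converging cells, so 3.5 means "more than 3.5
#'   cells' worth" of convergence). The threshold is strict (`> threshold`).
#' @param falloff radial intensity profile: a vectorized function of the
#'   perpendicular distance d (um) with value 1 at d = 0 and 0 at
#'   d >= radius, assumed monotone non-increasing. Default linear,
#'   `1 - d / radius_um`.
#' @return A `ray_params` object.
#' @export
ray_params <- function(radius_um = 15, threshold = 3.5, falloff = NULL) {
  stopifnot(radius_um > 0, threshold > 0)
  if (is.null(falloff)) {
    force(radius_um)
    falloff <- function(d) pmax(1 - d / radius_um, 0)
  }
  structure(list(radius_um = radius_um, threshold = threshold,
                 falloff = falloff),
            class = "ray_params")
}

# grid descriptor shared by the polarity stage
ray_grid <- function(dims, spacing) {
  stopifnot(length(dims) == 3, inherits(spacing, "voxel_spacing"))
  list(dims = as.integer(dims), spacing = spacing,
       spacing_um = unclass(spacing) * 1e-3)
}

#' Footprint of one cell's virtual ray
#'
#' Intensity of the ray on every voxel of the grid: `falloff(d)` where d is
#' the perpendicular physical distance from the voxel centre to the infinite
#' line through the cell centroid along its main axis (both directions,
#' clipped only by the grid); 0 beyond the ray radius. A voxel whose centre
#' lies on the axis gets exactly 1.
#'
#' @param axis a [principal_axis()]; an ambiguous axis is refused (skip such
#'   cells with a warning upstream).
#' @param params a [ray_params()].
#' @param dims grid dims `c(nx, ny, nz)`.
#' @param spacing a [voxel_spacing()].
#' @return 3D numeric array of intensities in 0..1.
#' @export
ray_footprint <- function(axis, params, dims, spacing) {
  stopifnot(inherits(axis, "principal_axis"), inherits(params, "ray_params"))
  if (isTRUE(axis$ambiguous)) stop("ambiguous axis: no defined ray direction")
  g <- ray_grid(dims, spacing)
  d <- line_perp_distance_cpp(g$dims, g$spacing_um,
                              as.numeric(axis$centroid),
                              as.numeric(axis$direction))
  val <- params$falloff(d)
  val[d >= params$radius_um] <- 0
  array(val, dim = g$dims)
}

#' Accumulate ray footprints voxel by voxel
#'
#' Per voxel, the sum over cells of that cell's footprint value; each cell
#' contributes at most its single footprint value per voxel, so the map is
#' bounded by the number of cells.
#'
#' @param footprints list of footprint arrays on one grid (see
#'   [ray_footprint()]).
#' @return 3D numeric accumulation array.
#' @export
accumulate_rays <- function(footprints) {
  stopifnot(length(footprints) >= 1)
  dims <- dim(footprints[[1]])
  for (fp in footprints) {
    if (!all(dim(fp) == dims)) stop("footprint grid mismatch")
  }
  Reduce(`+`, footprints)
}

#' Extract the main accumulation region (hot spot)
#'
#' Strictly thresholds the accumulation map, labels 26-connected components
#' and returns the largest one (ties broken by scan order of the first
#' voxel). An all-subthreshold map yields an empty mask.
#'
#' @param map 3D accumulation array.
#' @param threshold strict threshold (voxels kept where `map > threshold`).
#' @return Logical 3D mask of the hot spot.
#' @export
extract_hotspot <- function(map, threshold = 3.5) {
  stopifnot(threshold > 0)
  supra <- map > threshold
  if (!any(supra)) return(array(FALSE, dim = dim(map)))
  lab <- label_components26_cpp(as.vector(supra), dim(map))
  sizes <- tabulate(lab[lab > 0L])
  best <- which.max(sizes)
  array(lab == best, dim = dim(map))
}

#' Classify polarized cells
#'
#' A cell is polarized when its ray footprint has any positive-intensity
#' voxel inside the hot spot (its virtual ray reaches the main accumulation
#' region). With an empty hot spot no cell is polarized.
#'
#' @param footprints named list of footprint arrays (names = cell ids).
#' @param hotspot logical mask from [extract_hotspot()].
#' @return Integer vector of polarized cell ids.
#' @export
classify_polarized <- function(footprints, hotspot) {
  if (!any(hotspot)) return(integer(0))
  hit <- vapply(footprints, function(fp) {
    if (!all(dim(fp) == dim(hotspot))) stop("footprint/hotspot grid mismatch")
    any(fp[hotspot] > 0)
  }, logical(1))
  ids <- names(footprints)
  if (is.null(ids)) ids <- as.character(seq_along(footprints))
  as.integer(ids[hit])
}

#' Run the full polarity analysis
#'
#' Computes footprints for the supplied cell axes (skipping ambiguous axes
#' with a warning), accumulates them, extracts the hot spot at the
#' configured threshold and classifies polarized cells. Restrict `axes` to
#' cells with a complete nucleus to match the published filter.
#'
#' @param axes list of [principal_axis()] objects with `label_id` set.
#' @param params a [ray_params()].
#' @param dims,spacing the analysis grid.
#' @return A `polarity_result`: list with `map` (accumulation array),
#'   `hotspot` (logical mask), `polarized_ids` (integer vector) and
#'   `hotspot_centroid_um` (or NULL when empty).
#' @export
run_polarity <- function(axes, params, dims, spacing) {
  ok <- !vapply(axes, function(a) isTRUE(a$ambiguous), logical(1))
  if (any(!ok)) {
    warning(sprintf("%d cell(s) with ambiguous axis skipped", sum(!ok)))
    axes <- axes[ok]
  }
  if (length(axes) == 0) stop("no usable axes")
  footprints <- lapply(axes, ray_footprint, params = params, dims = dims,
                       spacing = spacing)
  names(footprints) <- vapply(axes, function(a) as.character(a$label_id),
                              character(1))
  map <- accumulate_rays(footprints)
  hotspot <- extract_hotspot(map, params$threshold)
  polarized <- classify_polarized(footprints, hotspot)
  centroid <- NULL
  if (any(hotspot)) {
    idx <- which(hotspot, arr.ind = TRUE)
    cen <- voxel_centres_um(dim(hotspot), spacing)
    centroid <- c(mean(cen$x[idx[, 1]]), mean(cen$y[idx[, 2]]),
                  mean(cen$z[idx[, 3]]))
  }
  structure(list(map = map, hotspot = hotspot, polarized_ids = polarized,
                 hotspot_centroid_um = centroid),
            class = "polarity_result")
}
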