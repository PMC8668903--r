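## Main-axis extraction and alignment-plane analysis.
##
## Each structure's main axis is the leading principal component of its
## voxel-centre coordinates in physical units. Axes are unsigned directions
## (a and -a are the same axis); every formula uses |n . a|. The alignment
## plane of a bundle of axes is the plane minimizing the sum of squared
## sines of the inclination angles, solved exactly by eigen-decomposition.

# canonical sign for an unsigned direction: first nonzero component positive
canonical_sign <- function(v, tol = 1e-12) {
  nz <- which(abs(v) > tol)
  if (length(nz) && v[nz[1]] < 0) -v else v
}

#' Principal axis of a structure
#'
#' Eigen-decomposition of the covariance (population convention) of the
#' voxel-centre physical coordinates of a mask. The direction is the leading
#' eigenvector with canonical sign (first nonzero component positive). When
#' the two leading eigenvalues nearly tie, the axis is not meaningful and
#' the result is flagged `ambiguous`.
#'
#' @param mask logical 3D array (at least 4 voxels).
#' @param spacing a [voxel_spacing()].
#' @param label_id optional id carried into the result.
#' @return A `principal_axis`: list with `label_id`, `centroid` (um),
#'   `direction` (unit 3-vector), `eigenvalues` (um^2, decreasing) and
#'   `ambiguous` flag.
#' @export
principal_axis <- function(mask, spacing, label_id = NA_integer_) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 4) stop("mask must contain at least 4 voxels")
  cen <- voxel_centres_um(dim(mask), spacing)
  pts <- cbind(cen$x[idx[, 1]], cen$y[idx[, 2]], cen$z[idx[, 3]])
  mu <- colMeans(pts)
  pc <- sweep(pts, 2, mu)
  cv <- crossprod(pc) / nrow(pc)
  eg <- eigen(cv, symmetric = TRUE)
  dir <- canonical_sign(eg$vectors[, 1])
  ambiguous <- (eg$values[1] - eg$values[2]) <=
    1e-9 * max(eg$values[1], .Machine$double.eps)
  structure(list(label_id = label_id, centroid = mu,
                 direction = dir / sqrt(sum(dir^2)),
                 eigenvalues = eg$values, ambiguous = ambiguous),
            class = "principal_axis")
}

#' @export
print.principal_axis <- function(x, ...) {
  cat(sprintf("principal axis (label %s): dir (%.3f, %.3f, %.3f)%s\n",
              x$label_id, x$direction[1], x$direction[2], x$direction[3],
              if (x$ambiguous) " [ambiguous]" else ""))
  invisible(x)
}

#' Best-fit alignment plane of a bundle of axes
#'
#' Finds the unit normal minimizing the axial least-squares objective
#' `sum_i (n . a_i)^2` (equivalently the summed squared sines of the
#' inclination angles): the normal is the eigenvector of the smallest
#' eigenvalue of `M = sum_i a_i a_i^T`. When the two smallest eigenvalues
#' tie (e.g. all axes equal), the normal subspace is degenerate; the
#' canonical eigen ordering and sign rule break the tie and the result is
#' flagged.
#'
#' @param axes list of [principal_axis()] objects, or a 3-column matrix of
#'   unit axis vectors; at least 3.
#' @return An `alignment_plane`: list with `normal` (unit 3-vector,
#'   canonical sign), `objective` (value of the minimized sum),
#'   `inclination_deg` (per input axis, degrees in 0..90) and `degenerate`
#'   flag.
#' @export
fit_alignment_plane <- function(axes) {
  A <- axes_matrix(axes)
  if (nrow(A) < 3) stop("at least 3 axes are required")
  M <- crossprod(A)
  eg <- eigen(M, symmetric = TRUE)
  normal <- canonical_sign(eg$vectors[, 3])
  normal <- normal / sqrt(sum(normal^2))
  degenerate <- (eg$values[2] - eg$values[3]) <=
    1e-9 * max(eg$values[1], .Machine$double.eps)
  obj <- sum((A %*% normal)^2)
  plane <- structure(list(normal = normal, objective = obj,
                          degenerate = degenerate),
                     class = "alignment_plane")
  plane$inclination_deg <- apply(A, 1, inclination_angle, plane = plane)
  plane
}

axes_matrix <- function(axes) {
  if (is.matrix(axes)) {
    stopifnot(ncol(axes) == 3)
    return(axes)
  }
  do.call(rbind, lapply(axes, function(a) {
    if (inherits(a, "principal_axis")) a$direction else as.numeric(a)
  }))
}

#' @export
print.alignment_plane <- function(x, ...) {
  cat(sprintf("alignment plane: normal (%.3f, %.3f, %.3f), objective %.4g%s\n",
              x$normal[1], x$normal[2], x$normal[3], x$objective,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Inclination angle of an axis to a plane
#'
#' `asin(|normal . axis|)` in degrees, in 0..90: 0 for an axis lying in the
#' plane, 90 for an axis along the normal.
#'
#' @param axis unit 3-vector (or [principal_axis()]).
#' @param plane an [fit_alignment_plane()] result, or a unit normal vector.
#' @return Angle in degrees.
#' @export
inclination_angle <- function(axis, plane) {
  if (inherits(axis, "principal_axis")) axis <- axis$direction
  n <- if (inherits(plane, "alignment_plane")) plane$normal else plane
  s <- abs(sum(n * axis))
  asin(min(max(s, 0), 1)) * 180 / pi
}

#' Histogram of inclination angles
#'
#' Nine 10-degree bins over 0..90 (the last bin closed at 90) plus the share
#' of angles at or below 20 degrees. The share uses an inclusive cutoff
#' ("0 to 20 degrees"); an angle of exactly 20 therefore counts in the share
#' but falls in the 20-30 bin.
#'
#' @param angles numeric vector of angles in degrees, all in 0..90,
#'   nonempty.
#' @return An `angle_histogram`: list with `breaks` (0, 10, ..., 90),
#'   `counts` (length 9, summing to `n`), `n` and `share_0_20`.
#' @export
angle_histogram <- function(angles) {
  if (length(angles) == 0) stop("no angles: share undefined")
  if (any(!is.finite(angles)) || any(angles < 0 | angles > 90)) {
    stop("angles must lie in [0, 90]")
  }
  breaks <- seq(0, 90, by = 10)
  bin <- pmin(floor(angles / 10) + 1L, 9L)  # 90 falls in the last bin
  counts <- tabulate(bin, nbins = 9L)
  structure(list(breaks = breaks, counts = counts, n = length(angles),
                 share_0_20 = mean(angles <= 20)),
            class = "angle_histogram")
}

#' @export
print.angle_histogram <- function(x, ...) {
  cat("inclination histogram (10 deg bins 0..90):\n")
  cat(" ", paste(x$counts, collapse = " "), "\n")
  cat(sprintf("  n = %d, share 0-20 deg = %.3f\n", x$n, x$share_0_20))
  invisible(x)
}
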