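## Semi-automatic segmentation by optical-flow label propagation.
##
## Manual segmentation of every serial section is prohibitively slow, so
## labels drawn on every k-th slice are carried through the stack: dense 2D
## displacement fields between neighbouring EM slices are estimated with a
## coarse-to-fine variational (Horn-Schunck type) solver and sparse labels
## are warped slice by slice from their nearest annotated section.

#' Optical-flow parameters
#'
#' @param smoothness_weight regularization weight of the quadratic
#'   smoothness term relative to the data term, on 0..255 grey values
#'   (default 15).
#' @param pyramid_levels coarse-to-fine pyramid depth (levels are capped so
#'   the coarsest image stays at least 8 px on a side).
#' @param warp_iterations relinearization (warping) steps per level.
#' @param stride annotation stride used by [propagate_stack()] (default 10:
#'   labels drawn on 1 slice out of 10).
#' @param solver_iterations Jacobi iterations of the linearized system per
#'   warp step.
#' @return A `flow_params` object.
#' @export
flow_params <- function(smoothness_weight = 15, pyramid_levels = 3,
                        warp_iterations = 5, stride = 10,
                        solver_iterations = 100) {
  stopifnot(smoothness_weight > 0, pyramid_levels >= 1,
            warp_iterations >= 1, stride >= 1, solver_iterations >= 1)
  structure(list(smoothness_weight = smoothness_weight,
                 pyramid_levels = as.integer(pyramid_levels),
                 warp_iterations = as.integer(warp_iterations),
                 stride = as.integer(stride),
                 solver_iterations = as.integer(solver_iterations)),
            class = "flow_params")
}

# 2x2 block-mean downsampling (odd trailing row/col replicated first)
downsample2 <- function(m) {
  n <- dim(m)
  if (n[1] %% 2 == 1) m <- rbind(m, m[n[1], , drop = FALSE])
  if (n[2] %% 2 == 1) m <- cbind(m, m[, ncol(m), drop = FALSE])
  n <- dim(m)
  io <- seq(1, n[1], by = 2)
  jo <- seq(1, n[2], by = 2)
  (m[io, jo] + m[io + 1, jo] + m[io, jo + 1] + m[io + 1, jo + 1]) / 4
}

# nearest upsampling of a flow component to target dims, values doubled
upsample_flow <- function(m, target_dims) {
  big <- m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2)]
  2 * big[seq_len(target_dims[1]), seq_len(target_dims[2]), drop = FALSE]
}

# central-difference gradients with replicated borders
grad_x <- function(m) {
  n <- nrow(m)
  (m[c(2:n, n), ] - m[c(1, 1:(n - 1)), ]) / 2
}
grad_y <- function(m) {
  n <- ncol(m)
  (m[, c(2:n, n)] - m[, c(1, 1:(n - 1))]) / 2
}

# 4-neighbour average with replicated borders
avg4 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  (m[c(1, 1:(n - 1)), ] + m[c(2:n, n), ] +
     m[, c(1, 1:(p - 1))] + m[, c(2:p, p)]) / 4
}

# bilinear sampling of matrix m at real coordinates (xs, ys), clamped to the
# image domain (replicate boundary)
bilinear_sample <- function(m, xs, ys) {
  n <- nrow(m); p <- ncol(m)
  xs <- pmin(pmax(xs, 1), n)
  ys <- pmin(pmax(ys, 1), p)
  x0 <- pmin(floor(xs), n - 1)
  y0 <- pmin(floor(ys), p - 1)
  fx <- xs - x0
  fy <- ys - y0
  i00 <- cbind(as.vector(x0), as.vector(y0))
  v00 <- m[i00]
  v10 <- m[i00 + rep(c(1L, 0L), each = nrow(i00))]
  v01 <- m[i00 + rep(c(0L, 1L), each = nrow(i00))]
  v11 <- m[i00 + 1L]
  out <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
  matrix(out, n, p)
}

# one pyramid level of the incremental Horn-Schunck solver.
# Convention: out(p) = source(p - u(p)) approximates target(p), i.e. u is the
# displacement of content from source to target.
hs_level <- function(src, tgt, u, v, params) {
  n <- nrow(src); p <- ncol(src)
  X <- matrix(seq_len(n), n, p)
  Y <- matrix(seq_len(p), n, p, byrow = TRUE)
  alpha2 <- params$smoothness_weight^2
  for (w in seq_len(params$warp_iterations)) {
    sw <- bilinear_sample(src, X - u, Y - v)
    gx <- grad_x(sw)
    gy <- grad_y(sw)
    it <- tgt - sw
    denom <- alpha2 + gx^2 + gy^2
    du <- matrix(0, n, p)
    dv <- matrix(0, n, p)
    for (i in seq_len(params$solver_iterations)) {
      dub <- avg4(du)
      dvb <- avg4(dv)
      t <- (gx * dub + gy * dvb + it) / denom
      du <- dub - gx * t
      dv <- dvb - gy * t
    }
    u <- u + du
    v <- v + dv
  }
  list(u = u, v = v)
}

#' Estimate dense 2D optical flow between two slices
#'
#' Coarse-to-fine variational flow with a quadratic data term and quadratic
#' (Horn-Schunck) smoothness. The returned displacement `(ux, uy)` moves
#' content from `source` to `target`: `source(p - u(p))` approximates
#' `target(p)`, which is exactly the sampling rule used by [warp_labels()].
#' Deterministic for fixed inputs and parameters.
#'
#' @param source,target 2D numeric matrices of equal dims, at least 16 x 16.
#' @param params a [flow_params()].
#' @return A `flow_field`: list with per-pixel `ux`, `uy` matrices.
#' @export
estimate_flow <- function(source, target, params = flow_params()) {
  if (!all(dim(source) == dim(target))) stop("slice dims mismatch")
  if (any(dim(source) < 16)) stop("slices must be at least 16 x 16 px")
  if (stats::sd(source) == 0 || stats::sd(target) == 0) {
    warning("degenerate (constant) slice: returning zero flow")
    z <- matrix(0, nrow(source), ncol(source))
    return(structure(list(ux = z, uy = z), class = "flow_field"))
  }
  levels <- min(params$pyramid_levels,
                max(1, floor(log2(min(dim(source)) / 8)) + 1))
  pyr_s <- list(source)
  pyr_t <- list(target)
  for (l in seq_len(levels - 1)) {
    pyr_s[[l + 1]] <- downsample2(pyr_s[[l]])
    pyr_t[[l + 1]] <- downsample2(pyr_t[[l]])
  }
  u <- matrix(0, nrow(pyr_s[[levels]]), ncol(pyr_s[[levels]]))
  v <- u
  for (l in rev(seq_len(levels))) {
    if (l < levels) {
      u <- upsample_flow(u, dim(pyr_s[[l]]))
      v <- upsample_flow(v, dim(pyr_s[[l]]))
    }
    res <- hs_level(pyr_s[[l]], pyr_t[[l]], u, v, params)
    u <- res$u
    v <- res$v
  }
  structure(list(ux = u, uy = v), class = "flow_field")
}

#' Warp a 2D label slice along a flow field
#'
#' Labels are categorical, so sampling is nearest-neighbour: the output label
#' at pixel `p` is the source label at `p - u(p)`, rounded to the nearest
#' pixel; samples falling outside the slice become background (0).
#'
#' @param labels 2D integer matrix.
#' @param flow a `flow_field` from [estimate_flow()] with matching dims.
#' @return Warped 2D integer label matrix.
#' @export
warp_labels <- function(labels, flow) {
  stopifnot(inherits(flow, "flow_field"))
  if (!all(dim(labels) == dim(flow$ux))) stop("label/flow dims mismatch")
  n <- nrow(labels); p <- ncol(labels)
  X <- matrix(seq_len(n), n, p)
  Y <- matrix(seq_len(p), n, p, byrow = TRUE)
  xs <- round(X - flow$ux)
  ys <- round(Y - flow$uy)
  out <- matrix(0L, n, p)
  valid <- xs >= 1 & xs <= n & ys >= 1 & ys <= p
  out[valid] <- labels[cbind(xs[valid], ys[valid])]
  out
}

#' Propagate sparse slice annotations through a stack
#'
#' Each unannotated slice receives labels warped sequentially from its
#' nearest annotated slice (equidistant slices take the lower-index source),
#' chaining slice-to-adjacent-slice flows: EM content decorrelates over a
#' micrometre or two, so short-range flows are concatenated rather than
#' estimating long-range flow directly. Annotated slices are preserved
#' verbatim, and no new label ids can appear.
#'
#' @param sparse a [label_volume()] with annotations on some slices
#'   (annotated = any nonzero voxel) and background elsewhere; see
#'   [sparse_annotation()].
#' @param stack the [intensity_stack()] the flow is estimated on; dims must
#'   match.
#' @param params a [flow_params()].
#' @return A dense [label_volume()].
#' @export
propagate_stack <- function(sparse, stack, params = flow_params()) {
  stopifnot(inherits(sparse, "label_volume"), inherits(stack, "intensity_stack"))
  if (!all(sparse$dims == stack$dims)) stop("label/stack dims mismatch")
  nz <- sparse$dims[3]
  annotated <- which(vapply(seq_len(nz),
                            function(iz) any(sparse$labels[, , iz] != 0L),
                            logical(1)))
  if (length(annotated) == 0) stop("no annotated slices")
  out <- sparse$labels

  # nearest annotated source per slice; which.min takes the first (lower) on ties
  src_of <- vapply(seq_len(nz),
                   function(j) annotated[which.min(abs(annotated - j))],
                   integer(1))

  for (a in annotated) {
    # forward chain a -> a+1 -> ...
    cur <- sparse$labels[, , a]
    j <- a + 1L
    while (j <= nz && src_of[j] == a && !(j %in% annotated)) {
      fl <- estimate_flow(stack$values[, , j - 1L], stack$values[, , j], params)
      cur <- warp_labels(cur, fl)
      out[, , j] <- cur
      j <- j + 1L
    }
    # backward chain a -> a-1 -> ...
    cur <- sparse$labels[, , a]
    j <- a - 1L
    while (j >= 1L && src_of[j] == a && !(j %in% annotated)) {
      fl <- estimate_flow(stack$values[, , j + 1L], stack$values[, , j], params)
      cur <- warp_labels(cur, fl)
      out[, , j] <- cur
      j <- j - 1L
    }
  }
  label_volume(out, sparse$spacing)
}
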