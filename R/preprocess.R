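#' Slice-wise normalization parameters
#'
#' @param clip_sigmas z-values are clipped to `[-clip_sigmas, clip_sigmas]`
#'   before the affine map to 0..255 (default 3; bounds the output and keeps
#'   hot pixels from compressing tissue contrast).
#' @return A `normalization_params` object.
#' @export
normalization_params <- function(clip_sigmas = 3) {
  if (!is.finite(clip_sigmas) || clip_sigmas <= 0) {
    stop("clip_sigmas must be positive")
  }
  structure(list(clip_sigmas = clip_sigmas), class = "normalization_params")
}

#' Crop a stack to a rectangular field of view
#'
#' @param stack an [intensity_stack()].
#' @param roi `c(x0, x1, y0, y1)`, half-open 0-based pixel bounds (so the
#'   full extent of an `nx` by `ny` stack is `c(0, nx, 0, ny)`).
#' @return The cropped [intensity_stack()]; spacing is unchanged.
#' @export
crop_stack <- function(stack, roi) {
  stopifnot(inherits(stack, "intensity_stack"), length(roi) == 4)
  x0 <- roi[1]; x1 <- roi[2]; y0 <- roi[3]; y1 <- roi[4]
  if (x0 >= x1 || y0 >= y1) stop("empty ROI")
  if (x0 < 0 || y0 < 0 || x1 > stack$dims[1] || y1 > stack$dims[2]) {
    stop("ROI out of bounds")
  }
  vals <- stack$values[(x0 + 1):x1, (y0 + 1):y1, , drop = FALSE]
  intensity_stack(vals, stack$spacing)
}

# round half away from zero (values here are always >= 0)
round_half_up <- function(x) floor(x + 0.5)

#' Slice-wise z-score normalization to 8 bit
#'
#' Each serial section is standardized independently — SBF-SEM contrast
#' drifts slowly along z, so per-slice statistics equalize brightness and
#' contrast through the stack. Per slice, `z = (v - mean) / sd` (population
#' sd) is clipped to `±clip_sigmas` and mapped affinely to 0..255, rounding
#' to the nearest integer with ties away from zero; the slice mean therefore
#' maps to 128. A constant slice (sd 0) maps entirely to 128 with a warning.
#'
#' @param stack an [intensity_stack()].
#' @param params a [normalization_params()].
#' @return An 8-bit [intensity_stack()] (integer values 0..255).
#' @export
normalize_slices <- function(stack, params = normalization_params()) {
  stopifnot(inherits(stack, "intensity_stack"))
  cs <- params$clip_sigmas
  out <- array(0, dim = stack$dims)
  flat <- 0L
  for (iz in seq_len(stack$dims[3])) {
    v <- stack$values[, , iz]
    mu <- mean(v)
    sigma <- sqrt(mean((v - mu)^2))
    if (sigma == 0) {
      out[, , iz] <- 128
      flat <- flat + 1L
      next
    }
    z <- pmin(pmax((v - mu) / sigma, -cs), cs)
    out[, , iz] <- round_half_up((z + cs) / (2 * cs) * 255)
  }
  if (flat > 0L) {
    warning(sprintf("%d constant slice(s) mapped to 128", flat))
  }
  intensity_stack(out, stack$spacing)
}
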