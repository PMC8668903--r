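## Per-structure volumetry, completeness and compartment composition.

# logical mask of one structure; for cells optionally including organelle
# labels parented to it (the flat label volume stores the most specific
# label per voxel, so a cell's full extent is the union with its children)
structure_mask <- function(volume, label_id, segments = NULL,
                           include_children = FALSE) {
  ids <- label_id
  if (include_children && !is.null(segments)) {
    ids <- c(ids, segments$label_id[!is.na(segments$parent_id) &
                                      segments$parent_id == label_id])
  }
  m <- array(volume$labels %in% ids, dim = volume$dims)
  m
}

#' Measure one labelled structure
#'
#' Voxel count, physical volume, centroid of voxel centres and boundary
#' contact for the voxels carrying `label_id` (optionally unioned with
#' labels parented to it, which is how a cell's full extent is recovered
#' from a flat label volume where nucleus and mitochondria override the
#' cell label).
#'
#' @param volume a [label_volume()].
#' @param label_id label to measure; must be present.
#' @param segments optional [segment_table()], needed for
#'   `include_children = TRUE`.
#' @param include_children union the structure with its child labels.
#' @return A one-row data.frame: `label_id`, `voxel_count`, `volume_um3`
#'   (voxel count times dx dy dz, nm^3 converted to um^3), `centroid_*_um`
#'   and `touches_boundary` (any voxel on any of the 6 stack faces).
#' @export
measure_structure <- function(volume, label_id, segments = NULL,
                              include_children = FALSE) {
  stopifnot(inherits(volume, "label_volume"))
  mask <- structure_mask(volume, label_id, segments, include_children)
  if (!any(mask)) stop("label ", label_id, " absent from volume")
  measure_mask(mask, volume$spacing, label_id)
}

# measurement core on a logical mask
measure_mask <- function(mask, spacing, label_id = NA_integer_) {
  idx <- which(mask, arr.ind = TRUE)
  cen <- voxel_centres_um(dim(mask), spacing)
  data.frame(
    label_id = label_id,
    voxel_count = nrow(idx),
    volume_um3 = nrow(idx) * voxel_volume_um3(spacing),
    centroid_x_um = mean(cen$x[idx[, 1]]),
    centroid_y_um = mean(cen$y[idx[, 2]]),
    centroid_z_um = mean(cen$z[idx[, 3]]),
    touches_boundary = mask_touches_boundary(mask)
  )
}

#' Derive cell compartment composition
#'
#' The cytoplasm is not segmented independently: it is the cell minus its
#' nucleus (the published compartment volumes are consistent with this
#' convention: cytoplasm plus nucleus reproduces the cell volume to rounding).
#' Mitochondria live inside the cytoplasm compartment.
#'
#' @param cell,nucleus,mitochondria logical 3D masks on one grid; `nucleus`
#'   and `mitochondria` must be contained in `cell` (violations are an error
#'   reporting the offending voxel count); `mitochondria` may be NULL.
#' @param spacing a [voxel_spacing()].
#' @param cell_id optional id carried into the result.
#' @return One-row data.frame: cell/nucleus/cytoplasm/mitochondria volumes
#'   (um^3), the nucleocytoplasmic ratio (nucleus / cytoplasm) and the
#'   mitochondrial fraction (mitochondria / cell).
#' @export
derive_composition <- function(cell, nucleus, mitochondria = NULL, spacing,
                               cell_id = NA_integer_) {
  stopifnot(all(dim(cell) == dim(nucleus)))
  out_nuc <- sum(nucleus & !cell)
  if (out_nuc > 0) {
    stop(sprintf("nucleus not contained in cell: %d voxel(s) outside", out_nuc))
  }
  if (is.null(mitochondria)) mitochondria <- array(FALSE, dim = dim(cell))
  stopifnot(all(dim(cell) == dim(mitochondria)))
  out_mito <- sum(mitochondria & !cell)
  if (out_mito > 0) {
    stop(sprintf("mitochondria not contained in cell: %d voxel(s) outside",
                 out_mito))
  }
  vv <- voxel_volume_um3(spacing)
  cell_v <- sum(cell) * vv
  nuc_v <- sum(nucleus) * vv
  cyto_v <- cell_v - nuc_v
  mito_v <- sum(mitochondria & !nucleus) * vv
  data.frame(
    cell_id = cell_id,
    cell_volume_um3 = cell_v,
    nucleus_volume_um3 = nuc_v,
    cytoplasm_volume_um3 = cyto_v,
    mito_total_volume_um3 = mito_v,
    nucleocytoplasmic_ratio = if (cyto_v > 0) nuc_v / cyto_v else NA_real_,
    mito_fraction = if (cell_v > 0) mito_v / cell_v else NA_real_
  )
}

#' Measure every structure in a segmentation
#'
#' Cells are measured over their full extent (own label plus nucleus and
#' mitochondria labels parented to them); other classes over their own
#' label. Adds per-cell completeness flags: `complete` (no voxel of the
#' structure on a stack face) and, for cells, `complete_nucleus` (the cell's
#' nucleus does not touch a face).
#'
#' @param volume a [label_volume()].
#' @param segments a [segment_table()].
#' @return A measurement data.frame, one row per table entry present in the
#'   volume (absent labels are dropped with a warning).
#' @export
measure_all <- function(volume, segments) {
  validate_segmentation(volume, segments)
  present <- segments$label_id %in% label_ids(volume)
  if (any(!present)) {
    warning("segment table entries absent from volume dropped: ",
            paste(segments$label_id[!present], collapse = ", "))
  }
  segs <- segments[present, , drop = FALSE]
  rows <- lapply(seq_len(nrow(segs)), function(i) {
    r <- measure_structure(volume, segs$label_id[i], segments,
                           include_children = segs$class[i] == "cell")
    r$class <- segs$class[i]
    r$parent_id <- segs$parent_id[i]
    r
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(label_id = integer(), voxel_count = integer(),
                      volume_um3 = numeric(), centroid_x_um = numeric(),
                      centroid_y_um = numeric(), centroid_z_um = numeric(),
                      touches_boundary = logical(), class = character(),
                      parent_id = integer())
  }
  tab$complete <- !tab$touches_boundary
  tab$complete_nucleus <- NA
  is_cell <- tab$class == "cell"
  for (i in which(is_cell)) {
    nuc <- which(tab$class == "nucleus" & !is.na(tab$parent_id) &
                   tab$parent_id == tab$label_id[i])
    tab$complete_nucleus[i] <- length(nuc) > 0 && all(tab$complete[nuc])
  }
  tab
}

#' Filter cells by completeness
#'
#' Analyses of whole-cell properties must exclude structures cut by the
#' stack boundary. Two modes mirror the two published filters:
#' `"cell_and_nucleus"` keeps cells whose own mask and whose nucleus are
#' both entirely inside the stack (the "fully segmented" criterion);
#' `"complete_nucleus"` keeps every cell whose nucleus is complete,
#' regardless of cell completeness (the orientation-analysis criterion).
#' Cells without a nucleus record are excluded with a warning.
#'
#' @param table a measurement table from [measure_all()].
#' @param segments a [segment_table()].
#' @param mode `"cell_and_nucleus"` or `"complete_nucleus"`.
#' @return The filtered table (cell rows only).
#' @export
select_complete <- function(table, segments,
                            mode = c("cell_and_nucleus", "complete_nucleus")) {
  mode <- match.arg(mode)
  cells <- table[table$class == "cell", , drop = FALSE]
  has_nuc <- vapply(cells$label_id, function(id) {
    any(segments$class == "nucleus" & !is.na(segments$parent_id) &
          segments$parent_id == id)
  }, logical(1))
  if (any(!has_nuc)) {
    warning("cells without a nucleus record excluded: ",
            paste(cells$label_id[!has_nuc], collapse = ", "))
    cells <- cells[has_nuc, , drop = FALSE]
  }
  keep <- if (mode == "cell_and_nucleus") {
    cells$complete & cells$complete_nucleus
  } else {
    cells$complete_nucleus
  }
  cells[keep %in% TRUE, , drop = FALSE]
}
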