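#' Voxel spacing in nanometres
#'
#' SBF-SEM stacks are strongly anisotropic: the lateral (x, y) pixel size is
#' set by the scan (e.g. 15 nm) while the axial step equals the cutting
#' thickness (e.g. 100 nm). All physical measurements in this package are
#' derived from an explicit spacing; spacing is never read from TIFF tags,
#' whose dialects are unreliable.
#'
#' @param dx,dy,dz voxel edge lengths in nm; all strictly positive.
#' @return A `voxel_spacing` object (named numeric vector, nm).
#' @examples
#' voxel_spacing(15, 15, 100)
#' @export
voxel_spacing <- function(dx, dy, dz) {
  s <- c(dx = as.numeric(dx), dy = as.numeric(dy), dz = as.numeric(dz))
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("voxel spacing must be strictly positive and finite")
  }
  structure(s, class = "voxel_spacing")
}

#' @export
print.voxel_spacing <- function(x, ...) {
  cat(sprintf("voxel spacing: %g x %g x %g nm\n", x[["dx"]], x[["dy"]], x[["dz"]]))
  invisible(x)
}

# physical volume of one voxel in cubic micrometres (1 um^3 = 1e9 nm^3)
voxel_volume_um3 <- function(spacing) {
  unname(spacing[["dx"]] * spacing[["dy"]] * spacing[["dz"]]) * 1e-9
}

# voxel-centre coordinates along each axis, in micrometres.
# 0-based index ix maps to (ix + 0.5) * dx nm.
voxel_centres_um <- function(dims, spacing) {
  list(
    x = (seq_len(dims[1]) - 0.5) * spacing[["dx"]] * 1e-3,
    y = (seq_len(dims[2]) - 0.5) * spacing[["dy"]] * 1e-3,
    z = (seq_len(dims[3]) - 0.5) * spacing[["dz"]] * 1e-3
  )
}

check_array3d <- function(a, what) {
  if (!is.array(a) || length(dim(a)) != 3L) {
    stop(sprintf("%s must be a 3D array", what))
  }
  if (any(dim(a) < 1L)) stop(sprintf("%s has empty dimensions", what))
  invisible(a)
}

#' Intensity stack
#'
#' A 3D grid of grey values with anisotropic voxel spacing. The array is
#' indexed `[ix, iy, iz]` with x fastest; slice `iz` is one serial section.
#'
#' @param values 3D numeric array, dims `(nx, ny, nz)`.
#' @param spacing a [voxel_spacing()].
#' @return An `intensity_stack` object.
#' @export
intensity_stack <- function(values, spacing) {
  check_array3d(values, "values")
  stopifnot(inherits(spacing, "voxel_spacing"))
  structure(list(values = values, dims = dim(values), spacing = spacing),
            class = "intensity_stack")
}

#' @export
print.intensity_stack <- function(x, ...) {
  cat(sprintf("intensity stack %d x %d x %d (range %g..%g)\n",
              x$dims[1], x$dims[2], x$dims[3],
              min(x$values), max(x$values)))
  print(x$spacing)
  invisible(x)
}

#' Label volume
#'
#' A 3D grid of non-negative integer labels (0 = background) paired with
#' the voxel spacing. Labels refer to rows of a [segment_table()].
#'
#' @param labels 3D integer array, dims `(nx, ny, nz)`.
#' @param spacing a [voxel_spacing()].
#' @return A `label_volume` object.
#' @export
label_volume <- function(labels, spacing) {
  check_array3d(labels, "labels")
  stopifnot(inherits(spacing, "voxel_spacing"))
  if (!is.integer(labels)) {
    li <- as.integer(round(labels))
    if (max(abs(li - labels)) > 0) stop("labels must be integer-valued")
    dim(li) <- dim(labels)
    labels <- li
  }
  if (min(labels) < 0L) stop("labels must be non-negative")
  structure(list(labels = labels, dims = dim(labels), spacing = spacing),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  ids <- label_ids(x)
  cat(sprintf("label volume %d x %d x %d, %d labels\n",
              x$dims[1], x$dims[2], x$dims[3], length(ids)))
  print(x$spacing)
  invisible(x)
}

#' Distinct nonzero labels present in a label volume
#' @param volume a [label_volume()].
#' @return Sorted integer vector of label ids.
#' @export
label_ids <- function(volume) {
  stopifnot(inherits(volume, "label_volume"))
  ids <- sort(unique(as.vector(volume$labels)))
  ids[ids != 0L]
}

segment_classes <- c("cell", "nucleus", "mitochondrion", "cytoplasm",
                     "capillary", "immune_cell", "red_blood_cell")

#' Segment table: the tissue inventory
#'
#' One row per labelled structure: its class and, for organelles, the id of
#' the owning cell. This is the canonical companion of a [label_volume()]
#' (one flat volume plus a class table, mirroring VAST-style exports).
#'
#' @param df data.frame with columns `label_id` (unique positive integers),
#'   `class` (one of cell, nucleus, mitochondrion, cytoplasm, capillary,
#'   immune_cell, red_blood_cell), `parent_id` (integer or NA; the parent
#'   must be of class cell) and optionally `notes`.
#' @return Validated data.frame with class `segment_table`.
#' @export
segment_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("label_id", "class", "parent_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("segment table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!"notes" %in% names(df)) df$notes <- character(nrow(df))
  df$label_id <- as.integer(df$label_id)
  df$parent_id <- as.integer(df$parent_id)
  if (anyDuplicated(df$label_id)) stop("duplicate label_id in segment table")
  if (nrow(df) && any(is.na(df$label_id) | df$label_id <= 0L)) {
    stop("label_id must be positive")
  }
  bad <- setdiff(unique(df$class), segment_classes)
  if (length(bad)) stop("unknown segment class: ", paste(bad, collapse = ", "))
  withpar <- !is.na(df$parent_id)
  if (any(withpar)) {
    pcls <- df$class[match(df$parent_id[withpar], df$label_id)]
    if (any(is.na(pcls) | pcls != "cell")) {
      stop("parent_id must reference a label of class 'cell'")
    }
  }
  df <- df[, c("label_id", "class", "parent_id", "notes")]
  class(df) <- c("segment_table", "data.frame")
  df
}

#' Check a label volume / segment table pair
#'
#' Every nonzero voxel label must appear in the table; orphan labels are an
#' error (the pair is inconsistent).
#'
#' @param volume a [label_volume()].
#' @param segments a [segment_table()].
#' @return Invisibly `TRUE` on success.
#' @export
validate_segmentation <- function(volume, segments) {
  ids <- label_ids(volume)
  orphans <- setdiff(ids, segments$label_id)
  if (length(orphans)) {
    stop("labels present in volume but absent from segment table: ",
         paste(orphans, collapse = ", "))
  }
  invisible(TRUE)
}

# ---- TIFF I/O --------------------------------------------------------------

# read a multi-page TIFF into a (nx, ny, nz) array; pages are (ny, nx)
# matrices in the file, so each is transposed on the way in.
read_tiff_array <- function(path, as_is = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = as_is)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1])) {
    stop("ragged stack: TIFF pages differ in shape")
  }
  nx <- shapes[2, 1]
  ny <- shapes[1, 1]
  nz <- length(pages)
  a <- array(0, dim = c(nx, ny, nz))
  for (iz in seq_len(nz)) {
    p <- pages[[iz]]
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] != 1L) stop("unsupported sample format: multi-channel TIFF")
      p <- p[, , 1L]
    }
    a[, , iz] <- t(p)
  }
  a
}

write_tiff_array <- function(a, path, bits) {
  scale <- 2^bits - 1
  if (min(a) < 0 || max(a) > scale) {
    stop(sprintf("values outside the %d-bit range 0..%d", bits, scale))
  }
  pages <- lapply(seq_len(dim(a)[3]), function(iz) t(a[, , iz]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

#' Load an intensity stack from a multi-page TIFF
#'
#' @param path multi-page grayscale TIFF (8/16-bit integer); all pages must
#'   share one shape.
#' @param spacing a [voxel_spacing()] — spacing is explicit input, never read
#'   from TIFF tags.
#' @return An [intensity_stack()] with `nz` equal to the page count and
#'   values preserved bit-exactly.
#' @export
load_stack <- function(path, spacing) {
  intensity_stack(read_tiff_array(path, as_is = TRUE), spacing)
}

#' Save an intensity stack as a multi-page TIFF
#' @param stack an [intensity_stack()]; values must fit the target bit depth.
#' @param path output path.
#' @param bits bits per sample (8 or 16).
#' @return The path, invisibly.
#' @export
save_stack <- function(stack, path, bits = 8L) {
  stopifnot(inherits(stack, "intensity_stack"), bits %in% c(8L, 16L))
  write_tiff_array(round(stack$values), path, bits)
}

#' Save a label volume as a 16-bit multi-page TIFF
#' @param volume a [label_volume()]; ids must be < 65536.
#' @param path output path.
#' @return The path, invisibly.
#' @export
save_labels <- function(volume, path) {
  stopifnot(inherits(volume, "label_volume"))
  write_tiff_array(volume$labels, path, 16L)
}

#' Load a label volume and its segment table
#'
#' @param label_path multi-page integer TIFF of labels.
#' @param table_path CSV with columns label_id, class, parent_id, notes.
#' @param spacing a [voxel_spacing()].
#' @return `list(volume, segments)`; the pair is cross-validated (any label
#'   in the volume missing from the table is an error naming the ids).
#' @export
load_segmentation <- function(label_path, table_path, spacing) {
  vol <- label_volume(read_tiff_array(label_path, as_is = TRUE), spacing)
  segs <- read_segment_table(table_path)
  validate_segmentation(vol, segs)
  list(volume = vol, segments = segs)
}

#' Read a segment table from CSV
#' @param path CSV path.
#' @return A [segment_table()].
#' @export
read_segment_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    df <- data.frame(label_id = integer(), class = character(),
                     parent_id = integer(), notes = character())
  }
  segment_table(df)
}

#' Write a segment table to CSV
#' @param segments a [segment_table()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_segment_table <- function(segments, path) {
  utils::write.csv(as.data.frame(segments), path, row.names = FALSE)
  invisible(path)
}

# fixed column order of the per-structure measurement table
measurement_columns <- c(
  "label_id", "class", "voxel_count", "volume_um3",
  "centroid_x_um", "centroid_y_um", "centroid_z_um",
  "complete", "complete_nucleus",
  "distance_to_capillary_um", "centroid_distance_um",
  "inclination_deg", "polarized"
)

#' Save a measurement table to CSV
#'
#' Columns are written in a fixed order; floating point values are rounded
#' to 6 significant digits, so a save/load round trip is lossless at that
#' precision.
#'
#' @param table data.frame with the measurement columns (missing ones are
#'   filled with NA).
#' @param path output path.
#' @return The path, invisibly.
#' @export
save_measurements <- function(table, path) {
  table <- as.data.frame(table)
  for (cn in measurement_columns) {
    if (!cn %in% names(table)) table[[cn]] <- NA
  }
  table <- table[, measurement_columns, drop = FALSE]
  for (cn in names(table)) {
    if (is.numeric(table[[cn]]) && !is.integer(table[[cn]])) {
      table[[cn]] <- signif(table[[cn]], 6)
    }
  }
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Load a measurement table written by [save_measurements()]
#' @param path CSV path.
#' @return data.frame with the fixed measurement columns.
#' @export
load_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cn in c("complete", "complete_nucleus", "polarized")) {
    if (cn %in% names(df)) df[[cn]] <- as.logical(df[[cn]])
  }
  df
}

#' Write a JSON run manifest
#'
#' Records spacing, free-form parameters, the seed and the package version so
#' a run can be reproduced.
#'
#' @param path output path.
#' @param spacing a [voxel_spacing()].
#' @param params named list of stage parameters.
#' @param seed integer seed used for the run.
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, spacing, params = list(), seed = NA_integer_) {
  manifest <- list(
    spacing_nm = as.list(unclass(spacing)),
    params = params,
    seed = seed,
    software = paste0("sbfmorph ", as.character(utils::packageVersion("sbfmorph")))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
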