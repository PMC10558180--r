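#' Read a volume or mask from a NIfTI-1 file
#'
#' Accepts single 3D volumes with an axis-aligned voxel-to-world transform
#' (diagonal linear part with positive diagonal). Spacing and origin are taken
#' from the file's xform; integer-typed values survive the round trip
#' bit-exactly.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return A [scalar_volume()] (`read_volume`) or [binary_mask()]
#'   (`read_mask`; any nonzero voxel is treated as set).
#' @seealso [write_volume()], [write_mask()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  img <- RNifti::readNifti(path)
  dims <- dim(img)
  if (length(dims) != 3L) {
    stop(
      "unsupported input: expected a single 3D volume, file has ",
      length(dims), " dimensions (", paste(dims, collapse = "x"), ")"
    )
  }
  xf <- unclass(RNifti::xform(img))
  lin <- xf[1:3, 1:3]
  offdiag <- lin - diag(diag(lin))
  if (max(abs(offdiag)) > 1e-6 * max(abs(diag(lin)))) {
    stop(
      "unsupported input: oblique (rotated) voxel-to-world transform; ",
      "resolve the rotation with the registration step first"
    )
  }
  spacing <- diag(lin)
  origin <- xf[1:3, 4]
  if (any(spacing < 0)) {
    # RNifti reports RAS; a negative diagonal is an axis flip. Reorder the
    # lattice so spacing is positive and the origin names the first center.
    for (ax in which(spacing < 0)) {
      idx <- rev(seq_len(dims[ax]))
      img <- switch(ax,
        img[idx, , , drop = FALSE],
        img[, idx, , drop = FALSE],
        img[, , idx, drop = FALSE]
      )
      origin[ax] <- origin[ax] + (dims[ax] - 1) * spacing[ax]
      spacing[ax] <- -spacing[ax]
    }
  }
  geometry <- grid_geometry(dims, spacing, origin)
  scalar_volume(array(as.numeric(img), dim = dims), geometry)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  binary_mask(vol$values != 0, vol$geometry)
}

#' Write a volume or mask to a NIfTI-1 file
#'
#' Geometry is stored in the sform (diagonal spacing, translation = origin).
#' Masks are written as uint8 with values in `{0, 1}`.
#'
#' @param x a [scalar_volume()] or [binary_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "scalar_volume") || inherits(x, "binary_mask"))
  g <- x$geometry
  if (geom_ndim(g) != 3L) stop("NIfTI output requires a 3D geometry")
  is_mask <- inherits(x, "binary_mask")
  values <- if (is_mask) array(as.integer(x$values), g$shape) else x$values
  hdr <- list(
    pixdim = c(1, g$spacing, 1, 1, 1, 1),
    sform_code = 2L, qform_code = 0L,
    srow_x = c(g$spacing[1], 0, 0, g$origin[1]),
    srow_y = c(0, g$spacing[2], 0, g$origin[2]),
    srow_z = c(0, 0, g$spacing[3], g$origin[3])
  )
  img <- RNifti::asNifti(values, hdr, datatype = if (is_mask) "uint8" else "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
write_mask <- function(x, path) {
  stopifnot(inherits(x, "binary_mask"))
  write_volume(x, path)
}

#' Read / write tab-separated tables
#'
#' Plain TSV with a header row; the pipeline's tabular interchange format.
#' Undefined surface distances are written as the `"nd"` ("not detected")
#' literal and read back as `NA`.
#'
#' @param path file path.
#' @param table a data.frame.
#' @return `read_tsv_table`: a data.frame; `write_tsv_table`: `path` invisibly.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path,
    sep = "\t", stringsAsFactors = FALSE, check.names = FALSE,
    na.strings = c("NA", "nd")
  )
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(table, path) {
  utils::write.table(table, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, na = "nd"
  )
  invisible(path)
}
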