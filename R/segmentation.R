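# Distance (mm) from every voxel center to the nearest set voxel center,
# anisotropic spacing respected. +Inf everywhere for an empty mask.
mask_distance_mm <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  g <- mask$geometry
  d2 <- edt_squared_mm2(as.logical(mask$values), g$shape, g$spacing)
  dist <- sqrt(d2)
  dim(dist) <- g$shape
  dist
}

#' Threshold segmentation with an optional exclusion region
#'
#' A voxel is segmented iff its value is `>=` the threshold (inclusive — so a
#' noiseless channel thresholded at its generative cutoff reproduces its
#' ground truth exactly) and it does not fall in the exclusion mask. The
#' exclusion mask plays the role of the manual cleanup step that removes
#' regions clearly not tumor (hyperintense ventricles, areas outside the
#' brain).
#'
#' @param volume a [scalar_volume()].
#' @param threshold finite numeric, in the image's units.
#' @param exclusion optional [binary_mask()] on the same grid.
#' @return A [binary_mask()] on the volume's grid.
#' @export
threshold_segment <- function(volume, threshold, exclusion = NULL) {
  stopifnot(inherits(volume, "scalar_volume"))
  if (!is.numeric(threshold) || length(threshold) != 1 || !is.finite(threshold)) {
    stop("threshold must be a single finite number")
  }
  values <- volume$values >= threshold
  if (!is.null(exclusion)) {
    stopifnot(inherits(exclusion, "binary_mask"))
    check_same_geometry(volume, exclusion, "volume and exclusion mask")
    values <- values & !exclusion$values
  }
  binary_mask(values, volume$geometry)
}

#' Voxelwise union of segmentations
#'
#' Logical OR over masks on a common grid; this is how the per-modality
#' segmentations are combined (T1 + T2 into "MRI", MRI + PET into "MRI+PET").
#'
#' @param ... [binary_mask()] objects, or a single list of them.
#' @return A [binary_mask()].
#' @export
union_masks <- function(...) {
  masks <- list(...)
  if (length(masks) == 1L && !inherits(masks[[1]], "binary_mask")) masks <- masks[[1]]
  if (length(masks) == 0L) stop("union_masks needs at least one mask")
  for (m in masks) stopifnot(inherits(m, "binary_mask"))
  out <- masks[[1]]$values
  for (m in masks[-1]) {
    check_same_geometry(masks[[1]], m, "masks to union")
    out <- out | m$values
  }
  binary_mask(out, masks[[1]]$geometry)
}

#' Voxelwise intersection of segmentations
#' @inheritParams union_masks
#' @return A [binary_mask()].
#' @export
intersect_masks <- function(...) {
  masks <- list(...)
  if (length(masks) == 1L && !inherits(masks[[1]], "binary_mask")) masks <- masks[[1]]
  if (length(masks) == 0L) stop("intersect_masks needs at least one mask")
  for (m in masks) stopifnot(inherits(m, "binary_mask"))
  out <- masks[[1]]$values
  for (m in masks[-1]) {
    check_same_geometry(masks[[1]], m, "masks to intersect")
    out <- out & m$values
  }
  binary_mask(out, masks[[1]]$geometry)
}

#' Metric (millimetre) expansion of a mask
#'
#' A voxel of the output is set iff its center lies within Euclidean world
#' distance `radius_mm` of some set voxel center of the input. The expansion
#' is computed with an exact anisotropic Euclidean distance transform, not an
#' index-space structuring element, so "2 mm" means 2 mm on a 0.2 x 0.2 x 0.5
#' grid too. Always a superset of the input; monotone in radius and in mask
#' inclusion.
#'
#' @param mask a [binary_mask()].
#' @param radius_mm expansion radius, mm, `>= 0`.
#' @return A [binary_mask()].
#' @export
expand_mask <- function(mask, radius_mm) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.numeric(radius_mm) || length(radius_mm) != 1 || is.na(radius_mm) || radius_mm < 0) {
    stop("radius_mm must be a single number >= 0")
  }
  if (radius_mm == 0 || !any(mask$values)) {
    return(binary_mask(mask$values, mask$geometry))
  }
  g <- mask$geometry
  d2 <- edt_squared_mm2(as.logical(mask$values), g$shape, g$spacing)
  # tiny relative slack so exact boundary offsets (d == r) survive float error
  keep <- d2 <= radius_mm^2 * (1 + 1e-12) + 1e-12
  dim(keep) <- g$shape
  binary_mask(keep, g)
}
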