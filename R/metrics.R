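#' Voxel-wise detection sensitivity
#'
#' Fraction of ground-truth tumor voxels covered by the detection:
#' `|detection n truth| / |truth|`.
#'
#' @param detection,truth [binary_mask()] objects on the same grid; `truth`
#'   must be non-empty.
#' @return numeric in `[0, 1]`.
#' @export
sensitivity <- function(detection, truth) {
  check_same_geometry(detection, truth, "detection and truth")
  n_truth <- sum(truth$values)
  if (n_truth == 0) stop("sensitivity undefined: ground-truth mask is empty")
  sum(detection$values & truth$values) / n_truth
}

#' Voxel-wise detection specificity within the brain region
#'
#' Among brain voxels outside the true tumor, the fraction not flagged:
#' `(|brain| - |(detection u truth) n brain|) / (|brain| - |truth|)`.
#' Detection voxels outside the brain region are ignored.
#'
#' @param detection,truth,brain [binary_mask()] objects on one grid;
#'   `truth` must be a strict subset of `brain`.
#' @return numeric in `[0, 1]`.
#' @export
specificity <- function(detection, truth, brain) {
  check_same_geometry(detection, truth, "detection and truth")
  check_same_geometry(detection, brain, "detection and brain region")
  if (any(truth$values & !brain$values)) {
    stop("ground-truth tumor must be contained in the brain region")
  }
  n_brain <- sum(brain$values)
  n_truth <- sum(truth$values)
  if (n_brain <= n_truth) {
    stop("specificity undefined: brain region contains no non-tumor voxels")
  }
  flagged <- sum((detection$values | truth$values) & brain$values)
  (n_brain - flagged) / (n_brain - n_truth)
}

#' Dice similarity coefficient
#'
#' `2 |A n B| / (|A| + |B|)`; 0 for disjoint masks, 1 for identical masks.
#'
#' @param detection,truth [binary_mask()] objects on the same grid, not both
#'   empty.
#' @return numeric in `[0, 1]`.
#' @export
dice <- function(detection, truth) {
  check_same_geometry(detection, truth, "detection and truth")
  na <- sum(detection$values)
  nb <- sum(truth$values)
  if (na + nb == 0) stop("dice undefined: both masks are empty")
  2 * sum(detection$values & truth$values) / (na + nb)
}

#' Surface voxels of a mask
#'
#' Set voxels with at least one unset 6-neighbour (face adjacency); voxels on
#' the volume boundary faces count as surface.
#'
#' @param mask a [binary_mask()].
#' @return A [binary_mask()] of the surface voxels.
#' @export
surface_voxels <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  v <- mask$values
  dims <- dim(v)
  d <- length(dims)
  interior <- v
  for (ax in seq_len(d)) {
    n <- dims[ax]
    if (n == 1L) {
      interior[] <- FALSE
      break
    }
    shift_lo <- shift_axis(v, ax, 1L) # neighbour at index - 1 (FALSE at face)
    shift_hi <- shift_axis(v, ax, -1L) # neighbour at index + 1
    interior <- interior & shift_lo & shift_hi
  }
  binary_mask(v & !interior, mask$geometry)
}

# Shift an array by `by` voxels along axis `ax`, filling with FALSE/0.
shift_axis <- function(arr, ax, by) {
  dims <- dim(arr)
  n <- dims[ax]
  idx <- seq_len(n) - by
  pad <- idx < 1L | idx > n
  idx[pad] <- 1L
  args <- rep(list(quote(expr = )), length(dims))
  args[[ax]] <- idx
  out <- do.call(`[`, c(list(arr), args, list(drop = FALSE)))
  argsp <- rep(list(quote(expr = )), length(dims))
  argsp[[ax]] <- which(pad)
  if (any(pad)) out <- do.call(`[<-`, c(list(out), argsp, list(value = FALSE)))
  out
}

#' Worst-case (maximum) symmetric surface distance
#'
#' For every surface voxel of one mask, the minimum world-mm distance to the
#' other mask's surface voxels; the maximum of these minima over both
#' directions (a symmetric Hausdorff distance over surface voxel centers).
#' Returns `NA` (reported as `"nd"`) when either mask is empty — the tumor
#' was not detected at all, so no surface comparison exists.
#'
#' @param a,b [binary_mask()] objects on the same grid.
#' @return distance in mm, or `NA_real_` if either mask is empty.
#' @export
max_surface_distance <- function(a, b) {
  check_same_geometry(a, b, "masks")
  if (!any(a$values) || !any(b$values)) {
    return(NA_real_)
  }
  sa <- surface_voxels(a)
  sb <- surface_voxels(b)
  da_to_b <- mask_distance_mm(sb)[sa$values] # min dist from each a-surface voxel
  db_to_a <- mask_distance_mm(sa)[sb$values]
  max(max(da_to_b), max(db_to_a))
}

#' Score one tumor case across all modalities
#'
#' Produces one detection-result row per modality in
#' `T1, T2, T1+T2 (MRI), PET, MRI+PET, MRI+2mm`, scored against the
#' fluorescence (tdTomato) ground truth on the common fine grid. PET
#' detections arrive on the PET grid and are upsampled (nearest-neighbour) to
#' the scoring grid first. The expanded-MRI detection is the combined MRI
#' segmentation grown by `expand_radius_mm` (in mm, anisotropy respected);
#' its specificity is computed after clipping to the brain region, while the
#' reported volume is unclipped.
#'
#' A modality whose detection mask is empty scores sensitivity 0, dice 0,
#' specificity from the empty detection (= 1), and an undefined (`NA`)
#' surface distance. A metric that errors for one modality is recorded as
#' `NA` without aborting the other modalities.
#'
#' @param detections named list of [binary_mask()] with entries `t1`, `t2`,
#'   `pet` (each on the scoring grid or upsampleable to it).
#' @param truth tdTomato ground-truth [binary_mask()] on the scoring grid.
#' @param brain brain-region [binary_mask()] on the scoring grid.
#' @param case_id character label.
#' @param gd_status logical, gadolinium enhancement.
#' @param expand_radius_mm expansion radius for the expanded-MRI row.
#' @return data.frame with columns `case_id`, `modality`, `volume_mm3`,
#'   `sensitivity`, `specificity`, `dice`, `max_surface_distance_mm`,
#'   `gd_status`.
#' @export
evaluate_case <- function(detections, truth, brain, case_id = "case",
                          gd_status = NA, expand_radius_mm = 2) {
  stopifnot(inherits(truth, "binary_mask"), inherits(brain, "binary_mask"))
  needed <- c("t1", "t2", "pet")
  if (!all(needed %in% names(detections))) {
    stop("detections must contain masks named ", paste(needed, collapse = ", "))
  }
  to_grid <- function(m) {
    if (geom_equal(m$geometry, truth$geometry)) m else upsample_nearest(m, truth$geometry)
  }
  t1 <- to_grid(detections$t1)
  t2 <- to_grid(detections$t2)
  pet <- to_grid(detections$pet)
  mri <- union_masks(t1, t2)
  mri_pet <- union_masks(mri, pet)
  mri_exp <- expand_mask(mri, expand_radius_mm)
  modality_masks <- list(
    "T1" = t1, "T2" = t2, "T1+T2" = mri, "PET" = pet,
    "MRI+PET" = mri_pet, "MRI+2mm" = mri_exp
  )
  rows <- lapply(names(modality_masks), function(mod) {
    det <- modality_masks[[mod]]
    spec_det <- if (mod == "MRI+2mm") intersect_masks(det, brain) else det
    safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
    data.frame(
      case_id = case_id,
      modality = mod,
      volume_mm3 = mask_volume_mm3(det),
      sensitivity = safe(sensitivity(det, truth)),
      specificity = safe(specificity(spec_det, truth, brain)),
      dice = safe(dice(det, truth)),
      max_surface_distance_mm = safe(max_surface_distance(det, truth)),
      gd_status = gd_status,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  optical <- data.frame(
    case_id = case_id, modality = "Optical",
    volume_mm3 = mask_volume_mm3(truth),
    sensitivity = NA_real_, specificity = NA_real_, dice = NA_real_,
    max_surface_distance_mm = NA_real_, gd_status = gd_status,
    stringsAsFactors = FALSE
  )
  rbind(out, optical)
}
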