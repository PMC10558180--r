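#' Build a slice-registration problem with known ground truth
#'
#' Emulates the ex vivo workflow for testing the slice-by-slice recovery:
#' a fine-grid channel of a phantom case is resampled to 1-mm slice
#' thickness (the physical sectioning), each coronal slice is pushed through
#' a known random small 2D affine (the deformation a cleared slice suffers),
#' and landmark pairs consistent with that transform are emitted per slice.
#' Registering the perturbed slices with the landmarks should recover the
#' original stack.
#'
#' @param volume a 3D [scalar_volume()] (e.g. the phantom tdTomato channel).
#' @param slice_thickness_mm physical slice thickness (default 1 mm).
#' @param max_rotation_deg,max_shift_mm,max_log_scale ranges of the random
#'   per-slice perturbations (rotation, translation, anisotropic log-scale).
#' @param n_landmarks landmarks per slice (>= 3; non-collinear by
#'   construction).
#' @param seed integer seed.
#' @return list with `slices` (perturbed 2D [scalar_volume()]s), `landmarks`
#'   (per-slice [landmark_pairs()] mapping perturbed -> target frame),
#'   `target` (3D [grid_geometry()] of the sliced stack), `reference` (the
#'   unperturbed sliced [scalar_volume()]), and `true_transforms`.
#' @export
make_slice_registration_problem <- function(volume,
                                            slice_thickness_mm = 1,
                                            max_rotation_deg = 10,
                                            max_shift_mm = 1.5,
                                            max_log_scale = 0.05,
                                            n_landmarks = 6,
                                            seed = 1L) {
  stopifnot(inherits(volume, "scalar_volume"), geom_ndim(volume$geometry) == 3L)
  sliced <- resample_to_spacing(
    volume,
    c(volume$geometry$spacing[1:2], slice_thickness_mm)
  )
  target <- sliced$geometry
  plane <- grid_geometry(target$shape[1:2], target$spacing[1:2], target$origin[1:2])
  extent <- (plane$shape - 1) * plane$spacing
  with_seed(seed, {
    n_slices <- target$shape[3]
    slices <- vector("list", n_slices)
    landmarks <- vector("list", n_slices)
    transforms <- vector("list", n_slices)
    for (i in seq_len(n_slices)) {
      theta <- stats::runif(1, -max_rotation_deg, max_rotation_deg) * pi / 180
      scales <- exp(stats::runif(2, -max_log_scale, max_log_scale))
      rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
      linear <- rot %*% diag(scales)
      center <- plane$origin + extent / 2
      shift <- stats::runif(2, -max_shift_mm, max_shift_mm)
      # perturbation about the slice center: target -> perturbed frame
      perturb <- affine_transform(linear, center - linear %*% center + shift)
      ref_slice <- scalar_volume(sliced$values[, , i], plane)
      moved <- apply_transform(ref_slice, perturb, plane, interpolation = "nearest")
      # landmarks: points around the slice, mapped into the perturbed frame
      fixed_pts <- cbind(
        stats::runif(n_landmarks, plane$origin[1], plane$origin[1] + extent[1]),
        stats::runif(n_landmarks, plane$origin[2], plane$origin[2] + extent[2])
      )
      moving_pts <- transform_points(perturb, fixed_pts)
      slices[[i]] <- moved
      landmarks[[i]] <- landmark_pairs(moving_pts, fixed_pts)
      transforms[[i]] <- perturb
    }
    list(
      slices = slices, landmarks = landmarks, target = target,
      reference = sliced, true_transforms = transforms
    )
  })
}
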