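#' Landmark pair set
#'
#' Corresponding points (world mm) in a moving and a fixed frame, used to fit
#' an affine transform by least squares. A d-dimensional affine needs at
#' least `d + 1` pairs whose moving points span the space (i.e. are not all
#' contained in a hyperplane).
#'
#' @param moving,fixed n x d numeric matrices of corresponding points (mm).
#' @return An object of class `landmark_pairs`.
#' @export
landmark_pairs <- function(moving, fixed) {
  moving <- as.matrix(moving)
  fixed <- as.matrix(fixed)
  d <- ncol(moving)
  if (!d %in% c(2L, 3L)) stop("landmarks must be 2D or 3D")
  if (!all(dim(moving) == dim(fixed))) stop("moving and fixed must have matching dimensions")
  if (nrow(moving) < d + 1) {
    stop("need at least ", d + 1, " landmark pairs for a ", d, "D affine")
  }
  if (any(!is.finite(moving)) || any(!is.finite(fixed))) stop("landmarks must be finite")
  structure(list(moving = moving, fixed = fixed, dimension = d), class = "landmark_pairs")
}

#' Read landmark pairs from a TSV file
#'
#' Expected columns: `slice_index` (optional for 3D), `moving_x`, `moving_y`
#' (`moving_z` for 3D), `fixed_x`, `fixed_y` (`fixed_z`), all in mm. When
#' `slice_index` is present, a list of per-slice [landmark_pairs()] is
#' returned (ordered by slice index); otherwise a single set.
#'
#' @param path TSV path.
#' @return A `landmark_pairs` object or a list of them keyed by slice.
#' @export
read_landmarks <- function(path) {
  tab <- read_tsv_table(path)
  has_z <- "moving_z" %in% names(tab)
  mcols <- c("moving_x", "moving_y", if (has_z) "moving_z")
  fcols <- c("fixed_x", "fixed_y", if (has_z) "fixed_z")
  if (!all(c(mcols, fcols) %in% names(tab))) {
    stop("landmark TSV must contain columns ", paste(c(mcols, fcols), collapse = ", "))
  }
  build <- function(rows) landmark_pairs(as.matrix(rows[mcols]), as.matrix(rows[fcols]))
  if ("slice_index" %in% names(tab)) {
    idx <- sort(unique(tab$slice_index))
    out <- lapply(idx, function(i) build(tab[tab$slice_index == i, , drop = FALSE]))
    names(out) <- as.character(idx)
    out
  } else {
    build(tab)
  }
}

#' Affine transform
#'
#' `y = linear %*% x + translation`, with an invertible linear part.
#'
#' @param linear d x d matrix.
#' @param translation length-d numeric vector (mm).
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(linear, translation) {
  linear <- as.matrix(linear)
  d <- nrow(linear)
  if (ncol(linear) != d || !d %in% c(2L, 3L)) stop("linear part must be 2x2 or 3x3")
  if (length(translation) != d) stop("translation length must match")
  if (abs(det(linear)) <= 1e-12) stop("linear part is singular (|det| <= 1e-12)")
  structure(
    list(linear = linear, translation = as.numeric(translation), dimension = d),
    class = "affine_transform"
  )
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("affine_transform (", x$dimension, "D)\n", sep = "")
  print(cbind(x$linear, t = x$translation))
  invisible(x)
}

#' Apply an affine transform to points
#'
#' @param transform an [affine_transform()].
#' @param points n x d matrix of points (mm).
#' @return n x d matrix of transformed points.
#' @export
transform_points <- function(transform, points) {
  points <- rbind(points) # promote a bare vector to a 1 x d matrix
  points %*% t(transform$linear) +
    matrix(transform$translation, nrow(points), transform$dimension, byrow = TRUE)
}

#' Invert an affine transform
#' @param transform an [affine_transform()].
#' @return The inverse [affine_transform()].
#' @export
invert_transform <- function(transform) {
  inv <- solve(transform$linear)
  affine_transform(inv, -as.numeric(inv %*% transform$translation))
}

#' Least-squares affine from landmark pairs
#'
#' Finds the affine minimizing the sum of squared distances between the
#' transformed moving points and the fixed points (ordinary least squares on
#' the homogeneous design). With exactly `d + 1` non-degenerate pairs the fit
#' interpolates (zero residual). The fiducial registration error (RMS
#' residual distance, mm) is attached for reporting.
#'
#' @param landmarks a [landmark_pairs()].
#' @return An [affine_transform()] with attribute `fre_mm`.
#' @export
fit_affine_landmarks <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_pairs"))
  d <- landmarks$dimension
  X <- cbind(landmarks$moving, 1)
  qr_x <- qr(X)
  if (qr_x$rank < d + 1) {
    # name the deficient direction: null-space vector of the design
    ns <- qr.Q(qr(t(X)), complete = TRUE)[, (qr_x$rank + 1):(d + 1), drop = FALSE]
    stop(
      "degenerate landmark configuration: moving points lie in a lower-",
      "dimensional affine subspace (deficient direction ~ [",
      paste(format(round(ns[seq_len(d), 1], 4)), collapse = ", "), "])"
    )
  }
  B <- qr.coef(qr_x, landmarks$fixed) # (d+1) x d; rows = moving coords + intercept
  linear <- t(B[seq_len(d), , drop = FALSE])
  translation <- as.numeric(B[d + 1, ])
  fit <- affine_transform(linear, translation)
  res <- transform_points(fit, landmarks$moving) - landmarks$fixed
  attr(fit, "fre_mm") <- sqrt(mean(rowSums(res^2)))
  fit
}

# Sample a value array at continuous 0-based indices (n x d matrix), by
# nearest neighbour or multilinear interpolation; outside the lattice -> fill.
sample_at_indices <- function(values, idx, interpolation, fill) {
  shape <- dim(values)
  d <- length(shape)
  n <- nrow(idx)
  if (interpolation == "nearest") {
    i <- floor(idx + 0.5)
    inside <- rep(TRUE, n)
    for (ax in seq_len(d)) inside <- inside & i[, ax] >= 0 & i[, ax] <= shape[ax] - 1
    out <- rep(fill, n)
    if (any(inside)) {
      flat <- i[inside, 1]
      mult <- 1
      for (ax in seq_len(d)[-1]) {
        mult <- mult * shape[ax - 1]
        flat <- flat + i[inside, ax] * mult
      }
      out[inside] <- values[flat + 1]
    }
    out
  } else {
    i0 <- floor(idx)
    frac <- idx - i0
    out <- rep(as.numeric(fill), n)
    corners <- as.matrix(do.call(expand.grid, rep(list(0:1), d)))
    acc <- numeric(n)
    ok <- rep(TRUE, n)
    for (ax in seq_len(d)) ok <- ok & idx[, ax] >= 0 & idx[, ax] <= shape[ax] - 1
    for (ci in seq_len(nrow(corners))) {
      corner <- corners[ci, ]
      w <- rep(1, n)
      flat <- numeric(n)
      mult <- 1
      for (ax in seq_len(d)) {
        iax <- pmin(i0[, ax] + corner[ax], shape[ax] - 1)
        iax <- pmax(iax, 0)
        w <- w * if (corner[ax] == 1) frac[, ax] else 1 - frac[, ax]
        flat <- flat + iax * mult
        mult <- mult * shape[ax]
      }
      acc <- acc + w * values[flat + 1]
    }
    out[ok] <- acc[ok]
    out
  }
}

#' Resample a volume or mask through an affine transform
#'
#' Pull-back resampling: each target voxel center is mapped through the
#' *inverse* of `transform` into the moving frame and sampled there. Samples
#' falling outside the moving volume take 0 (`FALSE` for masks) — areas
#' outside the acquired field are treated as removed. Masks require
#' `interpolation = "nearest"` so they stay binary.
#'
#' @param moving a [scalar_volume()] or [binary_mask()].
#' @param transform the moving-to-fixed [affine_transform()].
#' @param target the fixed-frame [grid_geometry()].
#' @param interpolation `"nearest"` or `"linear"`.
#' @return Same kind as `moving`, on `target`.
#' @export
apply_transform <- function(moving, transform, target,
                            interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(transform, "affine_transform"), inherits(target, "grid_geometry"))
  g <- moving$geometry
  d <- geom_ndim(g)
  if (transform$dimension != d || geom_ndim(target) != d) {
    stop("transform, moving volume and target must share dimensionality")
  }
  is_mask <- inherits(moving, "binary_mask")
  if (is_mask && interpolation != "nearest") {
    stop("masks must be resampled with interpolation = \"nearest\"")
  }
  inv <- invert_transform(transform)
  pts <- voxel_centers(target)
  back <- transform_points(inv, pts)
  idx <- sweep(sweep(back, 2, g$origin, "-"), 2, g$spacing, "/")
  vals <- sample_at_indices(
    if (is_mask) (moving$values + 0) else moving$values,
    idx, interpolation,
    fill = 0
  )
  dim(vals) <- target$shape
  if (is_mask) binary_mask(vals != 0, target) else scalar_volume(vals, target)
}

#' Register a stack of 2D optical slices into a 3D frame
#'
#' Each physical slice (e.g. a 1-mm cleared tissue section) carries its own
#' landmark correspondence with the matching in-plane grid of the target
#' volume; a full 2D affine (6 dof — slices deform anisotropically during
#' clearing) is fitted per slice, the slice is resampled into the target's
#' in-plane grid, and the slices are stacked along the third axis.
#'
#' @param slices list of 2D [scalar_volume()] objects, one per target slice
#'   plane, ordered along the target third axis.
#' @param per_slice_landmarks list of 2D [landmark_pairs()], same length.
#' @param target 3D [grid_geometry()]; its third-axis extent must equal the
#'   slice count.
#' @param interpolation `"linear"` or `"nearest"` in-plane resampling.
#' @return A [scalar_volume()] on `target`.
#' @export
register_slice_stack <- function(slices, per_slice_landmarks, target,
                                 interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(target, "grid_geometry"), geom_ndim(target) == 3L)
  n_slices <- target$shape[3]
  if (length(slices) != n_slices) {
    stop(
      "slice count (", length(slices), ") must equal the target third-axis ",
      "extent (", n_slices, ")"
    )
  }
  if (length(per_slice_landmarks) != length(slices)) {
    stop("need exactly one landmark set per slice")
  }
  plane <- grid_geometry(target$shape[1:2], target$spacing[1:2], target$origin[1:2])
  out <- array(0, target$shape)
  for (i in seq_len(n_slices)) {
    fit <- fit_affine_landmarks(per_slice_landmarks[[i]])
    reg <- apply_transform(slices[[i]], fit, plane, interpolation)
    out[, , i] <- reg$values
  }
  scalar_volume(out, target)
}
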