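#' Axis-aligned voxel grid geometry
#'
#' Describes the lattice a volume or mask lives on: voxels per axis, voxel
#' spacing in millimetres, and the world position (mm) of the *center* of
#' voxel index `(0, 0, 0)`. Voxel indices are 0-based and the world
#' coordinate of voxel `(i, j, k)` is `origin + index * spacing`; no rotation
#' is representable here, so oblique acquisitions must be resolved by the
#' registration step before any metric is computed.
#'
#' @param shape integer vector (length 2 or 3), voxels per axis; all >= 1.
#' @param spacing numeric vector of the same length, mm per voxel; all > 0.
#' @param origin numeric vector of the same length, world mm of the center of
#'   the first voxel. Defaults to zeros.
#' @return An object of class `grid_geometry`.
#' @examples
#' grid_geometry(c(64, 64, 24), c(0.2, 0.2, 0.5))
#' @export
grid_geometry <- function(shape, spacing, origin = rep(0, length(shape))) {
  d <- length(shape)
  if (!d %in% c(2L, 3L)) {
    stop("grid_geometry supports 2 or 3 axes, got ", d)
  }
  if (length(spacing) != d || length(origin) != d) {
    stop("shape, spacing and origin must have equal length")
  }
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (any(!is.finite(shape)) || any(shape < 1L)) {
    stop("all shape components must be >= 1")
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("all spacing components must be > 0 mm")
  }
  if (any(!is.finite(origin))) {
    stop("origin must be finite")
  }
  structure(
    list(shape = shape, spacing = spacing, origin = origin),
    class = "grid_geometry"
  )
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(
    "grid_geometry: ", paste(x$shape, collapse = " x "),
    " voxels, spacing (", paste(format(x$spacing), collapse = ", "),
    ") mm, origin (", paste(format(x$origin), collapse = ", "), ") mm\n",
    sep = ""
  )
  invisible(x)
}

geom_ndim <- function(geometry) length(geometry$shape)

#' @rdname grid_geometry
#' @param a,b two `grid_geometry` objects.
#' @param tol absolute tolerance (mm) for spacing/origin comparison.
#' @export
geom_equal <- function(a, b, tol = 1e-8) {
  length(a$shape) == length(b$shape) &&
    all(a$shape == b$shape) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

# World coordinates (mm) of voxel centers along one axis.
axis_coords <- function(geometry, axis) {
  geometry$origin[axis] + (seq_len(geometry$shape[axis]) - 1) * geometry$spacing[axis]
}

# n x d matrix of world coordinates for every voxel center, in array order
# (first axis fastest), matching as.vector() of the value array.
voxel_centers <- function(geometry) {
  coords <- lapply(seq_along(geometry$shape), function(ax) axis_coords(geometry, ax))
  as.matrix(do.call(expand.grid, coords))
}

#' Scalar image volume
#'
#' A lattice of finite real values (MR signal, PET activity concentration,
#' fluorescence radiant efficiency, ...) on a [grid_geometry()].
#'
#' @param values numeric array whose dim equals `geometry$shape`.
#' @param geometry a [grid_geometry()].
#' @return An object of class `scalar_volume` with fields `values`, `geometry`.
#' @export
scalar_volume <- function(values, geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  values <- as_array_dim(values, geometry$shape)
  if (!is.numeric(values)) stop("scalar_volume values must be numeric")
  if (any(!is.finite(values))) stop("scalar_volume values must all be finite")
  structure(list(values = values, geometry = geometry), class = "scalar_volume")
}

#' Binary segmentation mask
#'
#' A logical lattice on a [grid_geometry()] (tumor truth, detections, brain
#' region, exclusion regions).
#'
#' @param values logical (or 0/1 numeric) array whose dim equals
#'   `geometry$shape`.
#' @param geometry a [grid_geometry()].
#' @return An object of class `binary_mask` with fields `values`, `geometry`.
#' @export
binary_mask <- function(values, geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  values <- as_array_dim(values, geometry$shape)
  if (is.numeric(values)) {
    if (any(!values %in% c(0, 1))) stop("numeric mask values must be 0/1")
    storage.mode(values) <- "logical"
  }
  if (!is.logical(values)) stop("binary_mask values must be logical or 0/1")
  if (any(is.na(values))) stop("binary_mask values must not contain NA")
  structure(list(values = values, geometry = geometry), class = "binary_mask")
}

as_array_dim <- function(values, shape) {
  if (is.null(dim(values))) {
    if (length(values) != prod(shape)) stop("values length does not match geometry shape")
    dim(values) <- shape
  }
  if (length(dim(values)) != length(shape) || any(dim(values) != shape)) {
    stop(
      "values shape (", paste(dim(values), collapse = "x"),
      ") does not match geometry shape (", paste(shape, collapse = "x"), ")"
    )
  }
  values
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat("scalar_volume\n")
  print(x$geometry)
  cat("  value range [", format(min(x$values)), ", ", format(max(x$values)), "]\n", sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("binary_mask\n")
  print(x$geometry)
  cat("  ", sum(x$values), " of ", length(x$values), " voxels set (",
    format(mask_volume_mm3(x)), " mm^3)\n",
    sep = ""
  )
  invisible(x)
}

check_same_geometry <- function(a, b, what = "inputs") {
  if (!geom_equal(a$geometry, b$geometry)) {
    stop(what, " must share an identical grid geometry")
  }
  invisible(TRUE)
}

#' Mask volume in cubic millimetres
#'
#' Number of set voxels times the voxel volume (product of the spacings).
#'
#' @param mask a [binary_mask()].
#' @return volume in mm^3 (mm^2 area for 2D masks).
#' @examples
#' g <- grid_geometry(c(10, 10, 10), c(0.2, 0.2, 0.5))
#' m <- binary_mask(array(FALSE, g$shape), g)
#' mask_volume_mm3(m) # 0
#' @export
mask_volume_mm3 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$values) * prod(mask$geometry$spacing)
}

# Run code with a deterministic, locally-scoped RNG state. Restores (or
# removes) .Random.seed afterwards so callers' randomness is untouched.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
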