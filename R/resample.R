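#' Nearest-neighbour upsampling onto a finer grid
#'
#' Each target voxel takes the value of the input voxel whose *center* is
#' nearest in world millimetres. Masks stay binary, which keeps voxel-count
#' metrics (sensitivity/specificity) well defined; intensities are never
#' interpolated here. The target must be at least as fine as the input on
#' every axis and cover (within one input voxel) the same world extent.
#'
#' @param input a [scalar_volume()] or [binary_mask()].
#' @param target a [grid_geometry()] with per-axis spacing <= the input's.
#' @return The same kind of object as `input`, on `target`.
#' @export
upsample_nearest <- function(input, target) {
  stopifnot(inherits(target, "grid_geometry"))
  g <- input$geometry
  d <- geom_ndim(g)
  if (geom_ndim(target) != d) stop("target dimensionality must match input")
  if (any(target$spacing > g$spacing + 1e-9)) {
    bad <- which(target$spacing > g$spacing + 1e-9)
    stop(
      "target grid is coarser than the input on axis ",
      paste(bad, collapse = ", "), "; upsample_nearest requires spacing <= input"
    )
  }
  # world extent check: target centers must fall within one input voxel of
  # the input's covered extent
  lo <- g$origin - g$spacing
  hi <- g$origin + (g$shape - 1) * g$spacing + g$spacing
  t_lo <- target$origin
  t_hi <- target$origin + (target$shape - 1) * target$spacing
  if (any(t_lo < lo - 1e-9) || any(t_hi > hi + 1e-9)) {
    stop("target grid extends more than one input voxel beyond the input extent")
  }
  idx <- lapply(seq_len(d), function(ax) {
    centers <- axis_coords(target, ax)
    i <- floor((centers - g$origin[ax]) / g$spacing[ax] + 0.5)
    pmin(pmax(i, 0), g$shape[ax] - 1) + 1L
  })
  values <- do.call(`[`, c(list(input$values), idx, list(drop = FALSE)))
  dim(values) <- target$shape
  if (inherits(input, "binary_mask")) binary_mask(values, target) else scalar_volume(values, target)
}

# Mean-reduce axis 1 of an array in blocks of `f` voxels; trailing partial
# blocks average only the voxels present.
reduce_axis1_mean <- function(arr, f) {
  dims <- dim(arr)
  n <- dims[1]
  groups <- ((seq_len(n) - 1L) %/% f) + 1L
  m <- matrix(arr, nrow = n)
  sums <- rowsum(m, groups, reorder = TRUE)
  counts <- tabulate(groups)
  out <- sums / counts
  dim(out) <- c(length(counts), dims[-1])
  out
}

#' Block-mean downsampling to a coarser grid
#'
#' Averages the input over rectangular blocks; the target spacing must be an
#' integer multiple of the input spacing on every axis. Trailing partial
#' blocks average only the voxels present. For complete blocks the
#' voxel-volume-weighted total is conserved.
#'
#' @param input a [scalar_volume()].
#' @param target_spacing numeric vector, mm per voxel of the output grid.
#' @return A [scalar_volume()] on the coarser grid; the output origin is the
#'   center of the first block.
#' @export
downsample_block_mean <- function(input, target_spacing) {
  stopifnot(inherits(input, "scalar_volume"))
  g <- input$geometry
  d <- geom_ndim(g)
  if (length(target_spacing) != d) stop("target_spacing length must match dimensionality")
  ratio <- target_spacing / g$spacing
  f <- round(ratio)
  if (any(abs(ratio - f) > 1e-6) || any(f < 1)) {
    stop(
      "target spacing must be an integer multiple of input spacing per axis; ",
      "ratios are (", paste(format(ratio), collapse = ", "), ")"
    )
  }
  values <- input$values
  for (ax in seq_len(d)) {
    if (f[ax] > 1L) {
      perm <- seq_len(d)
      perm[c(1L, ax)] <- perm[c(ax, 1L)]
      values <- aperm(values, perm)
      values <- reduce_axis1_mean(values, f[ax])
      values <- aperm(values, perm) # perm is its own inverse (a swap)
    }
  }
  out_shape <- ceiling(g$shape / f)
  out_origin <- g$origin + (f - 1) / 2 * g$spacing
  scalar_volume(values, grid_geometry(out_shape, as.numeric(target_spacing), out_origin))
}

#' Resample to an arbitrary commensurable spacing
#'
#' Composes [upsample_nearest()] onto the common refinement grid with an
#' integer [downsample_block_mean()], so that e.g. a 0.2 mm lattice can be
#' brought to a 0.5 mm lattice (refine x2 to 0.1 mm, then average 5-blocks).
#' The per-axis refinement factor is the smallest integer `k` such that
#' `k * target / input` is an integer (searched up to `max_factor`).
#'
#' @param input a [scalar_volume()].
#' @param target_spacing numeric vector, mm.
#' @param max_factor largest refinement factor considered per axis.
#' @return A [scalar_volume()] at `target_spacing`.
#' @export
resample_to_spacing <- function(input, target_spacing, max_factor = 64L) {
  stopifnot(inherits(input, "scalar_volume"))
  g <- input$geometry
  d <- geom_ndim(g)
  k <- integer(d)
  for (ax in seq_len(d)) {
    found <- FALSE
    for (kk in seq_len(max_factor)) {
      r <- kk * target_spacing[ax] / g$spacing[ax]
      if (abs(r - round(r)) < 1e-9 && round(r) >= kk) {
        k[ax] <- kk
        found <- TRUE
        break
      }
    }
    if (!found) {
      stop(
        "no common refinement of input spacing ", g$spacing[ax],
        " and target spacing ", target_spacing[ax], " on axis ", ax
      )
    }
  }
  fine_spacing <- g$spacing / k
  # refined grid covering the same world extent (voxel edges preserved)
  fine_shape <- g$shape * k
  fine_origin <- g$origin - g$spacing / 2 + fine_spacing / 2
  fine <- upsample_nearest(input, grid_geometry(fine_shape, fine_spacing, fine_origin))
  downsample_block_mean(fine, target_spacing)
}
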