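test_that("NIfTI write/read round trip preserves values and geometry", {
  g <- grid_geometry(c(4, 4, 4), c(0.2, 0.2, 0.5), origin = c(1, -2, 0.5))
  vol <- scalar_volume(array(1, g$shape), g)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f)
  expect_true(geom_equal(back$geometry, g))
  expect_identical(back$values, vol$values)

  set.seed(11)
  vol2 <- scalar_volume(array(rnorm(prod(g$shape)), g$shape), g)
  write_volume(vol2, f)
  expect_equal(read_volume(f)$values, vol2$values, tolerance = 0)

  m <- binary_mask(array(runif(prod(g$shape)) > 0.5, g$shape), g)
  fm <- tempfile(fileext = ".nii.gz")
  write_mask(m, fm)
  back_m <- read_mask(fm)
  expect_identical(back_m$values, m$values)
  expect_true(geom_equal(back_m$geometry, g))
})

test_that("generated phantom volumes survive the NIfTI round trip losslessly", {
  case <- generate_phantom(phantom_spec(seed = 3L), "rt")
  f <- tempfile(fileext = ".nii.gz")
  write_volume(case$volumes$t2, f)
  back <- read_volume(f)
  expect_equal(max(abs(back$values - case$volumes$t2$values)), 0)
  expect_true(geom_equal(back$geometry, case$volumes$t2$geometry))
})

test_that("rotated or 4D NIfTI inputs are rejected with a named reason", {
  a <- array(as.double(1:64), c(4, 4, 4))
  th <- pi / 4
  rot <- diag(4)
  rot[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  img <- RNifti::asNifti(a, list(
    pixdim = c(1, 1, 1, 1, 1, 1, 1, 1), sform_code = 2L, qform_code = 0L,
    srow_x = rot[1, ], srow_y = rot[2, ], srow_z = rot[3, ]
  ))
  f <- tempfile(fileext = ".nii")
  RNifti::writeNifti(img, f)
  expect_error(read_volume(f), "oblique")

  img4 <- RNifti::asNifti(array(0, c(4, 4, 4, 2)))
  f4 <- tempfile(fileext = ".nii")
  RNifti::writeNifti(img4, f4)
  expect_error(read_volume(f4), "4 dimensions")

  expect_error(read_volume(tempfile(fileext = ".nii")), "cannot read")
})

test_that("upsample_nearest matches identity, constant-field and brute-force cases", {
  g <- grid_geometry(c(5, 4, 3), c(0.4, 0.4, 1))
  set.seed(21)
  vol <- scalar_volume(array(rnorm(prod(g$shape)), g$shape), g)
  expect_identical(upsample_nearest(vol, g)$values, vol$values)

  g1 <- grid_geometry(c(1, 1, 1), c(1, 1, 1))
  v1 <- scalar_volume(array(7, c(1, 1, 1)), g1)
  fine <- grid_geometry(c(2, 2, 2), c(0.5, 0.5, 0.5), origin = c(-0.25, -0.25, -0.25))
  up <- upsample_nearest(v1, fine)
  expect_true(all(up$values == 7))

  g3 <- grid_geometry(c(3, 3, 3), c(1, 1, 2), origin = c(0.3, -1, 2))
  vol3 <- scalar_volume(array(rnorm(27), c(3, 3, 3)), g3)
  tgt <- grid_geometry(c(6, 6, 6), c(0.5, 0.5, 1), origin = g3$origin - c(0.25, 0.25, 0.5))
  up3 <- upsample_nearest(vol3, tgt)
  coarse_pts <- tumorburden:::voxel_centers(g3)
  fine_pts <- tumorburden:::voxel_centers(tgt)
  for (q in seq_len(nrow(fine_pts))) {
    d2 <- rowSums(sweep(coarse_pts, 2, fine_pts[q, ], "-")^2)
    expect_identical(up3$values[q], vol3$values[which.min(d2)])
  }
})

test_that("upsample_nearest rejects a coarser target and keeps masks binary", {
  g <- grid_geometry(c(4, 4, 4), c(0.5, 0.5, 0.5))
  vol <- scalar_volume(array(1, g$shape), g)
  coarse <- grid_geometry(c(2, 2, 2), c(1, 1, 1))
  expect_error(upsample_nearest(vol, coarse), "coarser")

  set.seed(5)
  m <- binary_mask(array(runif(64) > 0.5, c(4, 4, 4)), g)
  fine <- grid_geometry(c(8, 8, 8), c(0.25, 0.25, 0.25), origin = c(-0.125, -0.125, -0.125))
  um <- upsample_nearest(m, fine)
  expect_type(um$values, "logical")
  # volume change bounded by the surface shell volume
  shell <- sum(surface_voxels(m)$values) * prod(g$spacing)
  expect_lte(abs(mask_volume_mm3(um) - mask_volume_mm3(m)), shell + 1e-9)
})

test_that("downsample_block_mean averages blocks and handles partial tails", {
  g <- grid_geometry(c(4, 4, 4), c(0.5, 0.5, 0.5))
  const <- scalar_volume(array(3.25, g$shape), g)
  down <- downsample_block_mean(const, c(1, 1, 1))
  expect_true(all(abs(down$values - 3.25) < 1e-15))
  expect_equal(down$geometry$shape, c(2L, 2L, 2L))
  expect_equal(down$geometry$origin, g$origin + 0.25)

  g2 <- grid_geometry(c(2, 2, 2), c(1, 1, 1))
  v <- scalar_volume(array(c(0, 0, 0, 0, 8, 8, 8, 8), c(2, 2, 2)), g2)
  expect_equal(as.vector(downsample_block_mean(v, c(2, 2, 2))$values), 4)

  set.seed(31)
  g8 <- grid_geometry(c(8, 8, 8), c(0.25, 0.25, 0.5))
  vol <- scalar_volume(array(rnorm(512), g8$shape), g8)
  down2 <- downsample_block_mean(vol, c(0.5, 0.5, 1))
  manual <- array(0, c(4, 4, 4))
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    manual[i, j, k] <- mean(vol$values[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), (2 * k - 1):(2 * k)])
  }
  expect_equal(down2$values, manual, tolerance = 1e-12)

  # partial tail: 5 voxels by factor 2 -> last output averages a single voxel
  g5 <- grid_geometry(c(5, 1, 1), c(1, 1, 1))
  v5 <- scalar_volume(array(as.double(1:5), c(5, 1, 1)), g5)
  d5 <- downsample_block_mean(v5, c(2, 1, 1))
  expect_equal(as.vector(d5$values), c(1.5, 3.5, 5))

  expect_error(downsample_block_mean(vol, c(0.6, 0.5, 1)), "integer multiple")
})

test_that("mask volume equals count times voxel volume", {
  g <- grid_geometry(c(10, 10, 10), c(0.2, 0.2, 0.5))
  expect_equal(mask_volume_mm3(binary_mask(array(FALSE, g$shape), g)), 0)

  v <- array(FALSE, g$shape)
  v[seq_len(100)] <- TRUE
  expect_equal(mask_volume_mm3(binary_mask(v, g)), 2)

  set.seed(41)
  rv <- array(runif(1000) > 0.7, g$shape)
  total <- 0
  for (i in seq_along(rv)) if (rv[i]) total <- total + prod(g$spacing)
  expect_equal(mask_volume_mm3(binary_mask(rv, g)), total)
})

test_that("block-mean then nearest upsampling is the identity on constant fields", {
  g <- grid_geometry(c(6, 6, 6), c(0.5, 0.5, 0.5))
  const <- scalar_volume(array(2.5, g$shape), g)
  down <- downsample_block_mean(const, c(1.5, 1.5, 1.5))
  up <- upsample_nearest(down, g)
  expect_true(all(abs(up$values - 2.5) < 1e-15))
})

test_that("resample_to_spacing bridges non-integer spacing ratios (0.2 -> 0.5 mm)", {
  g <- grid_geometry(c(10, 10, 4), c(0.2, 0.2, 0.5))
  const <- scalar_volume(array(1.75, g$shape), g)
  out <- resample_to_spacing(const, c(0.5, 0.5, 1))
  expect_equal(out$geometry$spacing, c(0.5, 0.5, 1))
  expect_equal(out$geometry$shape, c(4L, 4L, 2L))
  expect_true(all(abs(out$values - 1.75) < 1e-12))
  # mean over the full field is conserved for an exact tiling
  set.seed(51)
  vol <- scalar_volume(array(rnorm(prod(g$shape)), g$shape), g)
  out2 <- resample_to_spacing(vol, c(0.5, 0.5, 1))
  expect_equal(mean(out2$values), mean(vol$values), tolerance = 1e-12)
})
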