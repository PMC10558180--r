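test_that("landmark affine fit recovers identity and exact interpolating affines", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  fit <- fit_affine_landmarks(landmark_pairs(pts, pts))
  expect_equal(fit$linear, diag(3), tolerance = 1e-12)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(attr(fit, "fre_mm"), 0, tolerance = 1e-12)

  truth <- affine_transform(diag(c(1.1, 1.1, 1.1)), c(2, -1, 0.5))
  moving <- rbind(c(0, 0, 0), c(3, 0, 1), c(0, 2, 1), c(1, 1, 4))
  fixed <- transform_points(truth, moving)
  fit2 <- fit_affine_landmarks(landmark_pairs(moving, fixed))
  expect_equal(fit2$linear, truth$linear, tolerance = 1e-9)
  expect_equal(fit2$translation, truth$translation, tolerance = 1e-9)
  expect_lt(attr(fit2, "fre_mm"), 1e-9)
})

test_that("noisy landmark fit equals the explicit normal-equations solution", {
  set.seed(61)
  truth <- affine_transform(
    matrix(c(1.05, 0.1, 0, -0.08, 0.95, 0.02, 0.01, 0, 1.1), 3, 3),
    c(2, -1, 0.5)
  )
  moving <- matrix(runif(30, -5, 5), 10, 3)
  fixed <- transform_points(truth, moving) + matrix(rnorm(30, 0, 0.1), 10, 3)
  fit <- fit_affine_landmarks(landmark_pairs(moving, fixed))
  X <- cbind(moving, 1)
  B <- solve(t(X) %*% X) %*% t(X) %*% fixed
  expect_equal(fit$linear, t(B[1:3, ]), tolerance = 1e-9)
  expect_equal(fit$translation, as.numeric(B[4, ]), tolerance = 1e-9)
})

test_that("degenerate (coplanar) landmark configurations raise a rank error", {
  moving <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(2, 3, 0))
  expect_error(
    fit_affine_landmarks(landmark_pairs(moving, moving)),
    "degenerate landmark configuration"
  )
  expect_error(landmark_pairs(rbind(c(0, 0, 0), c(1, 1, 1)), rbind(c(0, 0, 0), c(1, 1, 1))), "at least 4")
})

test_that("affine fit is invariant to a common rigid motion of both frames", {
  set.seed(62)
  moving <- matrix(runif(15, -3, 3), 5, 3)
  fixed <- transform_points(affine_transform(diag(c(1.2, 0.9, 1)), c(1, 2, 3)), moving) +
    matrix(rnorm(15, 0, 0.05), 5, 3)
  th <- 0.4
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rigid <- affine_transform(rot, c(5, -2, 1))
  fit <- fit_affine_landmarks(landmark_pairs(moving, fixed))
  fit_moved <- fit_affine_landmarks(landmark_pairs(
    transform_points(rigid, moving), transform_points(rigid, fixed)
  ))
  # conjugating the fitted map by the rigid motion reproduces the moved fit
  conj_lin <- rot %*% fit$linear %*% t(rot)
  conj_tr <- as.numeric(rot %*% fit$linear %*% t(rot) %*% (-rigid$translation) +
    rot %*% fit$translation + rigid$translation)
  expect_equal(fit_moved$linear, conj_lin, tolerance = 1e-9)
  expect_equal(fit_moved$translation, conj_tr, tolerance = 1e-9)
  expect_equal(attr(fit_moved, "fre_mm"), attr(fit, "fre_mm"), tolerance = 1e-9)
})

test_that("apply_transform handles identity, pure shifts, and pullback sampling", {
  g <- grid_geometry(c(6, 5, 4), c(0.5, 0.5, 1))
  set.seed(63)
  vol <- scalar_volume(array(rnorm(prod(g$shape)), g$shape), g)
  ident <- affine_transform(diag(3), c(0, 0, 0))
  expect_equal(apply_transform(vol, ident, g, "nearest")$values, vol$values)

  shift <- affine_transform(diag(3), c(g$spacing[1], 0, 0))
  shifted <- apply_transform(vol, shift, g, "nearest")
  expect_equal(shifted$values[2:6, , ], vol$values[1:5, , ])
  expect_true(all(shifted$values[1, , ] == 0))

  # random invertible affine: probe 20 voxels against direct pullback
  A <- diag(3) + matrix(rnorm(9, 0, 0.05), 3, 3)
  tr <- c(0.3, -0.2, 0.4)
  tf <- affine_transform(A, tr)
  out <- apply_transform(vol, tf, g, "nearest")
  inv <- invert_transform(tf)
  centers <- tumorburden:::voxel_centers(g)
  probes <- sample(nrow(centers), 20)
  for (q in probes) {
    back <- as.numeric(transform_points(inv, centers[q, , drop = FALSE]))
    idx <- floor((back - g$origin) / g$spacing + 0.5)
    expected <- if (all(idx >= 0) && all(idx <= g$shape - 1)) {
      vol$values[idx[1] + 1, idx[2] + 1, idx[3] + 1]
    } else {
      0
    }
    expect_identical(out$values[q], expected)
  }
})

test_that("masks demand nearest interpolation and round-trip under T then T inverse", {
  g <- grid_geometry(c(8, 8, 4), c(0.5, 0.5, 1))
  set.seed(64)
  m <- random_blob_mask(g)
  tf <- affine_transform(diag(3), c(0.5, -0.5, 1))
  expect_error(apply_transform(m, tf, g, "linear"), "nearest")
  fwd <- apply_transform(m, tf, g, "nearest")
  back <- apply_transform(fwd, invert_transform(tf), g, "nearest")
  # interior voxels (two voxels from the volume face) are unchanged
  interior <- array(FALSE, g$shape)
  interior[3:6, 3:6, 2:3] <- TRUE
  expect_identical(back$values[interior], m$values[interior])
})

test_that("slice stacks with identity landmarks rebuild the input stack", {
  g <- grid_geometry(c(10, 8, 3), c(0.5, 0.5, 1))
  set.seed(65)
  vol <- scalar_volume(array(rnorm(prod(g$shape)), g$shape), g)
  plane <- grid_geometry(g$shape[1:2], g$spacing[1:2], g$origin[1:2])
  slices <- lapply(1:3, function(i) scalar_volume(vol$values[, , i], plane))
  pts <- rbind(c(0, 0), c(4, 0), c(0, 3), c(2, 2))
  lms <- lapply(1:3, function(i) landmark_pairs(pts, pts))
  out <- register_slice_stack(slices, lms, g, interpolation = "nearest")
  expect_equal(out$values, vol$values)
  expect_error(register_slice_stack(slices[1:2], lms, g), "slice count")
})

test_that("a 90-degree rotated slice is recovered through its landmarks", {
  n <- 11
  plane <- grid_geometry(c(n, n), c(0.5, 0.5))
  set.seed(66)
  img <- matrix(rnorm(n * n), n, n)
  center <- plane$origin + (plane$shape - 1) * plane$spacing / 2
  rot <- matrix(c(0, 1, -1, 0), 2, 2) # +90 degrees
  perturb <- affine_transform(rot, as.numeric(center - rot %*% center))
  moved <- apply_transform(scalar_volume(img, plane), perturb, plane, "nearest")
  fixed_pts <- rbind(c(0, 0), c(2, 0.5), c(0.5, 3), c(1.5, 1.5))
  lms <- landmark_pairs(transform_points(perturb, fixed_pts), fixed_pts)
  target <- grid_geometry(c(n, n, 1), c(0.5, 0.5, 1))
  out <- register_slice_stack(list(moved), list(lms), target, interpolation = "nearest")
  expect_equal(out$values[, , 1], img)
})

test_that("per-slice affine perturbations of a phantom are recovered with high Dice", {
  case <- memo("reg_case", generate_phantom(phantom_spec(seed = 9L), "reg"))
  problem <- make_slice_registration_problem(case$volumes$tdtomato, seed = 17L)
  recovered <- register_slice_stack(
    problem$slices, problem$landmarks, problem$target,
    interpolation = "nearest"
  )
  thr <- case$thresholds[["tdtomato"]]
  truth_sliced <- threshold_segment(problem$reference, thr)
  truth_rec <- threshold_segment(recovered, thr)
  expect_gte(dice(truth_rec, truth_sliced), 0.95)
})
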