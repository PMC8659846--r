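test_that("paired-point registration recovers exact correspondences", {
  tet <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  r <- paired_point_registration(tet, tet)
  expect_lt(max(abs(r$transform$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(r$transform$translation)), 1e-9)
  expect_lt(r$rms_residual, 1e-9)

  truth <- rigid_transform(rotation_about_axis(c(0, 0, 1), 90), c(1, 2, 3))
  r2 <- paired_point_registration(tet, apply_transform(truth, tet))
  expect_lt(max(abs(r2$transform$rotation - truth$rotation)), 1e-9)
  expect_lt(max(abs(r2$transform$translation - truth$translation)), 1e-9)
  expect_lt(r2$rms_residual, 1e-9)
})

test_that("noiseless recovery holds for arbitrary rigid motions", {
  set.seed(7)
  for (i in 1:20) {
    pts <- matrix(rnorm(24, sd = 25), ncol = 3)
    truth <- rand_rigid_transform()
    r <- paired_point_registration(pts, apply_transform(truth, pts))
    expect_lt(sqrt(sum((r$transform$rotation - truth$rotation)^2)), 1e-9)
    expect_lt(max(abs(r$transform$translation - truth$translation)), 1e-9)
  }
})

test_that("closed-form solution matches an independent numerical minimizer", {
  set.seed(11)
  truth <- rigid_transform(rotation_about_axis(c(1, 2, -1), 35), c(4, -2, 6))
  for (n in c(10, 12)) {
    pts <- matrix(rnorm(3 * n, sd = 30), ncol = 3)
    noisy <- apply_transform(truth, pts) + matrix(rnorm(3 * n, 0, 0.2), ncol = 3)
    r <- paired_point_registration(pts, noisy)
    oracle <- brute_force_rigid_rms(pts, noisy, start = rigid_params(truth))
    expect_lt(abs(r$rms_residual - oracle), 1e-6)
    expect_gte(r$max_residual, r$rms_residual)
  }
})

test_that("rms residual is invariant under a common pre-rotation", {
  set.seed(13)
  pts <- matrix(rnorm(30, sd = 20), ncol = 3)
  noisy <- pts + matrix(rnorm(30, 0, 0.5), ncol = 3)
  base <- paired_point_registration(pts, noisy)$rms_residual
  for (i in 1:5) {
    q <- rand_rigid_transform()
    r <- paired_point_registration(apply_transform(q, pts),
                                   apply_transform(q, noisy))
    expect_equal(r$rms_residual, base, tolerance = 1e-9)
  }
})

test_that("degenerate registration inputs are rejected", {
  expect_error(paired_point_registration(rbind(c(0, 0, 0), c(1, 1, 1)),
                                         rbind(c(0, 0, 0), c(1, 1, 1))),
               "at least 3")
  line <- cbind(seq_len(5), seq_len(5) * 2, seq_len(5) * -1)
  expect_error(paired_point_registration(line, line), "collinear")
  a <- fiducial_set(diag(3) * 5, c("x", "y", "z"))
  b <- fiducial_set(diag(3) * 5, c("x", "y", "q"))
  expect_error(paired_point_registration(a, b), "labels")
})

test_that("labeled fiducial sets are matched by label, not order", {
  pts <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  truth <- rigid_transform(rotation_about_axis(c(1, 1, 1), 20), c(1, -1, 2))
  moved <- apply_transform(truth, pts)
  perm <- c(3, 1, 4, 2)
  a <- fiducial_set(pts, paste0("f", 1:4))
  b <- fiducial_set(moved[perm, ], paste0("f", perm))
  r <- paired_point_registration(a, b)
  expect_lt(r$rms_residual, 1e-9)
})

test_that("ICP converges immediately from the exact pose and stays monotone", {
  ph <- make_phantom_mesh(phantom_spec(seed = 5, resolution = 64))
  set.seed(21)
  surf <- sample_surface_points(ph, 40)
  truth <- rigid_transform(rotation_about_axis(c(1, 0.5, 0.2), 8), c(12, -9, 15))
  trk <- apply_transform(truth, surf)
  exact <- icp_refine(trk, ph, init = invert_transform(truth))
  expect_lte(exact$iterations, 2)
  expect_lt(exact$rms_residual, 1e-6)
  expect_true(exact$converged)

  # perturbed initialization: 2 degrees + 1 mm off
  pert <- compose_transform(
    rigid_transform(rotation_about_axis(c(0, 1, 0), 2), c(1, 0, 0)),
    invert_transform(truth))
  ref <- icp_refine(trk, ph, init = pert)
  expect_lt(ref$rms_residual, 0.05)
  expect_true(all(diff(ref$rms_history) <= 1e-12))
})

test_that("noiseless landmark + surface registration meets the 0.1 mm bound", {
  ph <- make_phantom_mesh(phantom_spec(seed = 9, resolution = 64))
  reg <- simulate_registration(ph, seed = 17)
  expect_lt(reg$icp$rms_residual, 0.1)
  expect_lte(reg$icp$max_residual, 0.1)
  # the estimated transform is the inverse of the simulated pose
  comp <- compose_transform(reg$icp$transform, reg$truth)
  expect_lt(max(abs(comp$rotation - diag(3))), 1e-6)
})

test_that("planToReal estimation follows the 4-pinhole protocol", {
  pins <- fiducial_set(rbind(c(0, 0, 0), c(20, 0, 2), c(0, 18, 1), c(18, 16, -1)),
                       paste0("ph", 1:4))
  same <- plan_to_real(pins, pins)
  expect_lt(max(abs(same$transform$rotation - diag(3))), 1e-9)
  expect_lt(same$rms_residual, 1e-9)

  shifted <- fiducial_set(pins$points + rep(c(0, 3, 0), each = 4),
                          pins$labels)
  r <- plan_to_real(pins, shifted)
  expect_equal(sqrt(sum(r$transform$translation^2)), 3, tolerance = 1e-9)
  expect_lt(rotation_angle(r$transform), 1e-7)

  set.seed(31)
  noisy <- fiducial_set(pins$points + matrix(rnorm(12, 0, 0.2), 4, 3),
                        pins$labels)
  est <- plan_to_real(pins, noisy)
  oracle <- brute_force_rigid_rms(pins$points, noisy$points)
  expect_lt(abs(est$rms_residual - oracle), 1e-6)

  three <- fiducial_set(pins$points[1:3, ], pins$labels[1:3])
  expect_error(plan_to_real(three, three), "4 pinholes")
  relabeled <- fiducial_set(pins$points, c("ph1", "ph2", "ph3", "other"))
  expect_error(plan_to_real(pins, relabeled), "labels")
})
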