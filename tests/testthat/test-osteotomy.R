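test_that("cylinder and cube cross sections match closed forms", {
  cyl <- mesh_cylinder(radius = 1, height = 2, n_theta = 256, n_z = 8)
  sec <- intersect_plane_mesh(cyl, cutting_plane(c(0, 0, 0), c(0, 0, 1)), 0.01)
  r <- sqrt(rowSums(sec$points[, 1:2]^2))
  expect_true(all(abs(r - 1) < 1e-3))          # within chord sagitta
  expect_true(all(abs(sec$points[, 3]) < 1e-9))
  expect_equal(section_arc_length(sec), 2 * pi, tolerance = 1e-3)
  expect_equal(length(sec$polylines), 1)
  expect_true(sec$closed[1])

  box <- mesh_box(center = c(0.5, 0.5, 0.5), size = 1)
  sq <- intersect_plane_mesh(box, cutting_plane(c(0.5, 0.5, 0.5), c(1, 0, 0)),
                             0.01)
  expect_equal(section_arc_length(sq), 4, tolerance = 1e-9)
  expect_true(all(abs(sq$points[, 1] - 0.5) < 1e-9))
})

test_that("section points lie on the plane and on the mesh surface", {
  ph <- make_phantom_mesh(phantom_spec(seed = 2, resolution = 64))
  cs <- make_cases(ph, seed = 2)[[2]]$C
  sec <- intersect_plane_mesh(ph, cs$plane, 0.5)
  off_plane <- abs((sec$points %*% cs$plane$normal) -
                     sum(cs$plane$origin * cs$plane$normal))
  expect_lt(max(off_plane), 1e-6)
  expect_lt(max(closest_surface_points(sec$points, ph)$distance), 1e-6)
  expect_gte(nrow(sec$points), 2)
})

test_that("a plane missing the mesh raises a no-intersection error", {
  cyl <- fixture_cylinder()
  expect_error(intersect_plane_mesh(cyl, cutting_plane(c(0, 0, 100), c(0, 0, 1))),
               class = "psiplace_no_intersection")
  expect_error(intersect_plane_mesh(cyl, cutting_plane(c(0, 0, 0), c(0, 0, 1)),
                                    spacing = -1), "spacing")
})

test_that("MOD closed forms on the perpendicular cylinder fixture", {
  cyl <- fixture_cylinder(radius = 20)
  pl <- cutting_plane(c(0, 0, 0), c(0, 0, 1))

  expect_equal(assess_placement(cyl, pl, identity_transform(), 0.1)$mod, 0)

  shift <- rigid_transform(diag(3), c(0, 0, 3))
  dev <- assess_placement(cyl, pl, shift, 0.1)
  expect_equal(dev$mod, 3, tolerance = 0.01)
  expect_gte(dev$mod, dev$mean_deviation)
  expect_equal(dev$mod, max(dev$per_point_distances))

  spin <- rigid_transform(rotation_about_axis(c(0, 0, 1), 37), c(0, 0, 0))
  expect_lt(assess_placement(cyl, pl, spin, 0.1)$mod, 1e-9)
})

test_that("MOD equals the exhaustive all-pairs oracle on coarse meshes", {
  coarse <- mesh_cylinder(radius = 20, height = 60, n_theta = 24, n_z = 6)
  expect_lte(nrow(coarse$faces), 500)
  pl <- cutting_plane(c(0, 0, 0), c(0, 0, 1))
  spacing <- 0.2
  for (tr in list(rigid_transform(diag(3), c(0, 0, 3)),
                  rigid_transform(rotation_about_axis(c(1, 0, 0), 2), c(0.5, 0, 1)),
                  rigid_transform(rotation_about_axis(c(0, 1, 0), 3), c(0, 0, -2)))) {
    mod <- assess_placement(coarse, pl, tr, spacing)$mod
    raw_planned <- intersect_plane_mesh(coarse, pl, spacing = NULL)$points
    raw_actual <- intersect_plane_mesh(coarse, transform_plane(pl, tr),
                                       spacing = NULL)$points
    oracle <- all_pairs_directed_max(raw_planned, raw_actual)
    expect_lt(abs(mod - oracle), 2 * spacing)
  }
})

test_that("the directed deviation metric is asymmetric", {
  big <- mesh_box(size = c(40, 40, 10))
  small <- mesh_box(size = c(10, 10, 10))
  pl <- cutting_plane(c(0, 0, 0), c(0, 0, 1))
  sec_big <- intersect_plane_mesh(big, pl, 0.1)
  sec_small <- intersect_plane_mesh(small, pl, 0.1)
  fwd <- max_osteotomy_deviation(sec_small, sec_big)$mod
  rev <- max_osteotomy_deviation(sec_big, sec_small)$mod
  expect_gt(abs(fwd - rev), 1)   # corner of the big square is farther
  expect_gt(rev, fwd)
})

test_that("MOD is stable under refinement of the sampling spacing", {
  ph <- make_phantom_mesh(phantom_spec(seed = 4, resolution = 64))
  cs <- make_cases(ph, seed = 4)[[3]]$C
  tr <- rigid_transform(rotation_about_axis(c(0.3, 1, 0.1), 1.5), c(0.8, -0.4, 0.6))
  m1 <- assess_placement(ph, cs$plane, tr, spacing = 0.2)$mod
  m2 <- assess_placement(ph, cs$plane, tr, spacing = 0.1)$mod
  expect_lt(abs(m1 - m2), 0.2)
})

test_that("the intersection can be restricted to the nearest component", {
  b1 <- mesh_box(center = c(0, 0, 0), size = 10)
  b2 <- mesh_box(center = c(30, 0, 0), size = 10)
  two <- triangle_mesh(rbind(b1$vertices, b2$vertices),
                       rbind(b1$faces, b2$faces + nrow(b1$vertices)),
                       clean = FALSE)
  pl <- cutting_plane(c(0, 0, 0), c(0, 0, 1))
  all_cs <- intersect_plane_mesh(two, pl, 0.1)
  expect_equal(length(all_cs$polylines), 2)
  near <- intersect_plane_mesh(two, pl, 0.1, component = "nearest")
  expect_equal(length(near$polylines), 1)
  expect_lt(max(near$points[, 1]), 10)   # far box excluded
})

test_that("off-bone placements are flagged, not dropped", {
  cyl <- fixture_cylinder()
  pl <- cutting_plane(c(0, 0, 0), c(0, 0, 1))
  gone <- rigid_transform(diag(3), c(0, 0, 500))
  dev <- assess_placement(cyl, pl, gone, 0.1)
  expect_identical(dev$status, "off_bone")
  expect_identical(dev$mod, Inf)
})
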