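test_that("phantom generation is deterministic and well-formed", {
  spec <- phantom_spec(seed = 8)
  m1 <- make_phantom_mesh(spec)
  m2 <- make_phantom_mesh(spec)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)
  expect_gte(nrow(m1$faces), 5000)
  expect_true(all(c("C", "S") %in% attr(m1, "region")))
})

test_that("doubling the scale doubles the bounding-box diagonal", {
  d1 <- diff(mesh_bbox(make_phantom_mesh(phantom_spec(seed = 3, size_mm = 200))))
  d2 <- diff(mesh_bbox(make_phantom_mesh(phantom_spec(seed = 3, size_mm = 400))))
  expect_equal(sqrt(sum(d2^2)) / sqrt(sum(d1^2)), 2, tolerance = 1e-6)
})

test_that("with a homogeneous crest, the C band is flatter than the S notch", {
  m <- make_phantom_mesh(phantom_spec(seed = 6, crest_homogeneity = 1))
  curv <- vertex_normal_variation(m)
  region <- attr(m, "region")
  expect_lt(max(curv[region == "C"]), max(curv[region == "S"]))
})

test_that("generated cases satisfy their geometric contract", {
  ph <- make_phantom_mesh(phantom_spec(seed = 12))
  cases <- make_cases(ph, seed = 12)
  cases2 <- make_cases(ph, seed = 12)
  expect_equal(length(cases), 6)
  fpC <- fpS <- numeric(0)
  for (k in 1:6) {
    expect_identical(cases2[[k]]$C$pinholes_planned$points,
                     cases[[k]]$C$pinholes_planned$points)
    for (r in c("S", "C")) {
      cs <- cases[[k]][[r]]
      expect_identical(cs$region, r)
      # plane intersects the phantom (contract: no no-intersection error)
      expect_s3_class(intersect_plane_mesh(ph, cs$plane, 0.5), "cross_section")
      expect_equal(nrow(cs$pinholes_planned$points), 4)
      # pinholes stay within the footprint of the plane origin
      d <- sqrt(rowSums(sweep(cs$pinholes_planned$points, 2,
                              cs$plane$origin)^2))
      expect_true(all(d <= cs$footprint_size_mm))
      if (r == "C") fpC <- c(fpC, cs$footprint_size_mm)
      else fpS <- c(fpS, cs$footprint_size_mm)
    }
  }
  expect_lt(max(fpS), min(fpC))  # S guides are the small, characteristic ones
})

test_that("placement noise model has the designed limiting behaviour", {
  ph <- make_phantom_mesh(phantom_spec(seed = 3, resolution = 64))
  cs <- make_cases(ph, seed = 3)[[1]]$C

  set.seed(51)
  none <- placement_model("freehand", rot_sigma_deg = 0, trans_sigma_mm = 0,
                          slip_prob = 0)
  tr <- simulate_placement(cs, none)
  expect_lt(rotation_angle(tr), 1e-9)
  expect_lt(max(abs(tr$translation)), 1e-9)

  always <- placement_model("freehand", rot_sigma_deg = 0, trans_sigma_mm = 0,
                            slip_prob = 1, slip_scale_mm = 8)
  for (i in 1:20) {
    tr <- simulate_placement(cs, always)
    expect_gte(sqrt(sum(tr$translation^2)), 8)
  }
  # slips ride along the homogeneous crest direction
  tr <- simulate_placement(cs, always)
  expect_gt(abs(sum(tr$translation * cs$slip_dir)) /
              sqrt(sum(tr$translation^2)), 0.999)
})

test_that("freehand placements deviate more than AR-guided ones", {
  ph <- make_phantom_mesh(phantom_spec(seed = 3, resolution = 64))
  cs <- make_cases(ph, seed = 3)[[4]]$C
  models <- default_placement_models()
  set.seed(61)
  mod_of <- function(model, n) replicate(n, {
    tr <- simulate_placement(cs, model)
    assess_placement(ph, cs$plane, tr, spacing = 0.25)$mod
  })
  free <- mod_of(models$freehand, 150)
  ar <- mod_of(models$smartphone, 150)
  expect_gt(median(free), median(ar))
})

test_that("pinhole measurement closes the loop with planToReal", {
  ph <- make_phantom_mesh(phantom_spec(seed = 3, resolution = 64))
  cs <- make_cases(ph, seed = 3)[[2]]$S

  set.seed(71)
  meas0 <- simulate_pinhole_measurement(cs, identity_transform(), 0)
  expect_equal(meas0$points, cs$pinholes_planned$points, tolerance = 1e-12)

  truth <- simulate_placement(cs, default_placement_models()$freehand)
  meas <- simulate_pinhole_measurement(cs, truth, 0)
  est <- plan_to_real(cs$pinholes_planned, meas)
  expect_lt(max(abs(est$transform$rotation - truth$rotation)), 1e-9)
  expect_lt(max(abs(est$transform$translation - truth$translation)), 1e-9)

  # with 0.2 mm pointer noise the guide displacement (translation at the
  # footprint centroid) is recovered well inside the noise level
  errs <- replicate(500, {
    meas <- simulate_pinhole_measurement(cs, truth, 0.2)
    est <- plan_to_real(cs$pinholes_planned, meas)
    sqrt(sum((apply_transform(est$transform, cs$centroid) -
                apply_transform(truth, cs$centroid))^2))
  })
  expect_lt(mean(errs), 0.4)
})
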