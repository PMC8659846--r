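test_that("a single-triangle ASCII STL loads as 3 vertices and 1 face", {
  f <- withr::local_tempfile(fileext = ".stl")
  write_single_triangle_stl(f)
  m <- read_mesh(f)
  expect_s3_class(m, "triangle_mesh")
  expect_equal(nrow(m$vertices), 3)
  expect_equal(nrow(m$faces), 1)
  expect_equal(sort(m$vertices[, 1]), c(0, 0, 1))
})

test_that("binary STL save/load round-trips vertices at float32 precision", {
  cyl <- mesh_cylinder(radius = 12.5, height = 30, n_theta = 24, n_z = 4)
  f <- withr::local_tempfile(fileext = ".stl")
  write_mesh(cyl, f)
  back <- read_mesh(f)
  expect_equal(nrow(back$vertices), nrow(cyl$vertices))
  expect_equal(nrow(back$faces), nrow(cyl$faces))
  # vertices match up to float32 storage of coordinates ~12.5 mm
  reord <- function(V) V[order(V[, 1], V[, 2], V[, 3]), ]
  expect_lt(max(abs(reord(back$vertices) - reord(cyl$vertices))), 1e-4)
})

test_that("ASCII STL and PLY writers round-trip", {
  cyl <- mesh_cylinder(radius = 5, height = 10, n_theta = 16, n_z = 3)
  fa <- withr::local_tempfile(fileext = ".stl")
  write_mesh(cyl, fa, ascii = TRUE)
  expect_equal(nrow(read_mesh(fa)$vertices), nrow(cyl$vertices))
  fp <- withr::local_tempfile(fileext = ".ply")
  write_mesh(cyl, fp)
  back <- read_mesh(fp)
  expect_equal(back$vertices, cyl$vertices, tolerance = 1e-7)
  expect_equal(back$faces, cyl$faces)
})

test_that("empty, garbage and truncated mesh files raise format errors", {
  f0 <- withr::local_tempfile(fileext = ".stl")
  file.create(f0)
  expect_error(read_mesh(f0), "empty|truncated")
  fg <- withr::local_tempfile(fileext = ".stl")
  writeLines("hello", fg)
  expect_error(read_mesh(fg))
  # valid binary STL, then cut short
  ft <- withr::local_tempfile(fileext = ".stl")
  write_mesh(mesh_box(), ft)
  raw <- readBin(ft, "raw", n = file.info(ft)$size)
  writeBin(raw[1:(length(raw) - 30)], ft)
  expect_error(read_mesh(ft), "truncated")
  expect_error(read_mesh(tempfile(fileext = ".stl")), "not found")
  fx <- withr::local_tempfile(fileext = ".obj")
  file.create(fx)
  expect_error(read_mesh(fx), "unsupported")
})

test_that("load-time cleaning merges duplicate vertices and drops degenerate faces", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(1, 0, 0) + 1e-9,              # duplicate of vertex 2
             c(0, 0, 0), c(0.5, 0, 0), c(1, 0, 0))  # collinear = zero area
  F <- rbind(c(1, 2, 3), c(1, 4, 3), c(5, 6, 7))
  m <- triangle_mesh(V, F)
  expect_equal(nrow(m$vertices), 4)   # unique coordinates only
  expect_equal(nrow(m$faces), 2)            # degenerate face removed
  expect_true(all(mesh_areas(m) > 1e-9))
  expect_error(triangle_mesh(V[1:3, ], rbind(c(1, 2, 4))), "out of range")
  expect_error(triangle_mesh(V[c(1, 2, 5), ], rbind(c(1, 2, 3))),
               "no non-degenerate faces")
})

test_that("fiducial CSV and JSON round-trip with labels and frame", {
  fs <- fiducial_set(matrix(rnorm(12), 4, 3), c("a", "b", "c", "d"),
                     frame = "tracker")
  fc <- withr::local_tempfile(fileext = ".csv")
  write_fiducials_csv(fs, fc)
  back <- read_fiducials_csv(fc, frame = "tracker")
  expect_equal(back$labels, fs$labels)
  expect_equal(back$points, fs$points, tolerance = 1e-12)
  fj <- withr::local_tempfile(fileext = ".json")
  write_fiducials_json(fs, fj)
  back2 <- read_fiducials_json(fj)
  expect_equal(back2$points, fs$points)
  expect_equal(back2$frame, "tracker")
  # plane CSV variant
  fp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,x,y,z,nx,ny,nz", "osteo1,1,2,3,0,0,2"), fp)
  pl <- read_fiducials_csv(fp)
  expect_s3_class(pl$osteo1, "cutting_plane")
  expect_equal(pl$osteo1$normal, c(0, 0, 1))
})
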