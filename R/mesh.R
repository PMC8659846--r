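#' Triangle surface mesh
#'
#' Container for a triangulated bone surface in the bone coordinate frame
#' (mm). On construction duplicate vertices are merged (within 1e-6 mm)
#' and degenerate faces (repeated indices or area below 1e-9 mm^2) are
#' dropped, so that downstream closest-point queries see sane topology.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param clean merge duplicate vertices and drop degenerate faces
#'   (default `TRUE`).
#' @return An object of class `triangle_mesh` with elements `vertices`
#'   and `faces`.
#' @export
triangle_mesh <- function(vertices, faces, clean = TRUE) {
  V <- unname(as.matrix(vertices))
  F <- unname(as.matrix(faces))
  storage.mode(V) <- "double"
  if (ncol(V) != 3L) stop("vertices must be n x 3")
  if (ncol(F) != 3L) stop("faces must be m x 3")
  storage.mode(F) <- "integer"
  if (nrow(F) < 1L) stop("mesh must have at least one face")
  if (anyNA(V) || anyNA(F)) stop("mesh contains missing values")
  if (min(F) < 1L || max(F) > nrow(V)) stop("face indices out of range")

  if (clean) {
    # merge vertices closer than 1e-6 mm (grid snap)
    key <- paste(round(V[, 1], 6), round(V[, 2], 6), round(V[, 3], 6))
    first <- !duplicated(key)
    remap <- match(key, key[first])
    V <- V[first, , drop = FALSE]
    F <- matrix(remap[F], ncol = 3)
    bad <- F[, 1] == F[, 2] | F[, 2] == F[, 3] | F[, 1] == F[, 3]
    F <- F[!bad, , drop = FALSE]
    if (nrow(F) > 0) {
      a <- .face_areas(V, F)
      F <- F[a > 1e-9, , drop = FALSE]
    }
    if (nrow(F) < 1L) stop("mesh has no non-degenerate faces after cleaning")
  }
  structure(list(vertices = V, faces = F), class = "triangle_mesh")
}

.face_areas <- function(V, F) {
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Triangle areas of a mesh
#' @param mesh a `triangle_mesh`.
#' @return Numeric vector of face areas (mm^2).
#' @export
mesh_areas <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  .face_areas(mesh$vertices, mesh$faces)
}

#' Axis-aligned bounding box of a mesh
#' @param mesh a `triangle_mesh`.
#' @return 2 x 3 matrix with rows `min` and `max`.
#' @export
mesh_bbox <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  rbind(min = apply(mesh$vertices, 2, min), max = apply(mesh$vertices, 2, max))
}

#' Rigidly transform a mesh
#' @param mesh a `triangle_mesh`.
#' @param transform a `rigid_transform`.
#' @return The transformed `triangle_mesh`.
#' @export
transform_mesh <- function(mesh, transform) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  triangle_mesh(apply_transform(transform, mesh$vertices), mesh$faces, clean = FALSE)
}

#' Closest points on a mesh surface
#'
#' True point-to-triangle projection (not nearest vertex) of each query
#' point onto the mesh surface.
#'
#' @param points n x 3 matrix of query points.
#' @param mesh a `triangle_mesh`.
#' @return A list with `points` (n x 3 matrix of surface foot points),
#'   `distance` (mm) and `face` (1-based face index).
#' @export
closest_surface_points <- function(points, mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  P <- if (is.null(dim(points))) matrix(as.numeric(points), 1, 3) else as.matrix(points)
  storage.mode(P) <- "double"
  cpp_closest_on_mesh(P, mesh$vertices, mesh$faces)
}

#' Random points on a mesh surface
#'
#' Area-weighted uniform sampling via random barycentric coordinates.
#' Uses the current RNG stream.
#'
#' @param mesh a `triangle_mesh`.
#' @param n number of points.
#' @return n x 3 matrix of surface points.
#' @export
sample_surface_points <- function(mesh, n) {
  stopifnot(inherits(mesh, "triangle_mesh"), n >= 1)
  a <- mesh_areas(mesh)
  f <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = a)
  r1 <- sqrt(runif(n)); r2 <- runif(n)
  w1 <- 1 - r1; w2 <- r1 * (1 - r2); w3 <- r1 * r2
  V <- mesh$vertices; F <- mesh$faces[f, , drop = FALSE]
  w1 * V[F[, 1], , drop = FALSE] + w2 * V[F[, 2], , drop = FALSE] +
    w3 * V[F[, 3], , drop = FALSE]
}

#' Open cylinder fixture mesh
#'
#' Uncapped right circular cylinder about the z axis, a standard fixture
#' for closed-form cross-section checks.
#'
#' @param radius cylinder radius (mm).
#' @param height total height (mm), centred on z = 0.
#' @param n_theta circumferential resolution.
#' @param n_z number of vertex rings.
#' @return A `triangle_mesh`.
#' @export
mesh_cylinder <- function(radius = 1, height = 2, n_theta = 128, n_z = 10) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  z <- seq(-height / 2, height / 2, length.out = n_z)
  V <- cbind(radius * cos(rep(th, n_z)), radius * sin(rep(th, n_z)),
             rep(z, each = n_theta))
  F <- NULL
  idx <- function(i, j) (j - 1L) * n_theta + ((i - 1L) %% n_theta) + 1L
  i <- seq_len(n_theta)
  Fs <- vector("list", n_z - 1)
  for (j in seq_len(n_z - 1)) {
    a <- idx(i, j); b <- idx(i + 1L, j); c2 <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
    Fs[[j]] <- rbind(cbind(a, b, c2), cbind(a, c2, d))
  }
  triangle_mesh(V, do.call(rbind, Fs), clean = FALSE)
}

#' Axis-aligned box fixture mesh
#'
#' @param center length-3 box centre (mm).
#' @param size length-3 edge lengths (mm); recycled if scalar.
#' @return A `triangle_mesh` of 12 triangles.
#' @export
mesh_box <- function(center = c(0, 0, 0), size = 1) {
  size <- rep_len(as.numeric(size), 3)
  h <- size / 2
  s <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  V <- sweep(as.matrix(s) * rep(h, each = 8), 2, as.numeric(center), "+")
  F <- rbind(
    c(1, 3, 2), c(2, 3, 4),  # z-
    c(5, 6, 7), c(6, 8, 7),  # z+
    c(1, 2, 5), c(2, 6, 5),  # y-
    c(3, 7, 4), c(4, 7, 8),  # y+
    c(1, 5, 3), c(3, 5, 7),  # x-
    c(2, 4, 6), c(4, 8, 6))  # x+
  triangle_mesh(V, F, clean = FALSE)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  bb <- mesh_bbox(x)
  cat(sprintf("Triangle mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  extent (mm): [%.1f, %.1f] x [%.1f, %.1f] x [%.1f, %.1f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}
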