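# Shared fixtures and independent oracles used across the suite.

# Standard closed-form fixture: open cylinder, radius 20 mm, no vertex
# ring on z = 0 so plane z = 0 cuts cleanly through facets.
fixture_cylinder <- function(radius = 20, n_theta = 256)
  mesh_cylinder(radius = radius, height = 60, n_theta = n_theta, n_z = 8)

rand_rigid_transform <- function(max_angle = 180, max_trans = 50) {
  rigid_transform(rotation_about_axis(rnorm(3), runif(1, -max_angle, max_angle)),
                  runif(3, -max_trans, max_trans))
}

# Independent numerical oracle for rigid least squares: generic
# optimisation over a rotation-vector + translation parameterisation,
# started from a supplied guess (typically the known ground truth, so
# the oracle never touches the closed-form solver).
brute_force_rigid_rms <- function(moving, fixed, start = rep(0, 6)) {
  obj <- function(par) {
    th <- sqrt(sum(par[1:3]^2))
    R <- if (th < 1e-12) diag(3) else rotation_about_axis(par[1:3], th * 180 / pi)
    pred <- moving %*% t(R) + matrix(par[4:6], nrow(moving), 3, byrow = TRUE)
    sum((pred - fixed)^2)
  }
  fit <- optim(start, obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-16))
  fit <- optim(fit$par, obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-16))
  sqrt(fit$value / nrow(moving))
}

rigid_params <- function(tr) {
  ang <- rotation_angle(tr) * pi / 180
  if (ang < 1e-12) return(c(0, 0, 0, tr$translation))
  R <- tr$rotation
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  ax <- ax / sqrt(sum(ax^2))
  c(ax * ang, tr$translation)
}

# Exhaustive directed nearest-neighbour oracle (plain R, all pairs).
all_pairs_directed_max <- function(A, B) {
  max(apply(A, 1, function(a) sqrt(min(colSums((t(B) - a)^2)))))
}

# Independent Dunn implementation, written from the textbook formula
# with explicit loops and run-length tie counting.
dunn_oracle <- function(groups) {
  k <- length(groups)
  x <- unlist(groups)
  g <- rep(seq_len(k), vapply(groups, length, 0L))
  N <- length(x)
  r <- rank(x)
  tie_counts <- rle(sort(x))$lengths
  correction <- sum(tie_counts^3 - tie_counts) / (12 * (N - 1))
  out <- NULL
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    ni <- sum(g == i); nj <- sum(g == j)
    zij <- (mean(r[g == i]) - mean(r[g == j])) /
      sqrt((N * (N + 1) / 12 - correction) * (1 / ni + 1 / nj))
    out <- rbind(out, data.frame(i = i, j = j, z = zij,
                                 p = 2 * (1 - pnorm(abs(zij)))))
  }
  out
}

# Discrete curvature proxy: for each vertex, the largest angle (rad)
# between the unit normals of its incident faces.
vertex_normal_variation <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  e1 <- V[F[, 2], ] - V[F[, 1], ]; e2 <- V[F[, 3], ] - V[F[, 1], ]
  N <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  N <- N / pmax(sqrt(rowSums(N^2)), 1e-30)
  inc <- split(rep(seq_len(nrow(F)), 3), as.vector(F))
  out <- numeric(nrow(V))
  for (v in seq_along(inc)) {
    f <- inc[[v]]
    if (length(f) < 2) next
    cosangles <- tcrossprod(N[f, , drop = FALSE])
    out[as.integer(names(inc)[v])] <- acos(min(1, max(-1, min(cosangles))))
  }
  out
}

# Small ASCII STL with one triangle, written programmatically.
write_single_triangle_stl <- function(path) {
  writeLines(c("solid tri",
               "  facet normal 0 0 1",
               "    outer loop",
               "      vertex 0 0 0",
               "      vertex 1 0 0",
               "      vertex 0 1 0",
               "    endloop",
               "  endfacet",
               "endsolid tri"), path)
  path
}
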