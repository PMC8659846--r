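# Synthetic stand-ins for the physical experiment: a hemipelvis-like
# phantom shell with a broad homogeneous iliac-crest (C) band and a
# narrow characteristic supra-acetabular (S) notch, per-case PSI
# footprints with cutting planes and pinholes, and stochastic placement
# and pointer-measurement noise models.

#' Phantom specification
#'
#' @param seed integer seed; the generated mesh is a deterministic
#'   function of the spec.
#' @param size_mm overall scale of the phantom (default 200 mm, the
#'   order of a hemipelvis).
#' @param crest_homogeneity in `[0, 1]`; 1 gives a featureless crest
#'   band, lower values add surface texture bumps to part of the band.
#' @param tissue_thickness_mm soft-tissue (silicone) analog thickness;
#'   0 is the conventional bare-bone phantom, positive values the
#'   realistic coated one. Affects the placement noise model, not the
#'   bone geometry (registration happens before coating).
#' @param resolution parametric grid resolution per axis (default 96,
#'   about 18k faces).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L, size_mm = 200, crest_homogeneity = 0.7,
                         tissue_thickness_mm = 0, resolution = 96L) {
  if (crest_homogeneity < 0 || crest_homogeneity > 1)
    stop("crest_homogeneity must be in [0, 1]")
  if (tissue_thickness_mm < 0) stop("tissue_thickness_mm must be >= 0")
  if (size_mm <= 0) stop("size_mm must be positive")
  structure(list(seed = as.integer(seed), size_mm = size_mm,
                 crest_homogeneity = crest_homogeneity,
                 tissue_thickness_mm = tissue_thickness_mm,
                 resolution = as.integer(resolution)),
            class = "phantom_spec")
}

# sign-preserving power for the superellipsoid profile
.spow <- function(w, e) sign(w) * abs(w)^e

# Parametric phantom surface: a flattened superellipsoid "blade" whose
# long axis x carries the crest ridge on top (y max, v = 0). u in
# (0, pi) runs along the blade (tips at u = 0, pi), v in [-pi, pi)
# around the cross-section. The boxy cross-section exponent gives the
# crest a broad flat band; a narrow Gaussian dent on the lower face is
# the high-curvature S notch. Returns n x 3 coordinates for paired
# (u, v) vectors.
.phantom_surface <- function(u, v, spec, bumps) {
  size <- spec$size_mm
  a <- 0.475 * size; b <- 0.275 * size; c3 <- 0.085 * size
  e2 <- 0.7
  su <- sin(u)
  P <- cbind(a * cos(u), b * su * .spow(cos(v), e2), c3 * su * .spow(sin(v), e2))
  # cross-section radial direction (displacement direction for surface
  # features; degenerate only at the tips, which carry no features)
  nrm <- cbind(0, P[, 2] / b, P[, 3] / c3)
  nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-12)
  # crest texture: Gaussian bumps on the featured half of the band
  amp <- 0.010 * size * (1 - spec$crest_homogeneity)
  if (amp > 0 && nrow(bumps) > 0) {
    h <- rep(0, length(u))
    for (k in seq_len(nrow(bumps))) {
      du <- u - bumps[k, 1]; dv <- v - bumps[k, 2]
      h <- h + bumps[k, 3] * exp(-(du^2 + dv^2) / (2 * bumps[k, 4]^2))
    }
    P <- P + amp * h * nrm
  }
  # supra-acetabular notch: narrow deep dent, high local curvature
  us <- 0.62 * pi; vs <- 0.80 * pi
  dn <- exp(-((u - us)^2 + (v - vs)^2) / (2 * (0.045 * pi)^2))
  P - (0.055 * size) * dn * nrm
}

#' Generate the synthetic bone phantom mesh
#'
#' Builds a flattened superellipsoid "blade" (open at the two tips)
#' standing in for the iliac wing: its top ridge carries the broad
#' low-curvature crest band (C region, surface texture amplitude
#' scaling with `1 - crest_homogeneity`, bumps confined to one half so
#' the band has a smooth and a featured side) and its lower face a
#' narrow high-curvature notch (S region). Deterministic for a given
#' spec.
#'
#' @param spec a [phantom_spec()].
#' @return A `triangle_mesh` with attributes `uv` (per-vertex
#'   parameters), `grid_dim`, `region` (per-vertex `"C"`, `"S"` or
#'   `"other"`) and `phantom_spec`.
#' @export
make_phantom_mesh <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$resolution
  u <- seq(0.06 * pi, 0.94 * pi, length.out = n)   # open tips
  v <- seq(-pi, pi, length.out = n + 1L)[-(n + 1L)]  # closed around section
  uv <- cbind(rep(u, times = n), rep(v, each = n))  # u fastest
  bumps <- .phantom_bumps(spec)
  V <- .phantom_surface(uv[, 1], uv[, 2], spec, bumps)
  idx <- function(iu, iv) ((iv - 1L) %% n) * n + iu
  iu <- rep(seq_len(n - 1L), times = n)
  iv <- rep(seq_len(n), each = n - 1L)
  a <- idx(iu, iv); b <- idx(iu + 1L, iv)
  c2 <- idx(iu + 1L, iv + 1L); d <- idx(iu, iv + 1L)
  F <- rbind(cbind(a, b, c2), cbind(a, c2, d))
  mesh <- triangle_mesh(V, F, clean = FALSE)
  region <- rep("other", nrow(V))
  region[abs(uv[, 2]) < 0.15 * pi & uv[, 1] > 0.10 * pi &
           uv[, 1] < 0.90 * pi] <- "C"
  region[sqrt((uv[, 1] - 0.62 * pi)^2 + (uv[, 2] - 0.80 * pi)^2) < 0.12 * pi] <- "S"
  attr(mesh, "uv") <- uv
  attr(mesh, "grid_dim") <- c(n, n)
  attr(mesh, "region") <- region
  attr(mesh, "phantom_spec") <- spec
  mesh
}

# Local surface frame at parametric coordinates (u0, v0): position,
# unit normal and unit tangents along u and v (central differences on
# the deformed surface).
.surface_frame <- function(u0, v0, spec, bumps) {
  h <- 1e-4
  p0 <- .phantom_surface(u0, v0, spec, bumps)
  tu <- (.phantom_surface(u0 + h, v0, spec, bumps) -
           .phantom_surface(u0 - h, v0, spec, bumps)) / (2 * h)
  tv <- (.phantom_surface(u0, v0 + h, spec, bumps) -
           .phantom_surface(u0, v0 - h, spec, bumps)) / (2 * h)
  tu <- tu / sqrt(sum(tu^2)); tv <- tv / sqrt(sum(tv^2))
  nrm <- c(tu[2] * tv[3] - tu[3] * tv[2],
           tu[3] * tv[1] - tu[1] * tv[3],
           tu[1] * tv[2] - tu[2] * tv[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  # orient the normal outward (away from the blade axis)
  if (sum(nrm * c(0, p0[2], p0[3])) < 0) nrm <- -nrm
  list(p = as.numeric(p0), tu = as.numeric(tu), tv = as.numeric(tv), n = nrm)
}

# Texture bump parameters (u centre, v centre, signed height factor,
# width), confined to the featured (x > 0, u < pi/2) half of the crest
# band so the band has a smooth and a featured side.
.phantom_bumps <- function(spec) {
  with_seed(spec$seed, {
    nb <- 14L
    cbind(runif(nb, 0.12 * pi, 0.46 * pi),
          runif(nb, -0.13 * pi, 0.13 * pi),
          runif(nb, 0.5, 1.0) * sample(c(-1, 1), nb, replace = TRUE),
          runif(nb, 0.03, 0.06) * pi)
  })
}

#' Generate the six paired PSI case specifications
#'
#' For each of the six scenarios, one supra-acetabular (S) and one
#' iliac-crest (C) guide: a footprint centre on the surface, a cutting
#' plane transverse to the local surface (through the footprint centre,
#' so it always intersects the bone), and four planned pinhole
#' fiducials offset from the surface. C footprints vary in size and
#' position along the crest: cases 1 and 4 are small guides on the
#' smooth half of the band, cases 3 and 5 large guides on the featured
#' half, mirroring the size/location contrast the region comparison
#' hinges on. S footprints sit at the notch and are smaller than every
#' C footprint.
#'
#' @param phantom mesh from [make_phantom_mesh()].
#' @param seed integer seed for the small per-case jitters.
#' @return List of 6 elements, each `list(case_id, S = case_spec,
#'   C = case_spec)`.
#' @export
make_cases <- function(phantom, seed = 1L) {
  spec <- attr(phantom, "phantom_spec")
  if (is.null(spec)) stop("phantom must come from make_phantom_mesh()")
  bumps <- .phantom_bumps(spec)
  scale <- spec$size_mm / 200
  # C footprint centres along the crest (fraction of the half-length a;
  # x > 0 is the featured half): cases 1 and 4 small guides on the
  # smooth half, 3 and 5 large guides on the featured half.
  xC <- c(-0.70, -0.15, 0.55, -0.50, 0.70, 0.25)
  fpC <- c(30, 45, 60, 32, 58, 45) * scale
  fpS <- c(20, 22, 24, 21, 23, 22) * scale
  uS <- 0.62 * pi; vS <- 0.80 * pi
  jit <- with_seed(seed, matrix(runif(18, -0.01, 0.01) * pi, 6, 3))
  out <- vector("list", 6)
  for (k in 1:6) {
    frC <- .surface_frame(acos(xC[k]) + jit[k, 1], jit[k, 2], spec, bumps)
    frS <- .surface_frame(uS + jit[k, 3], vS + 0.02 * pi * (k - 3.5) / 2.5,
                          spec, bumps)
    out[[k]] <- list(
      case_id = k,
      C = .case_spec(k, "C", fpC[k], frC, phantom, slip_dir = frC$tu),
      S = .case_spec(k, "S", fpS[k], frS, phantom, slip_dir = NULL))
  }
  out
}

# Build one case_spec from a local surface frame: the cutting plane is
# transverse to the bone with normal along the blade tangent (tu), so
# the cut is a local cross-section ring, and the 4 pinholes are
# footprint corners projected to the surface and offset 2.5 mm along
# the local normal (surface curvature makes them non-coplanar).
.case_spec <- function(case_id, region, footprint, frame, phantom, slip_dir) {
  plane <- cutting_plane(frame$p, frame$tu)
  r <- 0.35 * footprint
  corners <- rbind(frame$p + r * frame$tu + r * frame$tv,
                   frame$p + r * frame$tu - r * frame$tv,
                   frame$p - r * frame$tu + r * frame$tv,
                   frame$p - r * frame$tu - r * frame$tv)
  cp <- closest_surface_points(corners, phantom)
  pins <- cp$points + 2.5 * matrix(frame$n, 4, 3, byrow = TRUE)
  structure(list(case_id = case_id, region = region,
                 footprint_size_mm = footprint, plane = plane,
                 pinholes_planned = fiducial_set(pins,
                                                 paste0("ph", 1:4), "bone"),
                 centroid = frame$p,
                 normal = frame$n,
                 slip_dir = slip_dir),
            class = "case_spec")
}

#' @export
print.case_spec <- function(x, ...) {
  cat(sprintf("PSI case %d, region %s: footprint %.0f mm\n",
              x$case_id, x$region, x$footprint_size_mm))
  print(x$plane)
  invisible(x)
}

#' Guide placement noise model
#'
#' Stochastic model of how far a placed guide ends up from its planned
#' pose: a small random rotation about the footprint centroid plus an
#' isotropic random translation, with an optional heavy-tailed
#' tangential slip (freehand placements on the homogeneous crest band
#' can slide along the band with little tactile feedback). A positive
#' soft-tissue thickness inflates the noise.
#'
#' @param method `"freehand"`, `"smartphone"` or `"hololens"`.
#' @param rot_sigma_deg rotation angle scale (half-normal, degrees).
#' @param trans_sigma_mm isotropic translation sigma (mm).
#' @param slip_prob probability of a tangential slip (freehand, C
#'   region only).
#' @param slip_scale_mm slip magnitude scale; the slip length is
#'   `slip_scale_mm * (1 + Exp(1))`.
#' @param tissue_extra_sigma_mm extra noise when the phantom is coated:
#'   added to `trans_sigma_mm` and multiplying `rot_sigma_deg` by
#'   `1 + tissue_extra_sigma_mm`.
#' @return An object of class `placement_model`.
#' @export
placement_model <- function(method = c("freehand", "smartphone", "hololens"),
                            rot_sigma_deg = 1, trans_sigma_mm = 0.5,
                            slip_prob = 0, slip_scale_mm = 8,
                            tissue_extra_sigma_mm = 0.8) {
  method <- match.arg(method)
  if (any(c(rot_sigma_deg, trans_sigma_mm, slip_scale_mm,
            tissue_extra_sigma_mm) < 0))
    stop("all sigmas must be >= 0")
  if (slip_prob < 0 || slip_prob > 1) stop("slip_prob must be in [0, 1]")
  structure(list(method = method, rot_sigma_deg = rot_sigma_deg,
                 trans_sigma_mm = trans_sigma_mm, slip_prob = slip_prob,
                 slip_scale_mm = slip_scale_mm,
                 tissue_extra_sigma_mm = tissue_extra_sigma_mm),
            class = "placement_model")
}

#' Default placement models per guidance method
#'
#' Loose calibrations placing the simulated deviation medians in the
#' same order of magnitude as bench measurements: precise AR guidance
#' (smartphone, HoloLens) versus imprecise, heavy-tailed freehand
#' placement.
#'
#' @return Named list of `placement_model`s.
#' @export
default_placement_models <- function() {
  list(
    freehand = placement_model("freehand", rot_sigma_deg = 2,
                               trans_sigma_mm = 1.5, slip_prob = 0.15,
                               slip_scale_mm = 8),
    smartphone = placement_model("smartphone", rot_sigma_deg = 1,
                                 trans_sigma_mm = 0.5),
    hololens = placement_model("hololens", rot_sigma_deg = 1.1,
                               trans_sigma_mm = 0.55))
}

#' Draw a random guide placement perturbation
#'
#' Samples a ground-truth placement error for one trial: rotation of
#' half-normal angle about a uniformly random axis through the footprint
#' centroid, plus an isotropic Gaussian translation; with probability
#' `slip_prob` (freehand method, C region only) an additional large
#' tangential slide along the crest's homogeneous direction, producing
#' the heavy upper tail of freehand deviations. Uses the current RNG
#' stream.
#'
#' @param case a `case_spec`.
#' @param model a `placement_model`.
#' @param tissue_thickness_mm soft-tissue analog thickness (0 disables
#'   the tissue inflation).
#' @return A `rigid_transform` (the true planned-to-actual motion).
#' @export
simulate_placement <- function(case, model, tissue_thickness_mm = 0) {
  stopifnot(inherits(case, "case_spec"), inherits(model, "placement_model"))
  tissue <- tissue_thickness_mm > 0
  rot_eff <- model$rot_sigma_deg *
    (1 + if (tissue) model$tissue_extra_sigma_mm else 0)
  trans_eff <- model$trans_sigma_mm +
    (if (tissue) model$tissue_extra_sigma_mm else 0)
  ang <- abs(rnorm(1, 0, max(rot_eff, 1e-12)))
  if (rot_eff == 0) ang <- 0
  ax <- rnorm(3)
  R <- if (ang > 0) rotation_about_axis(ax, ang) else diag(3)
  tr <- rnorm(3, 0, trans_eff)
  if (model$method == "freehand" && identical(case$region, "C") &&
      !is.null(case$slip_dir) && runif(1) < model$slip_prob) {
    tr <- tr + case$slip_dir * model$slip_scale_mm * (1 + rexp(1)) *
      sample(c(-1, 1), 1)
  }
  cen <- case$centroid
  rigid_transform(R, tr + cen - as.numeric(R %*% cen))
}

#' Simulate tracked pointer measurement of the pinholes
#'
#' Applies the (true) placement motion to the planned pinholes and adds
#' isotropic Gaussian pointer noise. Uses the current RNG stream.
#'
#' @param case a `case_spec`.
#' @param placement the true placement `rigid_transform`.
#' @param pointer_sigma_mm pointer localisation sigma (default 0.2 mm).
#' @return A `fiducial_set` of measured pinholes in the bone frame.
#' @export
simulate_pinhole_measurement <- function(case, placement,
                                         pointer_sigma_mm = 0.2) {
  stopifnot(inherits(case, "case_spec"), inherits(placement, "rigid_transform"),
            pointer_sigma_mm >= 0)
  m <- apply_transform(placement, case$pinholes_planned$points)
  m <- m + matrix(rnorm(12, 0, pointer_sigma_mm), 4, 3)
  fiducial_set(m, case$pinholes_planned$labels, frame = "bone")
}
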