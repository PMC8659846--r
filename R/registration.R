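# Rigid registration: paired-point (Horn/Kabsch) least squares, ICP
# surface refinement, and the planned-to-actual PSI transform.

registration_result <- function(transform, residuals, iterations = 0L,
                                converged = TRUE, rms_history = NULL) {
  structure(list(transform = transform,
                 rms_residual = sqrt(mean(residuals^2)),
                 max_residual = max(residuals),
                 iterations = as.integer(iterations),
                 converged = isTRUE(converged),
                 rms_history = rms_history),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("Rigid registration result\n")
  cat(sprintf("  rms residual: %.6f mm   max residual: %.6f mm\n",
              x$rms_residual, x$max_residual))
  cat(sprintf("  iterations: %d   converged: %s\n", x$iterations, x$converged))
  print(x$transform)
  invisible(x)
}

.as_points <- function(x) {
  if (inherits(x, "fiducial_set")) x$points
  else if (is.null(dim(x))) matrix(as.numeric(x), 1, 3)
  else as.matrix(x)
}

#' Paired-point rigid registration (Horn/Kabsch)
#'
#' Closed-form least-squares rigid transform mapping `moving` onto
#' `fixed`, minimising \eqn{\sum_i \|R m_i + t - f_i\|^2} via the SVD of
#' the cross-covariance with determinant correction, so reflections are
#' never returned. Correspondence is by position: the i-th moving point
#' is paired with the i-th fixed point. When both inputs are labeled
#' `fiducial_set`s, the fixed set is first reordered to match the moving
#' labels. The RMS residual is the fiducial registration error (FRE).
#'
#' @param moving,fixed corresponding point sets (`fiducial_set` or
#'   n x 3 matrices), n >= 3, not collinear.
#' @return A `registration_result` whose `transform` maps moving to
#'   fixed.
#' @export
paired_point_registration <- function(moving, fixed) {
  if (inherits(moving, "fiducial_set") && inherits(fixed, "fiducial_set")) {
    if (!setequal(moving$labels, fixed$labels))
      stop("moving and fixed fiducial labels do not match")
    fixed <- fiducial_set(fixed$points[match(moving$labels, fixed$labels), ,
                                       drop = FALSE],
                          moving$labels, frame = fixed$frame)
  }
  M <- .as_points(moving); Fx <- .as_points(fixed)
  if (nrow(M) != nrow(Fx)) stop("point sets must have equal size")
  if (nrow(M) < 3L)
    stop("paired-point registration needs at least 3 point pairs")
  mc <- colMeans(M); fc <- colMeans(Fx)
  M0 <- sweep(M, 2, mc); F0 <- sweep(Fx, 2, fc)
  sv <- svd(M0)
  if (sv$d[2] <= max(sv$d[1], 1) * 1e-10)
    stop("degenerate (collinear) point configuration")
  H <- crossprod(M0, F0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- as.numeric(fc - R %*% mc)
  tr <- rigid_transform(R, t)
  res <- sqrt(rowSums((apply_transform(tr, M) - Fx)^2))
  registration_result(tr, res)
}

#' Iterative closest point surface refinement
#'
#' Refines an initial rigid pose of a tracked point set against a bone
#' surface mesh by alternating (a) true point-to-triangle closest-point
#' correspondence and (b) a paired-point least-squares update fitted to
#' the original points, which guarantees the RMS point-to-surface
#' residual never increases across iterations.
#'
#' @param points surface sample points (`fiducial_set` or n x 3 matrix),
#'   n >= 3, in the frame `init` maps from (e.g. tracker).
#' @param mesh the bone `triangle_mesh`.
#' @param init initial `rigid_transform` (e.g. from
#'   [paired_point_registration()] on landmarks).
#' @param max_iter maximum iterations (default 50).
#' @param tol stop when the RMS change falls below this (mm, default
#'   1e-6).
#' @return A `registration_result`; `rms_residual` is the final RMS
#'   point-to-surface distance, `rms_history` the per-iteration RMS, and
#'   `converged` is `TRUE` when the tolerance (rather than the iteration
#'   cap) fired.
#' @export
icp_refine <- function(points, mesh, init = identity_transform(),
                       max_iter = 50L, tol = 1e-6) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(init, "rigid_transform"))
  P <- .as_points(points)
  if (nrow(P) < 3L) stop("ICP needs at least 3 points")
  tr <- init
  cp <- closest_surface_points(apply_transform(tr, P), mesh)
  rms <- sqrt(mean(cp$distance^2))
  hist <- rms
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    tr_new <- paired_point_registration(P, cp$points)$transform
    cp <- closest_surface_points(apply_transform(tr_new, P), mesh)
    rms_new <- sqrt(mean(cp$distance^2))
    tr <- tr_new
    hist <- c(hist, rms_new)
    if (abs(rms - rms_new) < tol) {
      converged <- TRUE
      rms <- rms_new
      break
    }
    rms <- rms_new
  }
  registration_result(tr, cp$distance, iterations = it, converged = converged,
                      rms_history = hist)
}

#' Planned-to-actual PSI transform from pinhole fiducials
#'
#' Estimates the rigid transform carrying a patient-specific instrument
#' from its planned pose on the bone to the pose actually achieved, from
#' the four pinhole fiducials present in every guide. Both sets must be
#' expressed in the bone frame (tracked measurements are first mapped
#' through the bone registration) and are matched by label.
#'
#' @param planned_pinholes planned pinhole `fiducial_set` (exactly 4).
#' @param measured_pinholes measured pinhole `fiducial_set` (exactly 4,
#'   same labels).
#' @return A `registration_result` whose `transform` is the
#'   planned-to-actual guide motion.
#' @export
plan_to_real <- function(planned_pinholes, measured_pinholes) {
  stopifnot(inherits(planned_pinholes, "fiducial_set"),
            inherits(measured_pinholes, "fiducial_set"))
  if (nrow(planned_pinholes$points) != 4L || nrow(measured_pinholes$points) != 4L)
    stop("the guide protocol uses exactly 4 pinholes per PSI")
  if (!setequal(planned_pinholes$labels, measured_pinholes$labels))
    stop("pinhole labels do not match between planned and measured sets")
  paired_point_registration(planned_pinholes, measured_pinholes)
}
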