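#' Proper rigid transform (rotation + translation)
#'
#' Constructs a rigid motion acting on column points as `p' = R p + t`.
#' All coordinates are in millimetres in a right-handed frame, the
#' convention of clinical CT data. The rotation must be orthonormal with
#' determinant +1; reflections are rejected.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation vector (mm).
#' @return An object of class `rigid_transform` with elements `rotation`
#'   and `translation`.
#' @examples
#' T1 <- rigid_transform(rotation_about_axis(c(0, 0, 1), 90), c(1, 2, 3))
#' apply_transform(T1, c(1, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  if (!identical(dim(rotation), c(3L, 3L)))
    stop("rotation must be a 3x3 matrix")
  if (length(translation) != 3L || anyNA(translation))
    stop("translation must be a numeric 3-vector")
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-7)
    stop(sprintf("rotation is not orthonormal (max |R'R - I| = %.2e)", err))
  if (det(rotation) < 0)
    stop("rotation has determinant -1 (reflection); not a proper rigid motion")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Identity rigid transform
#' @return A `rigid_transform` leaving every point fixed.
#' @export
identity_transform <- function() rigid_transform()

#' Rotation matrix about an axis
#'
#' Rodrigues' formula for the rotation of `angle_deg` degrees about the
#' (not necessarily unit) axis, right-hand rule.
#'
#' @param axis length-3 axis vector.
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  a <- as.numeric(axis)
  n <- sqrt(sum(a^2))
  if (n < 1e-12) stop("axis has zero length")
  a <- a / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid transform to points
#'
#' @param transform a `rigid_transform`.
#' @param points an n x 3 matrix of points, or a single length-3 vector.
#' @return Transformed points with the same shape as the input.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  vec <- is.null(dim(points))
  p <- if (vec) matrix(as.numeric(points), 1, 3) else as.matrix(points)
  if (ncol(p) != 3L) stop("points must be n x 3")
  out <- p %*% t(transform$rotation)
  out <- sweep(out, 2, transform$translation, "+")
  if (vec) as.numeric(out) else out
}

#' Compose two rigid transforms
#'
#' Returns the transform applying `first` and then `second`:
#' `compose_transform(second, first)(p) = second(first(p))`.
#'
#' @param second,first `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transform <- function(second, first) {
  stopifnot(inherits(second, "rigid_transform"), inherits(first, "rigid_transform"))
  rigid_transform(second$rotation %*% first$rotation,
                  as.numeric(second$rotation %*% first$translation) + second$translation)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return The inverse `rigid_transform`, with
#'   `compose_transform(invert_transform(T), T)` the identity.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  Rt <- t(transform$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% transform$translation))
}

#' Rotation angle of a rigid transform
#' @param transform a `rigid_transform`.
#' @return Rotation angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  c_ang <- (sum(diag(transform$rotation)) - 1) / 2
  acos(min(1, max(-1, c_ang))) * 180 / pi
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (mm)\n")
  cat(sprintf("  rotation angle: %.4f deg\n", rotation_angle(x)))
  cat(sprintf("  translation:    [%.4f, %.4f, %.4f]  (|t| = %.4f mm)\n",
              x$translation[1], x$translation[2], x$translation[3],
              sqrt(sum(x$translation^2))))
  invisible(x)
}
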