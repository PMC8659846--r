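#' Labeled 3-D fiducial point set
#'
#' Ordered, labeled points (mm): PSI pinholes, registration landmarks,
#' or ICP surface samples, tagged with the frame they are expressed in.
#'
#' @param points n x 3 numeric matrix (mm).
#' @param labels character vector of unique identifiers; defaults to
#'   `"p1"`, `"p2"`, ...
#' @param frame coordinate frame tag, `"bone"` or `"tracker"`.
#' @return An object of class `fiducial_set`.
#' @export
fiducial_set <- function(points, labels = NULL, frame = c("bone", "tracker")) {
  frame <- match.arg(frame)
  P <- if (is.null(dim(points))) matrix(as.numeric(points), 1, 3) else unname(as.matrix(points))
  storage.mode(P) <- "double"
  if (ncol(P) != 3L || anyNA(P)) stop("points must be a numeric n x 3 matrix")
  if (is.null(labels)) labels <- paste0("p", seq_len(nrow(P)))
  labels <- as.character(labels)
  if (length(labels) != nrow(P)) stop("labels and points lengths differ")
  if (anyDuplicated(labels)) stop("labels must be unique")
  structure(list(labels = labels, points = P, frame = frame),
            class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf("Fiducial set: %d points in %s frame\n", nrow(x$points), x$frame))
  df <- data.frame(label = x$labels, x = x$points[, 1], y = x$points[, 2],
                   z = x$points[, 3])
  print(df, row.names = FALSE)
  invisible(x)
}

#' Planned osteotomy cutting plane
#'
#' A plane given by a point on it and its unit normal, both in the bone
#' frame (mm).
#'
#' @param origin length-3 point on the plane (mm).
#' @param normal length-3 normal vector; normalised on construction.
#' @return An object of class `cutting_plane`.
#' @export
cutting_plane <- function(origin, normal) {
  origin <- as.numeric(origin); normal <- as.numeric(normal)
  if (length(origin) != 3L || length(normal) != 3L || anyNA(c(origin, normal)))
    stop("origin and normal must be numeric 3-vectors")
  n <- sqrt(sum(normal^2))
  if (n < 1e-12) stop("normal has zero length")
  structure(list(origin = origin, normal = normal / n), class = "cutting_plane")
}

#' Transform a cutting plane by a rigid motion
#'
#' The transformed plane has origin `R o + t` and normal `R n`; this is
#' how an estimated planned-to-actual guide transform is applied to a
#' planned osteotomy plane.
#'
#' @param plane a `cutting_plane`.
#' @param transform a `rigid_transform`.
#' @return The transformed `cutting_plane`.
#' @export
transform_plane <- function(plane, transform) {
  stopifnot(inherits(plane, "cutting_plane"), inherits(transform, "rigid_transform"))
  cutting_plane(apply_transform(transform, plane$origin),
                as.numeric(transform$rotation %*% plane$normal))
}

#' @export
print.cutting_plane <- function(x, ...) {
  cat(sprintf("Cutting plane: origin [%.2f, %.2f, %.2f] mm, normal [%.4f, %.4f, %.4f]\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}
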