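# Osteotomy geometry: plane-mesh cross sections and the maximum
# osteotomy deviation (MOD) between planned and achieved cuts.

no_intersection_error <- function(msg) {
  stop(errorCondition(msg, class = c("psiplace_no_intersection", "error",
                                     "condition")))
}

#' Plane-mesh cross section
#'
#' Intersects a cutting plane with a triangle mesh: computes every
#' triangle-edge/plane crossing segment, chains the segments into
#' polylines (all connected components), and resamples each polyline at
#' uniform arc-length spacing so that the resulting point cloud density
#' is independent of the mesh resolution.
#'
#' @param mesh a `triangle_mesh`.
#' @param plane a `cutting_plane` that intersects the mesh.
#' @param spacing arc-length resampling step in mm (default 0.1). Use
#'   `NULL` to return the raw, unchained edge-crossing points.
#' @param component `"all"` (default) keeps every connected component of
#'   the intersection; `"nearest"` keeps only the polyline closest to
#'   the plane origin (useful to restrict the deviation to the cut next
#'   to the guide footprint). Ignored when `spacing` is `NULL`.
#' @return An object of class `cross_section` with elements `points`
#'   (n x 3 matrix), `polylines` (list of k x 3 matrices, before
#'   resampling `NULL` when `spacing` is `NULL`), `closed` (logical per
#'   polyline) and `plane`.
#' @export
intersect_plane_mesh <- function(mesh, plane, spacing = 0.1,
                                 component = c("all", "nearest")) {
  component <- match.arg(component)
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(plane, "cutting_plane"))
  if (!is.null(spacing) && (!is.finite(spacing) || spacing <= 0))
    stop("spacing must be a positive length in mm")
  V <- mesh$vertices; F <- mesh$faces
  d <- as.numeric(V %*% plane$normal) - sum(plane$origin * plane$normal)
  pos <- d >= 0                          # vertices exactly on the plane count as positive
  s <- matrix(pos[F], ncol = 3)
  cross_face <- which(rowSums(s) %in% c(1L, 2L))
  if (length(cross_face) == 0)
    no_intersection_error("cutting plane does not intersect the mesh (off-bone placement)")

  # With the >= 0 sign convention every crossing face has exactly two
  # sign-change edges among (1,2), (2,3), (3,1).
  nc <- length(cross_face)
  edge_pairs <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  P_edge <- vector("list", 3)
  S_edge <- vector("list", 3)
  for (e in 1:3) {
    i <- F[cross_face, edge_pairs[e, 1]]
    j <- F[cross_face, edge_pairs[e, 2]]
    sel <- pos[i] != pos[j]
    P <- matrix(NA_real_, nc, 3)
    if (any(sel)) {
      ti <- d[i[sel]] / (d[i[sel]] - d[j[sel]])
      P[sel, ] <- V[i[sel], , drop = FALSE] +
        ti * (V[j[sel], , drop = FALSE] - V[i[sel], , drop = FALSE])
    }
    P_edge[[e]] <- P
    S_edge[[e]] <- sel
  }
  seg_a <- P_edge[[2]]
  seg_a[S_edge[[1]], ] <- P_edge[[1]][S_edge[[1]], , drop = FALSE]
  seg_b <- P_edge[[2]]
  seg_b[S_edge[[3]], ] <- P_edge[[3]][S_edge[[3]], , drop = FALSE]
  # drop zero-length segments (plane through a vertex)
  keep <- rowSums((seg_a - seg_b)^2) > 1e-20
  seg_a <- seg_a[keep, , drop = FALSE]
  seg_b <- seg_b[keep, , drop = FALSE]
  if (nrow(seg_a) == 0)
    no_intersection_error("cutting plane only touches the mesh at isolated points")

  if (is.null(spacing)) {
    pts <- unique(round(rbind(seg_a, seg_b), 9))
    return(structure(list(points = pts, polylines = NULL, closed = NULL,
                          plane = plane), class = "cross_section"))
  }

  chains <- .chain_segments(seg_a, seg_b)
  if (component == "nearest" && length(chains$lines) > 1) {
    d <- vapply(chains$lines, function(P)
      min(rowSums(sweep(P, 2, plane$origin)^2)), 0)
    keep <- which.min(d)
    chains$lines <- chains$lines[keep]
    chains$closed <- chains$closed[keep]
  }
  res <- lapply(chains$lines, .resample_polyline, spacing = spacing)
  structure(list(points = do.call(rbind, res), polylines = chains$lines,
                 closed = chains$closed, plane = plane),
            class = "cross_section")
}

# Chain crossing segments into polylines by snapping endpoints to a
# 1e-7 mm grid and walking the resulting node graph: open paths first
# (degree-1 ends), then remaining cycles.
.chain_segments <- function(seg_a, seg_b) {
  n <- nrow(seg_a)
  key <- function(P) paste(round(P[, 1], 7), round(P[, 2], 7), round(P[, 3], 7))
  ka <- key(seg_a); kb <- key(seg_b)
  nodes_key <- unique(c(ka, kb))
  coord <- rbind(seg_a, seg_b)[match(nodes_key, c(ka, kb)), , drop = FALSE]
  ia <- match(ka, nodes_key); ib <- match(kb, nodes_key)
  adj <- vector("list", length(nodes_key))      # list of c(seg, other-node)
  for (s in seq_len(n)) {
    adj[[ia[s]]] <- rbind(adj[[ia[s]]], c(s, ib[s]))
    adj[[ib[s]]] <- rbind(adj[[ib[s]]], c(s, ia[s]))
  }
  used <- logical(n)
  deg <- vapply(adj, function(a) if (is.null(a)) 0L else nrow(a), 0L)
  lines <- list(); closed <- logical(0)

  walk <- function(start) {
    path <- start
    node <- start
    repeat {
      nxt <- adj[[node]]
      free <- nxt[!used[nxt[, 1]], , drop = FALSE]
      if (nrow(free) == 0) break
      used[free[1, 1]] <<- TRUE
      node <- free[1, 2]
      path <- c(path, node)
      if (node == start) break
    }
    path
  }
  for (v in which(deg == 1L)) {
    if (all(used[adj[[v]][, 1]])) next
    p <- walk(v)
    lines[[length(lines) + 1]] <- coord[p, , drop = FALSE]
    closed <- c(closed, FALSE)
  }
  repeat {
    rem <- which(!used)
    if (length(rem) == 0) break
    v <- ia[rem[1]]
    p <- walk(v)
    lines[[length(lines) + 1]] <- coord[p, , drop = FALSE]
    closed <- c(closed, p[length(p)] == p[1])
  }
  list(lines = lines, closed = closed)
}

.resample_polyline <- function(P, spacing) {
  if (nrow(P) < 2) return(P)
  seg <- sqrt(rowSums(diff(P)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  if (L < spacing) return(P)
  m <- max(2L, as.integer(ceiling(L / spacing)) + 1L)
  s <- seq(0, L, length.out = m)
  cbind(approx(cum, P[, 1], xout = s)$y,
        approx(cum, P[, 2], xout = s)$y,
        approx(cum, P[, 3], xout = s)$y)
}

#' Total arc length of a cross section
#' @param section a `cross_section` with polylines.
#' @return Total polyline length in mm.
#' @export
section_arc_length <- function(section) {
  stopifnot(inherits(section, "cross_section"))
  if (is.null(section$polylines))
    stop("section was extracted without chaining (spacing = NULL)")
  sum(vapply(section$polylines,
             function(P) sum(sqrt(rowSums(diff(P)^2))), 0))
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("Cross section: %d points", nrow(x$points)))
  if (!is.null(x$polylines))
    cat(sprintf(" in %d polyline(s), total arc length %.2f mm",
                length(x$polylines), section_arc_length(x)))
  cat("\n")
  invisible(x)
}

deviation_report <- function(per_point, region = NA_character_,
                             status = "ok") {
  structure(list(mod = if (status == "ok") max(per_point) else Inf,
                 mean_deviation = if (status == "ok") mean(per_point) else Inf,
                 per_point_distances = per_point,
                 region = region, status = status),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("Osteotomy deviation: OFF-BONE placement (region %s)\n",
                x$region))
    return(invisible(x))
  }
  cat(sprintf("Osteotomy deviation (region %s): MOD = %.3f mm, mean = %.3f mm over %d points\n",
              x$region, x$mod, x$mean_deviation,
              length(x$per_point_distances)))
  invisible(x)
}

#' Maximum osteotomy deviation between two cross sections
#'
#' For every point of the planned cross section, the unsigned Euclidean
#' distance to its closest point on the achieved cross section; the MOD
#' is the maximum of these directed distances. The metric is
#' deliberately asymmetric (planned to actual).
#'
#' @param planned planned `cross_section`.
#' @param actual achieved `cross_section`.
#' @param region optional region tag (`"S"` or `"C"`).
#' @return A `deviation_report` with `mod`, `mean_deviation` and
#'   `per_point_distances` (mm).
#' @export
max_osteotomy_deviation <- function(planned, actual, region = NA_character_) {
  stopifnot(inherits(planned, "cross_section"), inherits(actual, "cross_section"))
  if (nrow(planned$points) < 1 || nrow(actual$points) < 1)
    stop("cross sections must be non-empty")
  d <- cpp_nn_dist(planned$points, actual$points)
  deviation_report(d, region = region)
}

#' Assess a guide placement: planned vs achieved osteotomy
#'
#' Intersects the planned cutting plane with the bone, applies the
#' estimated planned-to-actual transform to the plane (origin `R o + t`,
#' normal `R n`), re-intersects the fixed bone with the transformed
#' plane, and reports the maximum osteotomy deviation between the two
#' sections. If the transformed plane no longer meets the bone, the
#' placement is reported as `off_bone` with `mod = Inf` rather than
#' silently dropped.
#'
#' @param mesh bone `triangle_mesh`.
#' @param plane planned `cutting_plane`.
#' @param plan_to_real estimated planned-to-actual `rigid_transform`.
#' @param spacing cross-section resampling step (mm, default 0.1).
#' @param region optional region tag.
#' @param planned_section optional precomputed planned `cross_section`
#'   (the planned cut does not change across trials of one case).
#' @param component passed to [intersect_plane_mesh()]: score the whole
#'   intersection (default) or only the component nearest the plane
#'   origin.
#' @return A `deviation_report`.
#' @export
assess_placement <- function(mesh, plane, plan_to_real, spacing = 0.1,
                             region = NA_character_,
                             planned_section = NULL,
                             component = c("all", "nearest")) {
  component <- match.arg(component)
  stopifnot(inherits(plan_to_real, "rigid_transform"))
  planned <- planned_section %||%
    intersect_plane_mesh(mesh, plane, spacing, component)
  actual_plane <- transform_plane(plane, plan_to_real)
  actual <- tryCatch(intersect_plane_mesh(mesh, actual_plane, spacing, component),
                     psiplace_no_intersection = function(e) NULL)
  if (is.null(actual))
    return(deviation_report(numeric(0), region = region, status = "off_bone"))
  max_osteotomy_deviation(planned, actual, region = region)
}
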