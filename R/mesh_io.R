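# Mesh, fiducial and plane file I/O.
#
# STL (ASCII and binary little-endian) and ASCII PLY are parsed directly:
# both formats are simple enough that the readers live here, and loading
# always runs the triangle_mesh() cleaning pass (duplicate-vertex merge,
# degenerate-face removal) since STL stores each triangle's vertices
# verbatim.

#' Load a surface mesh from STL or PLY
#'
#' Reads binary or ASCII STL and ASCII PLY files. Coordinates are taken
#' verbatim as millimetres. Degenerate faces are removed and duplicated
#' vertices merged on load.
#'
#' @param path path to a `.stl` or `.ply` file.
#' @return A `triangle_mesh`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") return(.read_ply(path))
  if (ext == "stl") {
    if (.stl_is_ascii(path)) return(.read_stl_ascii(path))
    return(.read_stl_binary(path))
  }
  stop("unsupported mesh format: .", ext, " (expected .stl or .ply)")
}

.stl_is_ascii <- function(path) {
  head <- readBin(path, "raw", n = 512)
  if (length(head) < 6) stop("mesh file is empty or truncated: ", path)
  # keep printable ASCII only; binary STL headers contain arbitrary bytes
  txt <- tolower(rawToChar(head[head >= as.raw(32) & head <= as.raw(126)]))
  startsWith(trimws(txt), "solid") && grepl("facet", txt)
}

.read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("malformed ASCII STL (vertex count not a multiple of 3): ", path)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
  V <- do.call(rbind, nums)
  if (anyNA(V)) stop("malformed ASCII STL (non-numeric vertex): ", path)
  n_tri <- nrow(V) / 3
  F <- matrix(seq_len(3 * n_tri), ncol = 3, byrow = TRUE)
  triangle_mesh(V, F)
}

.read_stl_binary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  n_tri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (length(n_tri) == 0 || n_tri < 1 || sz < 84 + 50 * n_tri)
    stop("truncated or malformed binary STL: ", path)
  rec <- readBin(con, "raw", n = 50 * n_tri)
  if (length(rec) < 50 * n_tri) stop("truncated binary STL: ", path)
  m <- matrix(rec, nrow = 50)
  flo <- readBin(as.vector(m[1:48, ]), "double", size = 4, n = 12 * n_tri,
                 endian = "little")
  tri <- matrix(flo, nrow = 12)           # nx ny nz v1 v2 v3 per column
  V <- matrix(as.vector(tri[4:12, ]), ncol = 3, byrow = TRUE)
  F <- matrix(seq_len(3 * n_tri), ncol = 3, byrow = TRUE)
  triangle_mesh(V, F)
}

.read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("malformed PLY (no end_header): ", path)
  hdr <- tolower(trimws(lines[seq_len(end)]))
  if (!any(grepl("^format\\s+ascii", hdr)))
    stop("only ASCII PLY is supported: ", path)
  nv <- as.integer(sub("^element\\s+vertex\\s+", "", grep("^element\\s+vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("^element\\s+face\\s+", "", grep("^element\\s+face", hdr, value = TRUE)))
  if (length(nv) != 1 || is.na(nv)) stop("malformed PLY header: ", path)
  body <- lines[(end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vt <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  V <- do.call(rbind, lapply(vt, function(x) as.numeric(x[1:3])))
  if (length(nf) != 1 || is.na(nf) || nf < 1) stop("PLY has no faces: ", path)
  ft <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  F <- do.call(rbind, lapply(ft, function(x) {
    k <- as.integer(x[1])
    if (k != 3) stop("only triangular PLY faces are supported")
    as.integer(x[2:4]) + 1L
  }))
  triangle_mesh(V, F)
}

#' Write a surface mesh to STL or PLY
#'
#' @param mesh a `triangle_mesh`.
#' @param path output path ending in `.stl` or `.ply`.
#' @param ascii for STL, write ASCII instead of binary (default binary;
#'   PLY is always ASCII).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, ascii = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  ext <- tolower(tools::file_ext(path))
  V <- mesh$vertices; F <- mesh$faces
  if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(V)),
                 "property float x", "property float y", "property float z",
                 paste("element face", nrow(F)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(apply(V, 1, function(v) paste(format(v, digits = 9), collapse = " ")), con)
    writeLines(apply(F, 1, function(f) paste(c(3L, f - 1L), collapse = " ")), con)
    return(invisible(path))
  }
  if (ext != "stl") stop("unsupported mesh format: .", ext)
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  N <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  N <- N / pmax(sqrt(rowSums(N^2)), 1e-30)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(F))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g", N[i, 1], N[i, 2], N[i, 3]), con)
      writeLines("    outer loop", con)
      for (k in 1:3) {
        v <- V[F[i, k], ]
        writeLines(sprintf("      vertex %.9g %.9g %.9g", v[1], v[2], v[3]), con)
      }
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(F))) {
    writeBin(c(N[i, ], V[F[i, 1], ], V[F[i, 2], ], V[F[i, 3], ]), con,
             size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  invisible(path)
}

#' Read fiducials or cutting planes from CSV
#'
#' Fiducial CSV columns: `label,x,y,z`; plane CSV columns:
#' `label,x,y,z,nx,ny,nz` (origin and normal).
#'
#' @param path CSV path.
#' @param frame frame tag for the returned `fiducial_set`.
#' @return A `fiducial_set`, or a named list of `cutting_plane`s when the
#'   normal columns are present.
#' @export
read_fiducials_csv <- function(path, frame = "bone") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df))) stop("CSV must have columns label,x,y,z")
  if (all(c("nx", "ny", "nz") %in% names(df))) {
    pl <- lapply(seq_len(nrow(df)), function(i)
      cutting_plane(c(df$x[i], df$y[i], df$z[i]), c(df$nx[i], df$ny[i], df$nz[i])))
    names(pl) <- df$label
    return(pl)
  }
  fiducial_set(as.matrix(df[, c("x", "y", "z")]), df$label, frame = frame)
}

#' Write a fiducial set to CSV
#' @param fiducials a `fiducial_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fiducials_csv <- function(fiducials, path) {
  stopifnot(inherits(fiducials, "fiducial_set"))
  df <- data.frame(label = fiducials$labels, x = fiducials$points[, 1],
                   y = fiducials$points[, 2], z = fiducials$points[, 3])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write fiducials as JSON
#'
#' JSON schema: `{"frame": "bone", "fiducials": [{"label": ..., "xyz":
#' [x, y, z]}, ...]}`.
#'
#' @param fiducials a `fiducial_set`.
#' @param path JSON path.
#' @return `read_fiducials_json` returns a `fiducial_set`;
#'   `write_fiducials_json` returns `path` invisibly.
#' @export
write_fiducials_json <- function(fiducials, path) {
  stopifnot(inherits(fiducials, "fiducial_set"))
  obj <- list(frame = fiducials$frame,
              fiducials = lapply(seq_along(fiducials$labels), function(i)
                list(label = fiducials$labels[i],
                     xyz = fiducials$points[i, ])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fiducials_json
#' @export
read_fiducials_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$fiducials)) stop("malformed fiducial JSON: ", path)
  fd <- obj$fiducials
  pts <- if (is.data.frame(fd)) do.call(rbind, fd$xyz) else do.call(rbind, lapply(fd, `[[`, "xyz"))
  labels <- if (is.data.frame(fd)) fd$label else vapply(fd, `[[`, "", "label")
  fiducial_set(pts, labels, frame = obj$frame %||% "bone")
}

#' Write a cross-section point cloud as ASCII PLY
#'
#' @param section a `cross_section`.
#' @param path output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_section_ply <- function(section, path) {
  stopifnot(inherits(section, "cross_section"))
  P <- section$points
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(P)),
               "property float x", "property float y", "property float z",
               "element face 0",
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(P, 1, function(v) paste(format(v, digits = 9), collapse = " ")), con)
  invisible(path)
}
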