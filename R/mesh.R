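#' Triangle mesh in millimetres
#'
#' The unit of exchange for all geometry in cartscan. Vertices are stored as
#' an `n x 3` numeric matrix (mm) and faces as an `m x 3` integer matrix of
#' one-based vertex indices. On construction, duplicate vertices are merged
#' (coordinates equal within `tol`) and degenerate (zero-area) faces dropped,
#' so downstream distance queries never see sliver triangles.
#'
#' @param vertices Numeric matrix `n x 3` of vertex coordinates in mm.
#' @param faces Integer matrix `m x 3` of one-based vertex indices.
#' @param labels Optional per-vertex labels (patch membership), length `n`.
#' @param clean Merge duplicate vertices and drop degenerate faces (default
#'   `TRUE`).
#' @param tol Vertex-merge tolerance in mm.
#' @return An object of class `trimesh` with elements `vertices`, `faces`,
#'   and optionally `labels`.
#' @examples
#' m <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
#' n_vertices(m)
#' @export
trimesh <- function(vertices, faces, labels = NULL, clean = TRUE, tol = 1e-9) {
  vertices <- as_points3(vertices, "vertices")
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (nrow(vertices) < 3L || nrow(faces) < 1L)
    stop_validation("a triangle mesh needs at least 3 vertices and 1 face")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop_validation("face indices out of range")
  if (clean) {
    key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
                 round(vertices[, 3] / tol))
    first <- match(key, key)
    keep <- which(first == seq_along(first))
    remap <- match(first, keep)
    vertices <- vertices[keep, , drop = FALSE]
    if (!is.null(labels)) labels <- labels[keep]
    faces <- matrix(remap[faces], ncol = 3)
    faces <- faces[!degenerate_faces(vertices, faces), , drop = FALSE]
    if (nrow(faces) == 0L)
      stop_validation("mesh is empty after cleaning (all faces degenerate)")
  }
  out <- list(vertices = vertices, faces = faces)
  if (!is.null(labels)) out$labels <- labels
  structure(out, class = "trimesh")
}

degenerate_faces <- function(vertices, faces, area_tol = 1e-12) {
  dup <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- sqrt(rowSums(cr^2))
  dup | area2 / 2 < area_tol
}

#' Point cloud in millimetres
#'
#' @param points Numeric matrix `n x 3` (mm).
#' @return Object of class `point_cloud`.
#' @export
point_cloud <- function(points) {
  points <- as_points3(points, "points")
  structure(list(points = points), class = "point_cloud")
}

# Coerce anything point-like to an n x 3 finite numeric matrix.
as_points3 <- function(x, what = "points") {
  if (inherits(x, "point_cloud")) x <- x$points
  if (inherits(x, "trimesh")) x <- x$vertices
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop_validation(sprintf("%s must be 3D", what))
    x <- matrix(x, ncol = 3)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop_validation(sprintf("%s must have 3 columns", what))
  if (nrow(x) == 0L) stop_validation(sprintf("%s is empty", what))
  if (!all(is.finite(x))) stop_validation(sprintf("%s contains non-finite coordinates", what))
  dimnames(x) <- NULL
  x
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d faces (mm)\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points (mm)\n", nrow(x$points)))
  invisible(x)
}

#' Number of vertices / faces of a mesh
#' @param mesh A `trimesh`.
#' @return Integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' Per-vertex normals (area-weighted average of incident face normals)
#'
#' @param mesh A `trimesh`.
#' @return `n x 3` matrix of unit normals. Orientation follows the face
#'   winding; isolated vertices get a zero vector.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) # length = 2 * area
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    idx <- f[, k]
    for (j in 1:3) {
      acc <- rowsum(fn[, j], idx)
      n[as.integer(rownames(acc)), j] <- n[as.integer(rownames(acc)), j] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  ok <- len > 0
  n[ok, ] <- n[ok, , drop = FALSE] / len[ok]
  n
}

# face unit normals
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  fn / sqrt(rowSums(fn^2))
}
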