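#' Closest points on a mesh surface
#'
#' Exact minimum Euclidean distance from each query point to the surface of a
#' triangle mesh (faces, edges and vertices — not vertices only). This is the
#' primitive behind the closest-point thickness computation and the
#' mesh-deviation metrics.
#'
#' @param points Query points: numeric vector of length 3 or `n x 3` matrix,
#'   or a [point_cloud].
#' @param mesh A [trimesh].
#' @return A list with `distance` (mm), `footpoint` (`n x 3`), and `face`
#'   (one-based index of the triangle attaining the minimum).
#' @export
mesh_closest_points <- function(points, mesh) {
  stopifnot(inherits(mesh, "trimesh"))
  q <- as_points3(points, "query points")
  cpp_mesh_closest(q, mesh$vertices, mesh$faces)
}

#' Nearest-point distance from a single query point to a mesh
#'
#' @param query A 3D point (mm).
#' @param mesh A [trimesh].
#' @return List with scalar `distance` (mm), `footpoint` (length-3), `face`.
#' @examples
#' tri <- trimesh(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)), rbind(c(1, 2, 3)))
#' nearest_point_distance(c(0.5, 0.5, 1), tri)$distance # 1
#' @export
nearest_point_distance <- function(query, mesh) {
  res <- mesh_closest_points(matrix(query, ncol = 3), mesh)
  list(distance = res$distance[1], footpoint = res$footpoint[1, ],
       face = res$face[1])
}
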