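# Synthetic paired-scan phantoms with machine-readable ground truth.
#
# The generators stand in for the wet-lab side of the two-scan design: a
# bone surface scanned once with its cartilage layer and once without.
# Every derived quantity (thickness field, marker centres, frame axes,
# extent landmarks) is recorded analytically so each pipeline stage can be
# checked against truth.

#' Concentric-sphere phantom
#'
#' An icosphere pair: bone of radius `r_bone` and cartilage offset outward
#' by a constant `thickness`. The simplest analytic case: the closest-point
#' thickness equals the offset at every vertex.
#'
#' @param r_bone Bone radius (mm), positive.
#' @param thickness Constant cartilage thickness (mm), non-negative.
#' @param n_subdiv Icosahedron subdivision level (3 gives 1280 faces).
#' @return Object of class `cartilage_phantom` (see
#'   [make_bicondylar_phantom()] for the fields).
#' @export
make_concentric_sphere_phantom <- function(r_bone = 50, thickness = 2,
                                           n_subdiv = 3L) {
  if (r_bone <= 0) stop_validation("r_bone must be positive")
  if (thickness < 0) stop_validation("thickness must be non-negative")
  ico <- icosphere(n_subdiv)
  bone <- trimesh(r_bone * ico$vertices, ico$faces, clean = FALSE)
  cart <- trimesh((r_bone + thickness) * ico$vertices, ico$faces,
                  clean = FALSE)
  structure(list(bone = bone, cartilage = cart,
                 thickness = rep(thickness, n_vertices(cart)),
                 normals = ico$vertices,
                 patches = list(), frame = NULL, extent = NULL,
                 markers = NULL,
                 params = list(kind = "concentric_sphere", r_bone = r_bone,
                               t0 = thickness, a = 0)),
            class = "cartilage_phantom")
}

# unit icosphere by midpoint subdivision of an icosahedron
icosphere <- function(n_subdiv = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(n_subdiv)) {
    edge_key <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      got <- edge_key[[key]]
      if (!is.null(got)) return(got)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      id <- nv + length(newv)
      edge_key[[key]] <- id
      id
    }
    newf <- matrix(0L, 4L * nrow(f), 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[4L * k - 3L, ] <- c(a, ab, ca)
      newf[4L * k - 2L, ] <- c(b, bc, ab)
      newf[4L * k - 1L, ] <- c(c, ca, bc)
      newf[4L * k, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  list(vertices = v, faces = f)
}

# faces of an nu x nv structured grid of vertices (row-major in u)
grid_faces <- function(nu, nv) {
  i <- rep(seq_len(nu - 1L), each = nv - 1L)
  j <- rep(seq_len(nv - 1L), times = nu - 1L)
  a <- (i - 1L) * nv + j
  b <- a + 1L
  c <- a + nv
  d <- c + 1L
  rbind(cbind(a, b, d), cbind(a, d, c))
}

#' Bicondylar distal-femur phantom
#'
#' Emulates the distal femur articular surface: two spherical condylar
#' patches (radius `condyle_radius`, centres separated by
#' `condyle_separation` along ML) swept from anterior-distal to posterior,
#' joined by a trochlear groove surface (a cylinder-like patch, convex in
#' the sagittal plane, with a slight medio-lateral waist so its lowest
#' point is unique at the midline). The cartilage surface is the bone
#' surface offset along the outward normal by a smooth thickness field
#' `t(theta) = t0 + a * cos(theta)`, where `theta` is the polar angle from
#' the distal pole (so cartilage is thickest distally for `a > 0`).
#'
#' World coordinates coincide with the anatomical frame: x = ML
#' (medial to lateral), y = AP (posterior to anterior), z = PD (distal to
#' proximal), origin at the midpoint of the condylar sphere centres.
#'
#' @param condyle_radius Condylar sphere radius (mm).
#' @param condyle_separation Distance between condylar sphere centres (mm).
#' @param t0 Mean cartilage thickness (mm).
#' @param a Amplitude of the thickness variation (mm); `t0 + |a|` must stay
#'   physiological (<= 4 mm) and below the surface curvature radii.
#' @param step_deg Angular mesh resolution (degrees).
#' @return Object of class `cartilage_phantom` with fields `bone`,
#'   `cartilage` ([trimesh]), `thickness` (per cartilage vertex, mm),
#'   `normals` (outward unit normals), `patches` (vertex index sets:
#'   `trochlea`, `posterior_medial`, `posterior_lateral`; plus point clouds
#'   `plateau` and `anterior_ref`), `frame` (truth [anatomical_frame]),
#'   `extent` (truth landmarks: `W`, `L_med`, `L_lat`, extremal points),
#'   `params`.
#' @export
make_bicondylar_phantom <- function(condyle_radius = 25,
                                    condyle_separation = 44,
                                    t0 = 2, a = 0, step_deg = 2.5) {
  if (condyle_radius <= 0 || condyle_separation <= 0)
    stop_validation("condyle_radius and condyle_separation must be positive")
  tmax <- t0 + abs(a)
  tmin <- t0 - abs(a)
  if (tmin < 0) stop_validation("thickness field goes negative (|a| > t0)")
  if (tmax > 4)
    stop_validation("t0 + |a| exceeds 4 mm: not physiological for distal femur cartilage")
  r_troch <- 20
  if (tmax >= min(condyle_radius, r_troch))
    stop_validation("offset would self-intersect: thickness exceeds surface curvature radius")
  s <- condyle_separation / 2
  deg <- pi / 180
  th <- seq(-55, 115, by = step_deg) * deg   # polar angle from distal pole
  phm <- seq(-40, 40, by = step_deg) * deg   # ML sweep on each condyle
  thickness_at <- function(theta) t0 + a * cos(theta)

  condyle <- function(cx) {
    g <- expand.grid(ph = phm, th = th) # ph fastest: row-major in th
    dirs <- cbind(sin(g$ph),
                  -cos(g$ph) * sin(g$th),
                  -cos(g$ph) * cos(g$th))
    tt <- thickness_at(g$th)
    list(bone = sweep(condyle_radius * dirs, 2, c(cx, 0, 0), "+"),
         cart = sweep((condyle_radius + tt) * dirs, 2, c(cx, 0, 0), "+"),
         normals = dirs, thickness = tt, theta = g$th, phi = g$ph,
         faces = grid_faces(length(th), length(phm)))
  }
  med <- condyle(-s)
  lat <- condyle(s)

  # trochlear groove: sagittally convex cylinder-like patch, axis along ML,
  # lowest line at alpha = 0, waisted so the unique lowest point is at x = 0
  troch_cy <- 15; troch_cz <- 0; waist <- 1e-4
  al <- seq(-20, 40, by = step_deg) * deg
  xs <- seq(-12, 12, by = 1.5)
  gt <- expand.grid(x = xs, al = al)
  rloc <- r_troch * (1 - waist * gt$x^2)
  tb <- cbind(gt$x, troch_cy + rloc * sin(gt$al), troch_cz - rloc * cos(gt$al))
  tn <- cbind(0, sin(gt$al), -cos(gt$al))
  tt_t <- thickness_at(gt$al)
  tc <- tb + tt_t * tn
  tfaces <- grid_faces(length(al), length(xs))

  off <- c(0, nrow(med$bone), nrow(med$bone) + nrow(lat$bone))
  bone_v <- rbind(med$bone, lat$bone, tb)
  cart_v <- rbind(med$cart, lat$cart, tc)
  faces <- rbind(med$faces,
                 lat$faces + off[2],
                 tfaces + off[3])
  normals <- rbind(med$normals, lat$normals, tn)
  thickness <- c(med$thickness, lat$thickness, tt_t)
  bone <- trimesh(bone_v, faces, clean = FALSE)
  cart <- trimesh(cart_v, faces, clean = FALSE)

  theta_all <- c(med$theta, lat$theta, rep(NA_real_, nrow(tb)))
  posterior_med <- which(seq_len(nrow(bone_v)) <= off[2] &
                           theta_all >= 50 * deg)
  posterior_lat <- which(seq_len(nrow(bone_v)) > off[2] &
                           seq_len(nrow(bone_v)) <= off[3] &
                           theta_all >= 50 * deg)
  trochlea_idx <- seq.int(off[3] + 1L, nrow(bone_v))

  # tibial-side patches used only for frame construction
  plateau <- point_cloud(as.matrix(expand.grid(
    x = seq(-32, -12, by = 4), y = seq(-20, 20, by = 5), z = -35)))
  anterior_ref <- colMeans(tc)

  frame <- anatomical_frame(origin = c(0, 0, 0), axis_ml = c(1, 0, 0),
                            axis_ap = c(0, 1, 0), axis_pd = c(0, 0, 1),
                            side = "right")
  t90 <- thickness_at(pi / 2)
  extent <- list(
    W = max(cart_v[, 1]) - min(cart_v[, 1]),
    trochlear_lowest_point = c(0, troch_cy,
                               troch_cz - r_troch - thickness_at(0)),
    most_posterior_point_medial = c(-s, -(condyle_radius + t90), 0),
    most_posterior_point_lateral = c(s, -(condyle_radius + t90), 0),
    y_trochlea = troch_cy)

  structure(list(bone = bone, cartilage = cart, thickness = thickness,
                 normals = normals,
                 patches = list(trochlea = trochlea_idx,
                                posterior_medial = posterior_med,
                                posterior_lateral = posterior_lat,
                                plateau = plateau,
                                anterior_ref = anterior_ref),
                 frame = frame, extent = extent, markers = NULL,
                 params = list(kind = "bicondylar",
                               condyle_radius = condyle_radius,
                               condyle_separation = condyle_separation,
                               t0 = t0, a = a, step_deg = step_deg,
                               r_troch = r_troch, troch_cy = troch_cy)),
            class = "cartilage_phantom")
}

#' @export
print.cartilage_phantom <- function(x, ...) {
  cat(sprintf("cartilage_phantom (%s): bone %d vertices, cartilage %d vertices\n",
              x$params$kind, n_vertices(x$bone), n_vertices(x$cartilage)))
  cat(sprintf("  thickness field: %.2f to %.2f mm%s\n", min(x$thickness),
              max(x$thickness),
              if (!is.null(x$markers)) sprintf("; %d fiducial markers",
                                               length(x$markers$labels))
              else ""))
  invisible(x)
}

# deterministic quasi-uniform points on a sphere (Fibonacci lattice)
fibonacci_sphere <- function(n, radius = 1, center = c(0, 0, 0)) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  sweep(radius * cbind(cos(theta) * sin(phi), sin(theta) * sin(phi),
                       cos(phi)), 2, center, "+")
}

#' Attach fiducial markers to a phantom
#'
#' Places `n_markers` spherical markers at non-symmetric positions around
#' the phantom (irregular azimuths and heights on a ring, so that
#' distance-matrix correspondence matching is unambiguous) and records
#' their truth centres. Marker surfaces are sampled deterministically
#' (Fibonacci lattice) with `points_per_marker` points each.
#'
#' @param phantom A `cartilage_phantom`.
#' @param n_markers Number of markers, between 3 and 8.
#' @param radius Marker sphere radius (mm).
#' @param ring_radius Distance of marker centres from the origin (mm).
#' @param points_per_marker Surface samples per marker.
#' @return The phantom with a `markers` field: `labels`, `centers`
#'   (truth, one row per marker), `radius`, `clouds` (list of
#'   [point_cloud]).
#' @export
add_markers <- function(phantom, n_markers = 7, radius = 12,
                        ring_radius = 70, points_per_marker = 200L) {
  stopifnot(inherits(phantom, "cartilage_phantom"))
  if (n_markers < 3 || n_markers > 8)
    stop_validation("n_markers must be between 3 and 8")
  az <- c(0, 52, 97, 161, 206, 274, 331, 15)[seq_len(n_markers)] * pi / 180
  zz <- c(12, -26, 31, -6, 22, -31, 2, 40)[seq_len(n_markers)]
  centers <- cbind(ring_radius * cos(az), ring_radius * sin(az), zz)
  labels <- paste0("M", seq_len(n_markers))
  rownames(centers) <- labels
  clouds <- lapply(seq_len(n_markers), function(i)
    point_cloud(fibonacci_sphere(points_per_marker, radius, centers[i, ])))
  names(clouds) <- labels
  phantom$markers <- list(labels = labels, centers = centers,
                          radius = radius, clouds = clouds)
  phantom
}

#' Simulate the paired with/without-cartilage scans
#'
#' Produces the two scans of the two-scan design: the with-cartilage scan
#' in the phantom's own frame (frame A) and the without-cartilage scan in
#' a second frame B obtained by applying `inter_scan_transform` (the
#' unknown specimen repositioning between scans). Independent measurement
#' noise is added to every surface vertex as a Gaussian displacement of SD
#' `sigma` along the local outward normal (a surface-sensing error model;
#' per-vertex RMS displacement equals `sigma`). Marker clouds receive the
#' same treatment with radial normals. Fully reproducible from `seed`.
#'
#' @param phantom A `cartilage_phantom`, typically with markers attached.
#' @param sigma Per-scan surface noise SD (mm); 0.087 mm matches a
#'   high-accuracy laser scanner's repeatability.
#' @param inter_scan_transform A [rigid_transform] from frame A to frame B.
#' @param seed Integer seed; required for reproducibility.
#' @return List with `scan_with` (`mesh`, `markers` cloud list),
#'   `scan_without` (same, transformed into frame B), and `truth`
#'   (`transform`, marker centres in both frames).
#' @export
simulate_two_scans <- function(phantom, sigma = 0.087,
                               inter_scan_transform = rigid_transform(),
                               seed) {
  stopifnot(inherits(phantom, "cartilage_phantom"),
            inherits(inter_scan_transform, "rigid_transform"))
  if (missing(seed) || !is.finite(seed))
    stop_validation("simulate_two_scans requires an integer seed")
  if (sigma < 0) stop_validation("sigma must be non-negative")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  noisy_mesh <- function(mesh, normals) {
    if (sigma > 0)
      mesh$vertices <- mesh$vertices +
        stats::rnorm(nrow(mesh$vertices), 0, sigma) * normals
    mesh
  }
  noisy_cloud <- function(cloud, center) {
    p <- cloud$points
    if (sigma > 0) {
      nrm <- sweep(p, 2, center)
      nrm <- nrm / sqrt(rowSums(nrm^2))
      p <- p + stats::rnorm(nrow(p), 0, sigma) * nrm
    }
    point_cloud(p)
  }

  mk <- phantom$markers
  scan_with <- list(mesh = noisy_mesh(phantom$cartilage, phantom$normals),
                    markers = if (!is.null(mk))
                      lapply(seq_along(mk$clouds), function(i)
                        noisy_cloud(mk$clouds[[i]], mk$centers[i, ])))
  centers_b <- NULL
  mk_b <- NULL
  if (!is.null(mk)) {
    names(scan_with$markers) <- mk$labels
    centers_b <- apply_transform(inter_scan_transform, mk$centers)
    rownames(centers_b) <- mk$labels
    mk_b <- lapply(seq_along(mk$clouds), function(i) {
      cl <- point_cloud(apply_transform(inter_scan_transform,
                                        mk$clouds[[i]]$points))
      noisy_cloud(cl, centers_b[i, ])
    })
    names(mk_b) <- mk$labels
  }
  bone_b <- apply_transform(inter_scan_transform, phantom$bone)
  normals_b <- phantom$normals %*% t(inter_scan_transform$rotation)
  scan_without <- list(mesh = noisy_mesh(bone_b, normals_b), markers = mk_b)

  list(scan_with = scan_with, scan_without = scan_without,
       truth = list(transform = inter_scan_transform,
                    marker_centers_a = if (!is.null(mk)) mk$centers,
                    marker_centers_b = centers_b))
}
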