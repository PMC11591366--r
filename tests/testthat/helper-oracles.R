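# Independent oracles and small fixture builders used across the suite.
# The oracles deliberately use different formulations than the package
# internals (constrained quadratic minimisation instead of the Voronoi
# region walk; Horn's quaternion method instead of Kabsch/SVD; the
# algebraic sphere fit without geometric refinement).

# Brute-force distance from point p to every triangle of (V, F): for each
# face, minimise |A + s e0 + t e1 - p|^2 over the simplex by solving the
# unconstrained 2x2 system and, if infeasible, clamping along each edge.
oracle_mesh_distance <- function(p, V, F) {
  A <- V[F[, 1], , drop = FALSE]
  E0 <- V[F[, 2], , drop = FALSE] - A
  E1 <- V[F[, 3], , drop = FALSE] - A
  D <- sweep(-A, 2, p, "+") # p - A
  a <- rowSums(E0^2); b <- rowSums(E0 * E1); c <- rowSums(E1^2)
  d <- rowSums(E0 * D); e <- rowSums(E1 * D)
  det <- pmax(a * c - b^2, 1e-300)
  s <- (c * d - b * e) / det
  t <- (a * e - b * d) / det
  dist_at <- function(s, t) {
    q <- A + s * E0 + t * E1
    sqrt(rowSums(sweep(q, 2, p)^2))
  }
  clamp01 <- function(x) pmin(1, pmax(0, x))
  cand <- dist_at(s, t)
  cand[!(s >= 0 & t >= 0 & s + t <= 1)] <- Inf
  # edge t = 0: min over s of as^2 - 2ds + |D|^2
  s0 <- clamp01(d / pmax(a, 1e-300))
  c1 <- dist_at(s0, 0)
  # edge s = 0
  t0 <- clamp01(e / pmax(c, 1e-300))
  c2 <- dist_at(0, t0)
  # edge s + t = 1: parametrise s = 1 - u, t = u
  # f(u) = |A + E0 + u (E1 - E0) - p|^2
  E2 <- E1 - E0
  num <- rowSums(E2 * (D - E0))
  u <- clamp01(num / pmax(rowSums(E2^2), 1e-300))
  c3 <- dist_at(1 - u, u)
  min(pmin(cand, c1, c2, c3))
}

# Horn's closed-form absolute orientation (unit quaternion from the largest
# eigenvector of the 4x4 N matrix).
oracle_horn_transform <- function(src, tgt) {
  sc <- colMeans(src); tc <- colMeans(tgt)
  X <- sweep(src, 2, sc); Y <- sweep(tgt, 2, tc)
  S <- crossprod(X, Y)
  N <- rbind(
    c(S[1, 1] + S[2, 2] + S[3, 3], S[2, 3] - S[3, 2], S[3, 1] - S[1, 3], S[1, 2] - S[2, 1]),
    c(S[2, 3] - S[3, 2], S[1, 1] - S[2, 2] - S[3, 3], S[1, 2] + S[2, 1], S[3, 1] + S[1, 3]),
    c(S[3, 1] - S[1, 3], S[1, 2] + S[2, 1], -S[1, 1] + S[2, 2] - S[3, 3], S[2, 3] + S[3, 2]),
    c(S[1, 2] - S[2, 1], S[3, 1] + S[1, 3], S[2, 3] + S[3, 2], -S[1, 1] - S[2, 2] + S[3, 3]))
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- rbind(
    c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2))
  list(rotation = R, translation = tc - as.numeric(R %*% sc))
}

# Algebraic (Coope) sphere fit: linear least squares on
# |p|^2 = 2 p . c + (r^2 - |c|^2).
oracle_algebraic_sphere <- function(p) {
  w <- qr.solve(cbind(2 * p, 1), rowSums(p^2))
  list(center = w[1:3], radius = sqrt(w[4] + sum(w[1:3]^2)))
}

# Uniform random rotation (quaternion method)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2))
}

random_rigid <- function(max_shift = 20) {
  rigid_transform(random_rotation(), stats::runif(3, -max_shift, max_shift))
}

# Single-predicate recomputation of the staged subregion rules, used as the
# membership oracle. Everything is rederived from raw frame coordinates.
oracle_subregion_members <- function(v, trochlea_idx, spec, condyle, flexion,
                                     split = NULL, posterior_cutoff_ap = 0) {
  tl <- trochlea_idx[which.min(v[trochlea_idx, 3])]
  y_t <- v[tl, 2]
  if (is.null(split)) split <- v[tl, 1]
  on_side <- if (condyle == "medial") v[, 1] < split else v[, 1] >= split
  side_idx <- which(on_side)
  mp <- side_idx[which.min(v[side_idx, 2])]
  L <- spec$wb_fraction * (y_t - v[mp, 2])
  W <- max(v[, 1]) - min(v[, 1])
  half_w <- spec$ml_width_fraction * W / 2
  if (flexion == "0deg") {
    lo <- y_t - L * (1 - (1 - spec$ap_band_fraction) / 2)
    hi <- y_t - L * (1 - spec$ap_band_fraction) / 2
    band <- on_side & v[, 2] >= lo & v[, 2] <= hi
    cen_x <- mean(v[band, 1])
    which(band & abs(v[, 1] - cen_x) <= half_w)
  } else {
    len <- spec$ap_band_fraction * L
    band <- on_side & abs(v[, 3] - v[mp, 3]) <= len / 2 &
      v[, 2] <= posterior_cutoff_ap
    cen_x <- mean(v[band, 1])
    which(band & abs(v[, 1] - cen_x) <= half_w)
  }
}

# ---- small meshes -------------------------------------------------------

cube_mesh <- function(edge = 1) {
  v <- as.matrix(expand.grid(x = c(0, edge), y = c(0, edge), z = c(0, edge)))
  dimnames(v) <- NULL
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = 0
    c(5, 6, 8), c(5, 8, 7),   # z = edge
    c(1, 2, 6), c(1, 6, 5),   # y = 0
    c(3, 7, 8), c(3, 8, 4),   # y = edge
    c(1, 5, 7), c(1, 7, 3),   # x = 0
    c(2, 4, 8), c(2, 8, 6))   # x = edge
  trimesh(v, f)
}

plane_patch <- function(n = 5, spacing = 1, z = 0) {
  g <- as.matrix(expand.grid(x = seq_len(n) * spacing,
                             y = seq_len(n) * spacing))
  v <- cbind(g, z)
  dimnames(v) <- NULL
  f <- cartscan:::grid_faces(n, n)
  trimesh(v, f)
}

# jittered icosphere: a "random" closed mesh with controllable face count
random_bumpy_sphere <- function(n_subdiv = 2, r = 10, bump = 0.3) {
  ico <- cartscan:::icosphere(n_subdiv)
  radii <- r + stats::runif(nrow(ico$vertices), -bump, bump)
  trimesh(radii * ico$vertices, ico$faces, clean = FALSE)
}

translate_mesh <- function(mesh, d) {
  mesh$vertices <- sweep(mesh$vertices, 2, d, "+")
  mesh
}

rotation_about_z <- function(deg) {
  th <- deg * pi / 180
  rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
}

# small bicondylar phantom shared by several test files (coarser than the
# default for speed)
test_phantom <- function(t0 = 2, a = 0, step_deg = 5) {
  make_bicondylar_phantom(t0 = t0, a = a, step_deg = step_deg)
}

order_rows <- function(m) order(m[, 1], m[, 2], m[, 3])

load_example_table <- function() {
  utils::read.csv(system.file("extdata", "example_study_thickness.csv",
                              package = "cartscan"))
}
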