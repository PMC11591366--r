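test_that("rigid_transform rejects reflections and non-orthonormal input", {
  expect_error(rigid_transform(diag(c(1, 1, -1))),
               class = "cartscan_validation_error")
  expect_error(rigid_transform(matrix(1, 3, 3)),
               class = "cartscan_validation_error")
  tf <- rigid_transform(rotation_about_z(30), c(1, 2, 3))
  back <- transform_from_matrix(transform_matrix(tf))
  expect_equal(back$rotation, tf$rotation)
  expect_equal(back$translation, tf$translation)
})

test_that("identity correspondences give the identity transform", {
  set.seed(2)
  p <- matrix(stats::runif(18, -30, 30), ncol = 3)
  reg <- estimate_rigid_transform(p, p)
  expect_equal(reg$transform$rotation, diag(3), tolerance = 1e-12)
  expect_equal(reg$transform$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(reg$fre_rms, 0, tolerance = 1e-12)
})

test_that("a known rotation + translation is recovered exactly", {
  set.seed(4)
  p <- matrix(stats::runif(21, -40, 40), ncol = 3)
  R <- rotation_about_z(30)
  t <- c(1, 2, 3)
  q <- sweep(p %*% t(R), 2, t, "+")
  reg <- estimate_rigid_transform(p, q)
  expect_lt(max(abs(reg$transform$rotation - R)), 1e-12)
  expect_lt(max(abs(reg$transform$translation - t)), 1e-12)
  expect_lt(reg$fre_rms, 1e-9)
})

test_that("random proper rigid motions are recovered to machine precision
           and match Horn's quaternion oracle", {
  set.seed(10)
  for (rep in 1:40) {
    p <- matrix(stats::runif(18, -50, 50), ncol = 3)
    tf <- random_rigid()
    q <- apply_transform(tf, p)
    reg <- estimate_rigid_transform(p, q)
    expect_lt(max(abs(reg$transform$rotation - tf$rotation)), 1e-9)
    expect_lt(max(abs(reg$transform$translation - tf$translation)), 1e-9)
    expect_equal(det(reg$transform$rotation), 1, tolerance = 1e-12)
    horn <- oracle_horn_transform(p, q)
    expect_lt(max(abs(reg$transform$rotation - horn$rotation)), 1e-8)
  }
})

test_that("noisy fiducials: FRE in the expected range, small transform error", {
  set.seed(77)
  ang_errs <- replicate(20, {
    centers <- matrix(stats::runif(18, -60, 60), ncol = 3)
    tf <- random_rigid()
    target <- apply_transform(tf, centers) +
      matrix(stats::rnorm(18, 0, 0.05), ncol = 3)
    reg <- estimate_rigid_transform(centers, target)
    expect_gt(reg$fre_rms, 0.02)
    expect_lt(reg$fre_rms, 0.13)
    expect_lt(sqrt(sum((reg$transform$translation - tf$translation)^2)), 0.15)
    horn <- oracle_horn_transform(centers, target)
    expect_lt(max(abs(reg$transform$rotation - horn$rotation)), 1e-8)
    cartscan:::rotation_angle(t(reg$transform$rotation) %*% tf$rotation)
  })
  # 6 markers, 0.05 mm noise, ~60 mm lever arms: typical rotation error a
  # few hundredths of a degree, never large
  expect_lt(stats::median(ang_errs) * 180 / pi, 0.05)
  expect_lt(max(ang_errs) * 180 / pi, 0.2)
})

test_that("degenerate correspondences are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(estimate_rigid_transform(line, line),
               class = "cartscan_geometry_error")
  p <- matrix(stats::runif(9), ncol = 3)
  expect_error(estimate_rigid_transform(p[1:2, ], p[1:2, ]),
               class = "cartscan_validation_error")
})

test_that("transform composition is associative with the registration chain", {
  set.seed(31)
  p <- matrix(stats::runif(24, -30, 30), ncol = 3)
  tf1 <- random_rigid()
  tf2 <- random_rigid()
  a <- p
  b <- apply_transform(tf1, a)
  c <- apply_transform(tf2, b)
  reg_ab <- estimate_rigid_transform(a, b)
  reg_bc <- estimate_rigid_transform(b, c)
  reg_ac <- estimate_rigid_transform(a, c)
  composed <- compose_transforms(reg_bc$transform, reg_ab$transform)
  expect_lt(max(abs(transform_matrix(composed) -
                      transform_matrix(reg_ac$transform))), 1e-9)
  # inverse round trip
  inv <- invert_transform(tf1)
  expect_lt(max(abs(apply_transform(inv, apply_transform(tf1, p)) - p)), 1e-9)
})

make_set <- function(centers, id) {
  fits <- lapply(seq_len(nrow(centers)), function(i)
    structure(list(center = centers[i, ], radius = 12, rms_residual = 0,
                   n_points = 100L, iterations = 1L, converged = TRUE),
              class = "sphere_fit"))
  names(fits) <- rownames(centers)
  marker_set(fits, id)
}

test_that("marker matching by label, by geometry, and ambiguity detection", {
  set.seed(55)
  centers <- matrix(stats::runif(18, -60, 60), ncol = 3)
  rownames(centers) <- paste0("M", 1:6)
  set_a <- make_set(centers, "a")
  # identical labels -> identity pairing
  pair <- match_markers(set_a, make_set(centers, "b"))
  expect_identical(pair$label_a, pair$label_b)

  # shuffled labels, rigidly moved -> original pairing recovered by geometry
  tf <- random_rigid()
  moved <- apply_transform(tf, centers)
  shuffle <- sample(6)
  shuffled <- moved[shuffle, ]
  rownames(shuffled) <- paste0("B", 1:6)
  set_b <- make_set(shuffled, "b")
  pair <- match_markers(set_a, set_b)
  want_b <- paste0("B", match(1:6, shuffle))
  expect_identical(pair$label_b[match(paste0("M", 1:6), pair$label_a)], want_b)

  reg <- register_marker_sets(set_a, set_b)
  expect_lt(reg$fre_rms, 1e-9)
  expect_lt(max(abs(transform_matrix(reg$transform) - transform_matrix(tf))),
            1e-8)

  # symmetric (isosceles) layout is ambiguous
  sym <- rbind(c(-10, 0, 0), c(10, 0, 0), c(0, 15, 0))
  rownames(sym) <- paste0("S", 1:3)
  sym2 <- sym
  rownames(sym2) <- paste0("T", 1:3)
  expect_error(match_markers(make_set(sym, "a"), make_set(sym2, "b")),
               class = "cartscan_ambiguity_error")
})

test_that("propagate_to_cartilage_model applies the without-scan transform", {
  set.seed(6)
  mesh <- random_bumpy_sphere(1)
  reg <- estimate_rigid_transform(diag(3), diag(3))
  expect_equal(propagate_to_cartilage_model(reg, mesh)$vertices,
               mesh$vertices)
  shift <- rigid_transform(diag(3), c(0, 0, 5))
  moved <- propagate_to_cartilage_model(shift, mesh)
  expect_equal(moved$vertices, sweep(mesh$vertices, 2, c(0, 0, 5), "+"))
  tf <- random_rigid()
  round_trip <- propagate_to_cartilage_model(
    invert_transform(tf), propagate_to_cartilage_model(tf, mesh))
  expect_lt(max(abs(round_trip$vertices - mesh$vertices)), 1e-9)
})
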