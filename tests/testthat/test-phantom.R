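test_that("concentric-sphere phantom truth is the constant offset", {
  ph <- make_concentric_sphere_phantom(r_bone = 50, thickness = 2)
  expect_true(all(ph$thickness == 2))
  expect_equal(n_vertices(ph$bone), n_vertices(ph$cartilage))
  # thickness 0 -> coincident surfaces
  ph0 <- make_concentric_sphere_phantom(thickness = 0)
  expect_equal(ph0$bone$vertices, ph0$cartilage$vertices)
  # measured thickness equals truth within mesh tolerance (end to end)
  sub <- structure(list(vertex_indices = seq_len(n_vertices(ph$cartilage)),
                        condyle = "medial", flexion = "0deg",
                        centroid = c(0, 0, 0), bounds = list()),
                   class = "subregion")
  map <- compute_thickness_map(ph$cartilage, ph$bone, sub)
  expect_equal(map$mean, 2, tolerance = 0.01)
})

test_that("bicondylar truth is self-consistent on the condyles", {
  for (a in c(0, 0.5)) {
    ph <- test_phantom(a = a)
    # thickness field equals the point-wise cartilage-to-bone distance on
    # the convex condylar regions clear of the trochleo-condylar blend
    # (where the shells merge, as the anatomy does, the nearest bone point
    # can belong to the neighbouring patch)
    v <- ph$cartilage$vertices
    idx <- unique(c(ph$patches$posterior_medial, ph$patches$posterior_lateral,
                    which(v[, 3] < -20 & abs(v[, 1]) > 13)))
    d <- mesh_closest_points(ph$cartilage$vertices[idx, , drop = FALSE],
                             ph$bone)$distance
    expect_lt(max(abs(d - ph$thickness[idx])), 0.02)
    # offsets never negative, field within its stated range
    expect_true(all(ph$thickness >= 2 - abs(a) - 1e-12))
    expect_true(all(ph$thickness <= 2 + abs(a) + 1e-12))
  }
})

test_that("phantom parameter validation enforces physiology and curvature", {
  expect_error(make_bicondylar_phantom(t0 = 5), class = "cartscan_validation_error")
  expect_error(make_bicondylar_phantom(t0 = 2, a = 3),
               class = "cartscan_validation_error")
  expect_error(make_bicondylar_phantom(condyle_radius = -1),
               class = "cartscan_validation_error")
})

test_that("marker truth and fits agree at zero noise", {
  ph <- add_markers(test_phantom(), n_markers = 7)
  expect_length(ph$markers$clouds, 7L)
  fits <- lapply(ph$markers$clouds, fit_sphere)
  centers <- t(vapply(fits, `[[`, numeric(3), "center"))
  expect_lt(max(abs(centers - ph$markers$centers)), 1e-6)
  expect_lt(max(abs(vapply(fits, `[[`, numeric(1), "radius") - 12)), 1e-6)
  expect_error(add_markers(test_phantom(), n_markers = 2),
               class = "cartscan_validation_error")
})

test_that("same seed gives bit-identical scans; marker truth transforms exactly", {
  ph <- add_markers(test_phantom(), n_markers = 6)
  tf <- rigid_transform(rotation_about_z(25), c(4, -2, 9))
  s1 <- simulate_two_scans(ph, sigma = 0.087, inter_scan_transform = tf, seed = 42)
  s2 <- simulate_two_scans(ph, sigma = 0.087, inter_scan_transform = tf, seed = 42)
  expect_identical(s1$scan_with$mesh$vertices, s2$scan_with$mesh$vertices)
  expect_identical(s1$scan_without$mesh$vertices, s2$scan_without$mesh$vertices)
  s3 <- simulate_two_scans(ph, sigma = 0.087, inter_scan_transform = tf, seed = 43)
  expect_false(identical(s1$scan_with$mesh$vertices, s3$scan_with$mesh$vertices))
  expect_equal(s1$truth$marker_centers_b,
               apply_transform(tf, s1$truth$marker_centers_a),
               ignore_attr = TRUE)
})

test_that("zero noise, identity transform reproduces the phantom exactly", {
  ph <- add_markers(test_phantom(), n_markers = 6)
  s <- simulate_two_scans(ph, sigma = 0, seed = 1)
  expect_equal(s$scan_with$mesh$vertices, ph$cartilage$vertices)
  expect_equal(s$scan_without$mesh$vertices, ph$bone$vertices)
})

test_that("the registration pipeline recovers the inter-scan transform", {
  ph <- add_markers(test_phantom(), n_markers = 7)
  set.seed(303)
  tf <- random_rigid()
  s <- simulate_two_scans(ph, sigma = 0, inter_scan_transform = tf, seed = 2)
  al <- align_scans(s$scan_with, s$scan_without)
  expect_lt(al$registration$fre_rms, 1e-6)
  expect_lt(max(abs(transform_matrix(al$registration$transform) -
                      transform_matrix(tf))), 1e-6)
  # with noise, FRE stays well under the configuration warning level
  s2 <- simulate_two_scans(ph, sigma = 0.087, inter_scan_transform = tf, seed = 3)
  al2 <- align_scans(s2$scan_with, s2$scan_without)
  expect_lt(al2$registration$fre_rms, 0.2)
  expect_gt(al2$registration$fre_rms, 0)
})

test_that("per-vertex normals of the phantom point outward", {
  ph <- test_phantom()
  vn <- vertex_normals(ph$bone)
  agree <- rowSums(vn * ph$normals)
  # away from patch borders the discrete normals align with analytic ones
  expect_gt(stats::median(agree), 0.99)
})
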