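fake_subregion <- function(idx) {
  structure(list(vertex_indices = idx, condyle = "medial", flexion = "0deg",
                 centroid = c(0, 0, 0), bounds = list()),
            class = "subregion")
}

test_that("concentric spheres give a uniform 2 mm thickness map", {
  ph <- make_concentric_sphere_phantom(r_bone = 50, thickness = 2,
                                       n_subdiv = 3)
  sub <- fake_subregion(seq_len(n_vertices(ph$cartilage)))
  map <- compute_thickness_map(ph$cartilage, ph$bone, sub)
  expect_equal(map$mean, 2, tolerance = 0.01)
  # each query sits radially above a bone vertex: the only discretisation
  # error is the small tilt of the adjacent faces
  expect_gt(min(map$thickness), 1.98)
  expect_lt(max(map$thickness), 2.02)
  expect_lt(map$sd, 0.01)
})

test_that("parallel planar patches are separated by exactly 1.5 mm", {
  bone <- plane_patch(8)
  cart <- translate_mesh(plane_patch(8), c(0, 0, 1.5))
  map <- compute_thickness_map(cart, bone,
                               fake_subregion(seq_len(n_vertices(cart))))
  expect_equal(unique(round(map$thickness, 12)), 1.5)
  expect_equal(map$sd, 0)
})

test_that("max_valid flags far points and coverage errors are raised", {
  bone <- plane_patch(8)
  cart <- translate_mesh(plane_patch(8), c(0, 0, 1.5))
  # push a few cartilage vertices far away: they must be excluded
  cart$vertices[1:3, 3] <- 100
  map <- compute_thickness_map(cart, bone,
                               fake_subregion(seq_len(n_vertices(cart))))
  expect_equal(sum(!map$valid), 3L)
  expect_equal(map$mean, 1.5, tolerance = 1e-12)
  expect_equal(map$n_valid, n_vertices(cart) - 3L)
  # fewer than 10 valid points -> coverage error
  expect_error(
    compute_thickness_map(cart, bone, fake_subregion(1:9)),
    class = "cartscan_geometry_error")
})

test_that("thickness maps are invariant under a common rigid transform", {
  set.seed(23)
  ph <- test_phantom()
  ext <- measure_cartilage_extent(ph$cartilage, ph$patches$trochlea)
  sub <- subregion_0deg(ph$cartilage, ext, condyle = "medial")
  base <- compute_thickness_map(ph$cartilage, ph$bone, sub)
  tf <- random_rigid()
  moved <- compute_thickness_map(apply_transform(tf, ph$cartilage),
                                 apply_transform(tf, ph$bone), sub)
  expect_lt(max(abs(base$thickness - moved$thickness)), 1e-9)
})

test_that("subregion_stats recomputes from the per-point list", {
  expect_equal(subregion_stats(c(2, 2, 2))$mean, 2)
  expect_equal(subregion_stats(c(2, 2, 2))$sd, 0)
  s <- subregion_stats(c(1, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(s$sd_rounded, 1.4)
  expect_error(subregion_stats(2), class = "cartscan_validation_error")
  set.seed(25)
  ph <- test_phantom()
  ext <- measure_cartilage_extent(ph$cartilage, ph$patches$trochlea)
  map <- compute_thickness_map(ph$cartilage, ph$bone,
                               subregion_0deg(ph$cartilage, ext,
                                              condyle = "lateral"))
  s <- subregion_stats(map)
  expect_equal(s$mean, mean(map$thickness[map$valid]))
  expect_equal(s$sd, stats::sd(map$thickness[map$valid]))
})

test_that("the example study table reproduces its printed summaries", {
  tab <- load_example_table()
  summ <- summarize_study(tab)
  expect_equal(unname(summ$column_means),
               c(1.9, 2.1, 1.6, 2.1))
  expect_equal(summ$overall_mean, 1.9)
  expect_equal(summ$min_cell$mean_mm, 1.2)
  expect_equal(summ$min_cell$condyle, "medial")
  expect_equal(summ$min_cell$flexion, "90deg")
  expect_equal(summ$min_cell$specimen, "Specimen 3")
  expect_equal(summ$max_cell$mean_mm, 2.8)
  expect_equal(summ$max_cell$condyle, "lateral")
  expect_equal(summ$max_cell$flexion, "0deg")
  # the overall mean is the mean of the (unrounded) column means
  expect_equal(summ$overall_mean_raw, mean(summ$column_means_raw))
})

test_that("summarize_study validates its table and handles a single specimen", {
  one <- data.frame(specimen = "S1",
                    condyle = c("medial", "lateral", "medial", "lateral"),
                    flexion = c("0deg", "0deg", "90deg", "90deg"),
                    mean_mm = 2, sd_mm = 0.1)
  summ <- summarize_study(one)
  expect_true(all(summ$column_means == 2))
  expect_equal(summ$overall_mean, 2)
  expect_error(summarize_study(one[-1, ]),
               class = "cartscan_validation_error")
  expect_error(summarize_study(one[, -4]),
               class = "cartscan_validation_error")
})

test_that("two-scan precision propagation is sqrt(2) exactly", {
  expect_equal(propagate_precision(0.092)$sigma_thickness, sqrt(2) * 0.092)
  expect_equal(round(propagate_precision(0.092)$sigma_thickness, 2), 0.13)
  expect_lte(propagate_precision(0.087)$sigma_thickness, 0.13)
  expect_equal(propagate_precision(0)$sigma_thickness, 0)
  for (s in c(0.01, 0.087, 0.5))
    expect_equal(propagate_precision(s)$sigma_thickness / s, sqrt(2),
                 tolerance = 1e-15)
  pm <- propagate_precision(0.092, reference_thickness = 2)
  expect_equal(pm$relative_error, sqrt(2) * 0.092 / 2)
  expect_error(propagate_precision(-1), class = "cartscan_validation_error")
})
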