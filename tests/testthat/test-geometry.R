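test_that("polygon area matches the triangulation oracle", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(sq), 1)
  tri <- rbind(c(0, 0), c(4, 0), c(0, 3))
  expect_equal(polygon_area(tri), 6)
  expect_equal(polygon_area(tri[3:1, ]), 6)   # orientation invariance
  set.seed(21)
  for (i in 1:50) {
    p <- regular_polygon(sample(5:12, 1), r = runif(1, 0.5, 10),
                         cx = runif(1, -5, 5), cy = runif(1, -5, 5),
                         phase = runif(1, 0, 2))
    expect_equal(polygon_area(p), brute_area(p), tolerance = 1e-12)
  }
  bow <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  expect_error(polygon_area(bow), "self-intersecting")
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1))), "invalid-shape")
})

test_that("longest planar axis equals the all-pairs chord oracle", {
  rect <- rbind(c(0, 0), c(4, 0), c(4, 2), c(0, 2))
  ax <- longest_planar_axis(rect)
  expect_equal(ax$length, sqrt(20))
  expect_equal(ax$orientation_deg %% 180, atan2(2, 4) * 180 / pi,
               tolerance = 1e-9)
  hexa <- regular_polygon(6)
  expect_equal(longest_planar_axis(hexa)$length, 2, tolerance = 1e-12)
  set.seed(22)
  for (i in 1:50) {
    p <- regular_polygon(sample(4:10, 1), r = runif(1, 0.5, 8),
                         phase = runif(1, 0, 2))
    p <- p + matrix(rnorm(length(p), 0, 0.05), ncol = 2)
    ax <- longest_planar_axis(p, validate = FALSE)
    expect_equal(ax$length, brute_longest_chord(p), tolerance = 1e-12)
    expect_gte(ax$orientation_deg, 0)
    expect_lt(ax$orientation_deg, 180)
  }
})

test_that("cell height is a guarded difference", {
  expect_equal(cell_height(7.89, 0), 7.89)
  expect_warning(h0 <- cell_height(5, 5), "degenerate")
  expect_equal(h0, 0)
  expect_error(cell_height(2, 5), "negative")
})

test_that("height_width_ratio divides height by the longest chord", {
  expect_equal(height_width_ratio(10, width = 8), 1.25)
  expect_equal(height_width_ratio(6, width = 6), 1)
  rect <- rbind(c(0, 0), c(4, 0), c(4, 2), c(0, 2))
  expect_equal(height_width_ratio(sqrt(20), polygon = rect), 1)
  expect_error(height_width_ratio(5, width = 0), "width")
})

test_that("elongation nematic: ellipse closed form, equivariance, scale invariance", {
  # 2:1 aspect -> 100 * (4 - 1) / (4 + 1) = 60
  e <- elongation_nematic(ellipse_polygon(2, 1), validate = FALSE)
  expect_equal(e$magnitude, 60, tolerance = 0.5)
  expect_equal(e$axis_deg, 0, tolerance = 1e-6)
  circ <- elongation_nematic(regular_polygon(64), validate = FALSE)
  expect_lt(circ$magnitude, 1e-8)
  rot <- elongation_nematic(rotate_polygon(ellipse_polygon(2, 1), 37),
                            validate = FALSE)
  expect_equal(rot$magnitude, e$magnitude, tolerance = 1e-9)
  expect_equal(rot$axis_deg, 37, tolerance = 1e-6)
  scaled <- elongation_nematic(ellipse_polygon(2, 1) * 3.7, validate = FALSE)
  expect_equal(scaled$magnitude, e$magnitude, tolerance = 1e-9)
})

test_that("polygon classes: honeycomb is all six-sided, Voronoi mode is 6", {
  # hexagonal lattice of cells built directly
  centers <- expand.grid(i = 0:6, j = 0:6)
  cx <- centers$i * 1.5
  cy <- centers$j * sqrt(3) + (centers$i %% 2) * sqrt(3) / 2
  polys <- lapply(seq_along(cx), function(k)
    regular_polygon(6, r = 1, cx = cx[k], cy = cy[k]))
  adj <- polygon_adjacency(polys, tol = 0.05)
  nc <- attr(adj, "neighbor_count")
  # lattice-interior cells (one full ring of neighbors) are all six-sided
  interior <- centers$i %in% 1:5 & centers$j %in% 1:5
  expect_true(all(nc[interior] == 6))
  pcd <- polygon_class_distribution(polys, tol = 0.05)
  expect_equal(pcd$class[which.max(pcd$count)], 6)
  expect_equal(sum(pcd$proportion), 1)
  # relaxed Voronoi field: hexagons dominate
  sim <- generate_field(sim_config(seed = 14, n_divisions = 0))
  pcd2 <- polygon_class_distribution(sim$field)
  expect_equal(pcd2$class[which.max(pcd2$count)], 6)
})

test_that("density is intensive and proliferation is a percentage", {
  sim <- generate_field(sim_config(field_width = 40, field_height = 30,
                                   target_density = 215 / 12,
                                   n_divisions = 5, seed = 31))
  expect_equal(nrow(sim$field$cells), 215)
  expect_equal(cell_density(sim$field, reference_area = 1200), 215)
  # doubling the field at the same density leaves the normalized value alone
  sim2 <- generate_field(sim_config(field_width = 80, field_height = 30,
                                    target_density = 215 / 12,
                                    n_divisions = 5, seed = 31))
  expect_equal(cell_density(sim2$field, 1200), 215, tolerance = 0.01)
  expect_equal(proliferation_rate(sim$field), 100 * 5 / 215)
})

test_that("tissue thickness is area over lateral extent", {
  expect_equal(tissue_thickness(matrix(1, 20, 100), 0.5), 10)
  band <- matrix(1, 20, 100)
  band[1:5, 11:20] <- 0   # notch of 50 px
  expect_equal(tissue_thickness(band, 0.5), (2000 - 50) * 0.25 / 50)
  shifted <- cbind(band[, 51:100], band[, 1:50])
  expect_equal(tissue_thickness(shifted, 0.5), tissue_thickness(band, 0.5))
  expect_error(tissue_thickness(matrix(0, 5, 5), 1), "empty")
})

test_that("axial difference folds to [0, 90]", {
  expect_equal(axial_difference(10, 170), 20)
  expect_equal(axial_difference(0, 90), 90)
  expect_equal(axial_difference(179, 1), 2)
  set.seed(5)
  a <- runif(100, 0, 180); b <- runif(100, 0, 180)
  d <- axial_difference(a, b)
  expect_true(all(d >= 0 & d <= 90))
  expect_equal(d, axial_difference(b, a))
})

test_that("generated geometry recovers configured means", {
  cfg <- sim_config(seed = 71, n_divisions = 0)
  sim <- generate_field(cfg)
  cells <- sim$field$cells
  interior <- !cells$boundary
  sem_h <- sd(cells$height) / sqrt(nrow(cells))
  expect_lt(abs(mean(cells$height) - cfg$height_mean), 2 * sem_h + 1e-9)
  # density and area pipelines agree: mean area ~ 100 / target_density
  expect_lt(abs(mean(cells$area[interior]) - 100 / cfg$target_density) /
              (100 / cfg$target_density), 0.05)
})

test_that("hertwig_alignment relates interphase shape to division axis", {
  shapes <- data.frame(cell_id = c("m1", "m2", "m3"),
                       height = c(5, 10, 8),
                       width = c(10, 5, 8),
                       axis_deg = c(30, 100, 170))
  ev <- data.frame(mother_id = c("m1", "m2", "m3", "m9"),
                   angle_deg = c(5, 85, 40, 10),
                   category = c("planar", "perpendicular", "oblique", "planar"),
                   xy_axis_deg = c(35, 10, 100, 0))
  expect_warning(ha <- hertwig_alignment(ev, shapes), "1 event")
  expect_equal(ha$n_unmatched, 1)
  expect_equal(nrow(ha$per_event), 3)
  expect_equal(ha$per_event$hw_ratio, c(0.5, 2, 1))
  expect_equal(ha$per_event$delta_xy_deg[1], 5)
  expect_equal(unname(ha$hw_by_category["planar"]), 0.5)
  expect_equal(ha$mean_delta_xy_planar, 5)
})
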