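test_that("configuration validation rejects degenerate inputs", {
  expect_error(sim_config(field_width = 0), "invalid-config")
  expect_error(sim_config(target_density = -1), "invalid-config")
  expect_error(sim_config(angle_mixture = c(0.5, 0.5, 0.5)), "invalid-config")
  expect_error(sim_config(fate_given_angle = c(1.2, 0.4, 0.1)), "invalid-config")
  expect_error(sim_config(frame_interval = 0), "invalid-config")
  expect_error(sim_config(polarity_axis = 200), "invalid-config")
  expect_error(sim_config(seed = 2^31), "invalid-config")
  expect_s3_class(sim_config(), "sim_config")
  expect_output(print(sim_config()), "mixture")
})

test_that("identical seeds give byte-identical output", {
  cfg <- sim_config(field_width = 50, field_height = 40, n_divisions = 8,
                    seed = 77)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$field$polygons, s2$field$polygons)
  expect_identical(s1$tracks, s2$tracks)
  expect_identical(s1$edges, s2$edges)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_experiment(sim_config(field_width = 50, field_height = 40,
                                       n_divisions = 8, seed = 78))
  expect_false(identical(s1$tracks$z_um, s3$tracks$z_um))
})

test_that("realized cell count tracks the target density", {
  # the 215-cells-per-1200-um2 field-of-view convention
  cfg <- sim_config(field_width = 40, field_height = 30,
                    target_density = 215 / 12, n_divisions = 0, seed = 1)
  sim <- generate_field(cfg)
  expect_equal(nrow(sim$field$cells), 215)
  counts <- vapply(1:10, function(s) {
    nrow(generate_field(sim_config(field_width = 40, field_height = 30,
                                   target_density = 215 / 12,
                                   n_divisions = 0, seed = s))$field$cells)
  }, numeric(1))
  expect_true(all(abs(counts - 215) <= 22))
  # tessellation is exhaustive: tile areas sum to the field area
  areas <- vapply(sim$field$polygons, polygon_area, numeric(1),
                  validate = FALSE)
  expect_equal(sum(areas), 1200, tolerance = 1e-6)
})

test_that("every cell and division has exactly one ground-truth record", {
  sim <- generate_field(sim_config(field_width = 60, field_height = 45,
                                   n_divisions = 10, seed = 3))
  expect_identical(sim$truth$cells$cell_id, sim$field$cells$cell_id)
  expect_equal(anyDuplicated(sim$truth$divisions$mother_id), 0)
  expect_true(all(sim$truth$divisions$mother_id %in% sim$field$cells$cell_id))
  expect_identical(sim$field$mitotic_ids, sim$truth$divisions$mother_id)
})

test_that("mixture-mode angle sampling respects weights and bins", {
  cfg_planar <- mixture_config(c(1, 0, 0))
  d <- withr::with_seed(4, sample_division_angles(cfg_planar, 500))
  expect_true(all(d$angle_deg >= 0 & d$angle_deg <= 20))
  expect_true(all(d$category == "planar"))
  # binomial oracle: frequencies within 3 SDs of the weights
  w <- c(0.51, 0.29, 0.20)
  d2 <- withr::with_seed(5, sample_division_angles(mixture_config(w), 1e4))
  freq <- as.numeric(table(factor(d2$category,
                                  c("planar", "oblique", "perpendicular")))) / 1e4
  expect_true(all(abs(freq - w) <= 3 * sqrt(w * (1 - w) / 1e4)))
  # sine-weighted within-bin law still lands in the right bins
  cfg_sine <- mixture_config(c(0, 1, 0), within_bin = "sine")
  d3 <- withr::with_seed(6, sample_division_angles(cfg_sine, 400))
  expect_true(all(d3$angle_deg > 20 & d3$angle_deg <= 70))
})

test_that("hertwig-mode sampling follows the 3D long axis", {
  cfg <- sim_config(hertwig_mode = TRUE, hertwig_noise_sd = 0)
  la <- data.frame(elevation_deg = c(0, 90), xy_deg = c(40, 10))
  d <- withr::with_seed(7, sample_division_angles(cfg, long_axes = la))
  expect_equal(d$angle_deg, c(0, 90))
  expect_equal(d$xy_axis_deg, c(40, 10))
  cfgn <- sim_config(hertwig_mode = TRUE, hertwig_noise_sd = 10)
  dn <- withr::with_seed(8, sample_division_angles(
    cfgn, long_axes = data.frame(elevation_deg = rep(0, 2000),
                                 xy_deg = rep(0, 2000))))
  expect_true(all(dn$angle_deg >= 0 & dn$angle_deg <= 90))
  # reflected half-normal around 0: mean ~ sd * sqrt(2/pi)
  expect_equal(mean(dn$angle_deg), 10 * sqrt(2 / pi), tolerance = 0.6)
  expect_error(sample_division_angles(cfgn), "long_axes")
})

test_that("emitted tracks honor lineage, fate windows and the z threshold", {
  cfg <- sim_config(field_width = 60, field_height = 45, n_divisions = 10,
                    z_noise_sd = 0, xy_noise_sd = 0, seed = 9)
  sim <- generate_field(cfg)
  tracks <- emit_tracks(sim$field, sim$truth$divisions, cfg)
  expect_identical(validate_tracks(tracks)$type, character(0))
  w <- 9
  for (j in seq_len(nrow(sim$truth$divisions))) {
    dv <- sim$truth$divisions[j, ]
    mo <- tracks[tracks$cell_id == dv$mother_id, ]
    da <- tracks[tracks$cell_id == dv$daughter_a_id, ]
    db <- tracks[tracks$cell_id == dv$daughter_b_id, ]
    expect_equal(max(mo$frame), dv$division_frame)
    expect_equal(min(da$frame), dv$division_frame + 1)
    expect_equal(min(db$frame), dv$division_frame + 1)
    # separation at the telophase frame equals daughter_separation
    pa <- unlist(da[1, c("x_um", "y_um", "z_um")])
    pb <- unlist(db[1, c("x_um", "y_um", "z_um")])
    expect_equal(sqrt(sum((pa - pb)^2)), cfg$daughter_separation,
                 tolerance = 1e-9)
    win <- dv$division_frame + seq_len(w)
    za <- da$z_um[match(win, da$frame)]
    zb <- db$z_um[match(win, db$frame)]
    if (dv$fate == "asymmetric") {
      # exactly one daughter crosses and stays: up within 3 frames, up at end
      up_a <- za > cfg$basal_threshold
      up_b <- zb > cfg$basal_threshold
      expect_true(xor(all(up_a[3:w]), all(up_b[3:w])))
    } else {
      # basal from the second post-division frame onward
      expect_true(all(za[2:w] < cfg$basal_threshold))
      expect_true(all(zb[2:w] < cfg$basal_threshold))
    }
  }
})

test_that("tracks reject divisions whose fate window does not fit", {
  cfg <- sim_config(field_width = 60, field_height = 45, n_divisions = 2,
                    seed = 10)
  sim <- generate_field(cfg)
  bad <- sim$truth$divisions
  bad$division_frame[1] <- cfg$n_frames - 5L
  expect_error(emit_tracks(sim$field, bad, cfg), "window")
})

test_that("edge intensities carry the configured nematic", {
  # noise-free: per-cell harmonic fit recovers (m/2, phi0) almost exactly
  cfg <- sim_config(field_width = 50, field_height = 40,
                    polarity_magnitude = 0.5, polarity_axis = 30,
                    polarity_axis_noise_sd = 0, edge_noise_sd = 0,
                    n_divisions = 0, seed = 12)
  sim <- generate_field(cfg)
  edges <- emit_edge_intensities(sim$field, cfg)
  pf <- field_polarity(edges, method = "harmonic")
  expect_equal(median(pf$magnitude), 0.25, tolerance = 0.01)
  expect_lt(median(axial_difference(pf$axis_deg, 30)), 1)
  # m = 0: recovered tissue magnitude near zero
  cfg0 <- sim_config(field_width = 50, field_height = 40,
                     polarity_magnitude = 0, polarity_axis_noise_sd = 0,
                     edge_noise_sd = 0, n_divisions = 0, seed = 12)
  sim0 <- generate_field(cfg0)
  tp0 <- tissue_polarity(field_polarity(emit_edge_intensities(sim0$field, cfg0),
                                        method = "harmonic"))
  expect_lt(tp0$magnitude, 0.02)
})
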