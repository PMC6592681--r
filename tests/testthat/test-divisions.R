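test_that("division_angle matches hand trigonometry and handles edges", {
  expect_equal(division_angle(c(0, 0, 0), c(1, 0, 0)), 0)
  expect_equal(division_angle(c(0, 0, 0), c(0, 0, 2)), 90)
  expect_equal(division_angle(c(0, 0, 0), c(3, 0, 4)), asin(4 / 5) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(division_angle(c(0, 0, 0), c(3, 0, 4)), 53.1301023541560,
               tolerance = 1e-10)
  expect_error(division_angle(c(1, 2, 3), c(1, 2, 3)), "degenerate-geometry")
})

test_that("division_angle is symmetric and invariant to rigid in-plane motion", {
  set.seed(10)
  for (i in 1:200) {
    pa <- runif(3, -20, 20); pb <- runif(3, -20, 20)
    th <- division_angle(pa, pb)
    expect_equal(th, division_angle(pb, pa))
    expect_equal(th, trig_angle(pa, pb), tolerance = 1e-9)
    ang <- runif(1, 0, 2 * pi); tr <- c(runif(2, -50, 50), 0)
    rot <- function(p) c(p[1] * cos(ang) - p[2] * sin(ang),
                         p[1] * sin(ang) + p[2] * cos(ang), p[3]) + tr
    expect_equal(th, division_angle(rot(pa), rot(pb)), tolerance = 1e-9)
  }
})

test_that("classify_angle uses inclusive boundaries at 20 and 70 degrees", {
  expect_identical(classify_angle(20), "planar")
  expect_identical(classify_angle(20.001), "oblique")
  expect_identical(classify_angle(70), "oblique")
  expect_identical(classify_angle(70.001), "perpendicular")
  expect_identical(classify_angle(c(0, 45, 90)),
                   c("planar", "oblique", "perpendicular"))
  expect_error(classify_angle(-1), "range")
  expect_error(classify_angle(90.5), "range")
})

test_that("measurement frame is the first daughter co-present frame", {
  mo <- data.frame(frame = 1:11)
  da <- data.frame(frame = 12:20)
  db <- data.frame(frame = 12:20)
  expect_equal(select_measurement_frame(mo, da, db), 12)
  db2 <- data.frame(frame = 13:20)
  expect_equal(select_measurement_frame(mo, da, db2), 13)
  expect_error(select_measurement_frame(mo, da, data.frame(frame = integer())),
               "incomplete-event")
  mo2 <- data.frame(frame = 1:12)
  expect_error(select_measurement_frame(mo2, da, db), "inconsistent-lineage")
})

test_that("fate assignment follows the persistence rule", {
  w <- 9
  # both basal throughout
  t1 <- toy_division_tracks(rep(3, w), rep(3, w))
  expect_identical(assign_fate(t1$a, t1$b, 3, 5.5)$fate, "symmetric")
  # one daughter up from frame 3 onward
  zb <- c(3, 3, rep(10, w - 2))
  t2 <- toy_division_tracks(rep(3, w), zb)
  expect_identical(assign_fate(t2$a, t2$b, 3, 5.5)$fate, "asymmetric")
  # transient single-frame excursion, basal at window end -> symmetric
  z1 <- c(3, 8, rep(3, w - 2))
  t3 <- toy_division_tracks(z1, rep(3, w))
  expect_identical(assign_fate(t3$a, t3$b, 3, 5.5)$fate, "symmetric")
  # two-frame run but basal at the final frame -> symmetric
  z2 <- c(3, 8, 8, rep(3, w - 3))
  t4 <- toy_division_tracks(z2, rep(3, w))
  expect_identical(assign_fate(t4$a, t4$b, 3, 5.5)$fate, "symmetric")
  # suprabasal at the end but only single-frame runs -> symmetric
  z3 <- c(3, 8, 3, 8, 3, 8, 3, 3, 8)
  t5 <- toy_division_tracks(z3, rep(3, w))
  expect_identical(assign_fate(t5$a, t5$b, 3, 5.5)$fate, "symmetric")
  # run of >= 2 including the final frame -> that daughter is suprabasal
  z4 <- c(3, 3, 3, 3, 3, 3, 3, 8, 8)
  t6 <- toy_division_tracks(z4, rep(3, w))
  expect_identical(assign_fate(t6$a, t6$b, 3, 5.5)$fate, "asymmetric")
  # both suprabasal is flagged separately
  t7 <- toy_division_tracks(rep(10, w), rep(10, w))
  expect_identical(assign_fate(t7$a, t7$b, 3, 5.5)$fate, "both_suprabasal")
  # incomplete window -> indeterminate with a reason
  t8 <- toy_division_tracks(rep(3, 5), rep(3, 5))
  ft <- assign_fate(t8$a, t8$b, 3, 5.5)
  expect_identical(ft$fate, "indeterminate")
  expect_match(ft$reason, "missing frames")
})

test_that("angle_fate_table counts categories by fate with row proportions", {
  ev <- data.frame(
    category = c("planar", "planar", "planar", "oblique", "perpendicular",
                 "perpendicular", "oblique"),
    fate = c("symmetric", "symmetric", "asymmetric", "symmetric",
             "asymmetric", "asymmetric", "indeterminate"))
  tab <- angle_fate_table(ev)
  expect_equal(unname(tab$counts["planar", ]), c(2L, 1L))
  expect_equal(unname(tab$counts["perpendicular", ]), c(0L, 2L))
  expect_equal(tab$n_excluded, 1)
  expect_equal(unname(tab$proportions["planar", "symmetric"]), 2 / 3)
  # degenerate inputs
  all_planar <- data.frame(category = rep("planar", 5),
                           fate = rep("symmetric", 5))
  expect_equal(sum(angle_fate_table(all_planar)$counts), 5)
  empty <- angle_fate_table(data.frame(category = character(),
                                       fate = character()))
  expect_true(all(empty$counts == 0))
})

test_that("angular_histogram conserves counts and closes the top bin", {
  h <- angular_histogram(c(5, 15, 85), 10)
  expect_equal(h$count[c(1, 2, 9)], c(1, 1, 1))
  expect_equal(sum(h$count), 3)
  expect_equal(angular_histogram(90, 10)$count[9], 1)
  set.seed(3)
  x <- runif(500, 0, 90)
  h2 <- angular_histogram(x, 15)
  expect_equal(sum(h2$count), 500)
  expect_equal(sum(h2$proportion), 1)
  expect_error(angular_histogram(c(10), 7), "config")
})

test_that("analyze_divisions recovers constructed events end to end", {
  cfg <- sim_config(field_width = 60, field_height = 45, n_divisions = 12,
                    z_noise_sd = 0, xy_noise_sd = 0, seed = 8)
  sim <- generate_field(cfg)
  tracks <- emit_tracks(sim$field, sim$truth$divisions, cfg)
  ev <- analyze_divisions(tracks, basal_threshold = cfg$basal_threshold)
  tru <- sim$truth$divisions
  m <- match(ev$mother_id, tru$mother_id)
  expect_equal(nrow(ev), nrow(tru))
  expect_equal(ev$angle_deg, tru$angle_deg[m], tolerance = 1e-9)
  expect_identical(ev$category, tru$category[m])
  expect_identical(ev$fate, tru$fate[m])
  expect_equal(axial_difference(ev$xy_axis_deg, tru$xy_axis_deg[m]),
               rep(0, nrow(ev)), tolerance = 1e-6)
})

test_that("fate misclassification is monotone in z-noise", {
  err_rate <- function(z_sd, seed) {
    cfg <- sim_config(field_width = 120, field_height = 90, n_divisions = 150,
                      n_frames = 14, z_noise_sd = z_sd, xy_noise_sd = 0,
                      seed = seed)
    sim <- generate_field(cfg)
    tracks <- emit_tracks(sim$field, sim$truth$divisions, cfg)
    ev <- analyze_divisions(tracks, basal_threshold = cfg$basal_threshold)
    m <- match(ev$mother_id, sim$truth$divisions$mother_id)
    mean(ev$fate != sim$truth$divisions$fate[m])
  }
  e <- vapply(c(0, 1.25, 2.5), err_rate, numeric(1), seed = 5)
  expect_equal(e[1], 0)
  expect_false(is.unsorted(e))
})
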