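test_that("anatomy meshes match their analytic surface areas", {
  pl <- synthetic_scene("plane")
  expect_equal(surface_area(make_anatomy(pl)), 100)  # flat patch is exact

  cy <- synthetic_scene("cylinder_limb")
  lateral <- 2 * pi * 40 * 200 / 100
  expect_lt(abs(surface_area(make_anatomy(cy)) - lateral) / lateral, 0.005)

  sp <- synthetic_scene("sphere_torso")
  full <- 4 * pi * 100^2 / 100
  expect_lt(abs(surface_area(make_anatomy(sp)) - full) / full, 0.005)
})

test_that("ground-truth areas are closed-form and mesh-independent", {
  sp <- synthetic_scene("sphere_torso", wound_spec = list(theta = 0.3))
  expect_equal(ground_truth_area_cm2(sp), 2 * pi * 1e4 * (1 - cos(0.3)) / 100)
  cy <- synthetic_scene("cylinder_limb",
                        wound_spec = list(phi_span = pi / 2,
                                          patch_length = 50))
  expect_equal(ground_truth_area_cm2(cy), 40 * (pi / 2) * 50 / 100)
  pl <- synthetic_scene("plane", wound_spec = list(radius = 20))
  expect_equal(ground_truth_area_cm2(pl), pi * 400 / 100)
  # changing resolution never changes the ground truth
  sp2 <- synthetic_scene("sphere_torso", wound_spec = list(theta = 0.3),
                         resolution = 3)
  expect_identical(ground_truth_area_cm2(sp2), ground_truth_area_cm2(sp))
})

test_that("extracted ROI areas sit within 1% of closed form at default resolution", {
  for (sc in list(synthetic_scene("sphere_torso"),
                  synthetic_scene("cylinder_limb"),
                  synthetic_scene("plane"))) {
    m <- paint_wound(make_anatomy(sc), sc)
    roi <- roi_from_labels(m)
    gt <- ground_truth_area_cm2(sc)
    expect_lt(abs(roi$area_cm2 - gt) / gt, 0.01)
  }
})

test_that("extraction error shrinks when the edge length halves", {
  err <- function(res) {
    sc <- synthetic_scene("sphere_torso", resolution = res)
    roi <- roi_from_labels(paint_wound(make_anatomy(sc), sc))
    abs(roi$area_cm2 - ground_truth_area_cm2(sc)) /
      ground_truth_area_cm2(sc)
  }
  e_coarse <- err(4)
  e_fine <- err(2)
  expect_lt(e_fine, e_coarse)
  expect_lt(e_fine, 0.01)
})

test_that("a vanishing cap paints an empty or negligible label set", {
  sc <- synthetic_scene("sphere_torso", wound_spec = list(theta = 0),
                        resolution = 2)
  m <- paint_wound(make_anatomy(sc), sc)
  expect_equal(ground_truth_area_cm2(sc), 0)
  expect_lte(sum(m$labels), 1L)  # at most the pole vertex, never a face
})

test_that("scene generation is bit-identical for identical scene and seed", {
  sc <- small_limb_scene()
  traj <- trajectory_spec("exponential", a0_cm2 = 15, rate = 0.1,
                          scan_days = c(1, 5, 9), noise_sigma_mm = 0.1)
  s1 <- generate_series(sc, traj)
  s2 <- generate_series(sc, traj)
  for (i in seq_len(nrow(s1))) {
    expect_identical(s1$mesh[[i]]$vertices, s2$mesh[[i]]$vertices)
  }
  # a different seed changes the jittered vertices
  sc2 <- small_limb_scene()
  sc2$seed <- 99L
  s3 <- generate_series(sc2, traj)
  expect_false(identical(s1$mesh[[1]]$vertices, s3$mesh[[1]]$vertices))
})

test_that("scanner noise at 0.1 mm changes extracted areas by less than 1%", {
  sc <- synthetic_scene("cylinder_limb")
  traj0 <- trajectory_spec("exponential", a0_cm2 = 500, rate = 0.1,
                           scan_days = c(1, 4, 8, 15))
  trajn <- trajectory_spec("exponential", a0_cm2 = 500, rate = 0.1,
                           scan_days = c(1, 4, 8, 15),
                           noise_sigma_mm = 0.1)
  a0 <- extract_series_areas(generate_series(sc, traj0))
  an <- extract_series_areas(generate_series(sc, trajn))
  expect_true(all(abs(an$measured_area_cm2 - a0$measured_area_cm2) /
                    a0$measured_area_cm2 < 0.01))
})

test_that("exponential series follow A0 * exp(-k (d - d1)) and are recovered", {
  sc <- synthetic_scene("cylinder_limb")
  traj <- trajectory_spec("exponential", a0_cm2 = 500, rate = 0.1,
                          scan_days = c(1, 4, 8, 15))
  ser <- generate_series(sc, traj)
  expect_equal(ser$true_area_cm2, 500 * exp(-0.1 * (ser$day - 1)))
  ex <- extract_series_areas(ser)
  expect_true(all(abs(ex$measured_area_cm2 - ex$true_area_cm2) /
                    ex$true_area_cm2 < 0.01))
  fit <- fit_exponential_decay(ex$day, ex$measured_area_cm2)
  expect_lt(abs(fit$k_per_day - 0.1) / 0.1, 0.05)

  # end-to-end percent reduction within 2 percentage points of prescription
  pr_true <- percent_reduction(ex$true_area_cm2[1], ex$true_area_cm2)
  pr_meas <- percent_reduction(ex$measured_area_cm2[1],
                               ex$measured_area_cm2)
  expect_true(all(abs(pr_true - pr_meas) < 2))
})

test_that("a linear trajectory reaching zero ends with no wound label", {
  sc <- small_limb_scene()
  traj <- trajectory_spec("linear", a0_cm2 = 10, rate = 1,
                          scan_days = c(1, 6, 11))
  ser <- generate_series(sc, traj)
  expect_equal(ser$true_area_cm2[3], 0)
  expect_equal(sum(ser$mesh[[3]]$labels), 0L)
  ex <- extract_series_areas(ser)
  expect_equal(ex$measured_area_cm2[3], 0)
})

test_that("impossible geometry and unrepresentable trajectories error", {
  expect_error(
    synthetic_scene("plane", anatomy_params = list(width = 30, height = 30),
                    wound_spec = list(radius = 20)),
    class = "bp_error_geometry")
  expect_error(
    synthetic_scene("sphere_torso", wound_spec = list(theta = pi)),
    class = "bp_error_geometry")
  # wound feature smaller than the meshing resolution
  sc <- synthetic_scene("plane", wound_spec = list(radius = 5),
                        resolution = 2)
  traj <- trajectory_spec("exponential", a0_cm2 = pi * 25 / 100, rate = 1,
                          scan_days = c(1, 10))
  expect_error(generate_series(sc, traj), class = "bp_error_resolution")
  expect_error(
    make_anatomy(synthetic_scene("plane", wound_spec = list(radius = 0.5),
                                 resolution = 2)),
    class = "bp_error_resolution")
  expect_error(trajectory_spec("linear", a0_cm2 = 5, rate = 1,
                               scan_days = c(1, 20)),
               class = "bp_error_input")
  expect_error(trajectory_spec("linear", a0_cm2 = 5, rate = 1,
                               scan_days = c(3, 2)),
               class = "bp_error_input")
})
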