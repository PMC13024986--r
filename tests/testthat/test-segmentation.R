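test_that("label selection saturates, errors on empty, and orders rules", {
  m <- small_painted_limb()
  all1 <- m
  all1$labels <- rep(1L, n_vertices(m))
  expect_equal(length(roi_from_labels(all1)$face_indices), n_faces(m))

  none <- m
  none$labels <- rep(0L, n_vertices(m))
  expect_error(roi_from_labels(none), class = "bp_error_empty_selection")

  unlabelled <- m
  unlabelled$labels <- NULL
  expect_error(roi_from_labels(unlabelled), class = "bp_error_config")

  strict <- roi_from_labels(m, inclusion_rule = "all_vertices")
  loose <- roi_from_labels(m, inclusion_rule = "majority")
  expect_true(all(strict$face_indices %in% loose$face_indices))
})

test_that("selection area converges to the analytic cap area with resolution", {
  errs <- vapply(c(4, 2), function(res) {
    sc <- synthetic_scene("sphere_torso",
                          anatomy_params = list(radius = 60),
                          wound_spec = list(theta = 0.4),
                          resolution = res)
    m <- paint_wound(make_anatomy(sc), sc)
    roi <- roi_from_labels(m)
    abs(roi$area_cm2 - ground_truth_area_cm2(sc)) / ground_truth_area_cm2(sc)
  }, 0)
  expect_lt(errs[2], 0.01)
  expect_lt(errs[2], errs[1])
})

test_that("colour rule recovers the painted label set exactly", {
  m <- small_painted_limb()
  # default tones: wound (0.8,0.2,0.2) scores 0.4; skin (0.9,0.75,0.6) -0.45
  roi <- roi_from_color(m, channel_weights = c(1, -1, -1), threshold = 0)
  ref <- roi_from_labels(m)
  expect_identical(roi$face_indices, ref$face_indices)
  expect_identical(roi$labels, m$labels)

  # idempotence: re-selecting from the induced labels reproduces the ROI
  m2 <- m
  m2$labels <- roi$labels
  expect_identical(roi_from_labels(m2)$face_indices, roi$face_indices)
})

test_that("colour rule flags degenerate thresholds", {
  m <- small_painted_limb()
  red <- m
  red$colors <- matrix(rep(c(1, 0, 0), each = n_vertices(m)), ncol = 3)
  expect_warning(
    roi <- roi_from_color(red, c(1, 0, 0), threshold = 0.5),
    class = "bp_warning_degenerate_threshold")
  expect_equal(length(roi$face_indices), n_faces(m))

  expect_error(
    expect_warning(roi_from_color(red, c(1, 0, 0), threshold = 1.0),
                   class = "bp_warning_degenerate_threshold"),
    class = "bp_error_empty_selection")

  nocol <- m
  nocol$colors <- NULL
  expect_error(roi_from_color(nocol), class = "bp_error_config")
})

test_that("two painted patches come back as two edge-connected components", {
  sc <- synthetic_scene("cylinder_limb",
                        anatomy_params = list(radius = 30, length = 120),
                        wound_spec = list(phi_span = pi / 3,
                                          patch_length = 30),
                        resolution = 1)
  m <- paint_wound(make_anatomy(sc), sc)
  # paint a second, smaller patch on the opposite side, bounded by existing
  # grid knots so its polyhedral area has a closed form too
  phiv <- atan2(m$vertices[, 2], m$vertices[, 1])
  zv <- m$vertices[, 3]
  phis <- sort(unique(round(phiv, 12)))
  phi_lo <- phis[which.min(abs(phis - 2))]        # ~115 deg away from patch 1
  phi_hi <- phis[which.min(abs(phis - (2 + pi / 6)))]
  second <- abs(phiv - (phi_lo + phi_hi) / 2) <=
    (phi_hi - phi_lo) / 2 + 1e-9 & zv >= 50 - 1e-9 & zv <= 70 + 1e-9
  m2 <- m
  m2$labels <- pmax(m$labels, as.integer(second))
  truth_small <- 30 * (phi_hi - phi_lo) * 20 / 100  # chordal deficit ~1e-5

  roi <- roi_from_labels(m2)
  comps <- mesh_components(m2, roi$face_indices)
  expect_length(comps, 2L)
  # ordered by descending area; each within 1% of its analytic value
  a <- vapply(comps, function(fs) surface_area(m2, fs), 0)
  expect_true(a[1] > a[2])
  expect_lt(abs(a[1] - ground_truth_area_cm2(sc)) /
              ground_truth_area_cm2(sc), 0.01)
  expect_lt(abs(a[2] - truth_small) / truth_small, 0.01)

  expect_identical(mesh_components(m2, integer(0)), list())
})

test_that("component filtering suppresses speckle and errors when all fail", {
  m <- small_painted_limb()
  roi <- roi_from_labels(m)
  comps <- mesh_components(m, roi$face_indices)
  expect_length(comps, 1L)

  # min area 0 is a no-op union
  all_roi <- filter_components(comps, m, min_area_cm2 = 0)
  expect_identical(all_roi$face_indices, roi$face_indices)

  # add a single-face speckle far from the patch
  outside <- setdiff(seq_len(n_faces(m)), roi$face_indices)[1]
  comps2 <- c(comps, list(outside))
  kept <- filter_components(comps2, m, min_area_cm2 = 0.5)
  expect_identical(kept$face_indices, roi$face_indices)

  expect_error(filter_components(comps, m, min_area_cm2 = 1e6),
               class = "bp_error_empty_selection")
})

test_that("boundary-loop seed fill reproduces the label pathway exactly", {
  sc <- synthetic_scene("plane",
                        anatomy_params = list(width = 60, height = 60),
                        wound_spec = list(radius = 10),
                        resolution = 2)
  m <- paint_wound(make_anatomy(sc), sc)
  ref <- roi_from_labels(m)
  # the wound rim is the mesh ring at exactly the disc radius; order it by
  # polar angle to get the closed boundary polyline
  r <- sqrt(m$vertices[, 1]^2 + m$vertices[, 2]^2)
  ring <- which(abs(r - 10) < 1e-6)
  loop <- ring[order(atan2(m$vertices[ring, 2], m$vertices[ring, 1]))]
  # seed with a face whose vertices are all strictly inside the rim
  inside <- r < 10 - 1e-6
  seed <- which(rowSums(matrix(inside[m$faces], ncol = 3)) == 3L)[1]
  roi <- roi_from_boundary_loop(m, loop, seed_face = seed)
  expect_identical(roi$face_indices, ref$face_indices)
  expect_equal(roi$area_cm2, ref$area_cm2)
  expect_identical(roi$source, "boundary_loop")
})
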