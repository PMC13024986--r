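# expected values marked "recorded" below come from the bundled pilot
# cohort's clinical records; derived expectations were recomputed by hand
# from the recorded per-scan areas

test_that("Du Bois BSA reproduces recorded values and exposes its coefficient", {
  expect_equal(du_bois_bsa(1, 1), 0.007184)
  expect_equal(du_bois_bsa(100, 183), 2.22, tolerance = 0.01)
  expect_equal(du_bois_bsa(100, 190), 2.28, tolerance = 0.01)
  expect_error(du_bois_bsa(0, 180), class = "bp_error_domain")
  expect_error(du_bois_bsa(80, -1), class = "bp_error_domain")
})

test_that("Du Bois BSA is monotone and scales exactly in each argument", {
  w <- c(50, 70, 90, 110)
  h <- c(150, 165, 180, 195)
  expect_true(all(diff(du_bois_bsa(w, 170)) > 0))
  expect_true(all(diff(du_bois_bsa(80, h)) > 0))
  expect_equal(du_bois_bsa(2 * w, 170), du_bois_bsa(w, 170) * 2^0.425)
  expect_equal(du_bois_bsa(w, 2 * 170), du_bois_bsa(w, 170) * 2^0.725)
})

test_that("absolute and percentage reduction match recorded wound rows", {
  expect_equal(absolute_reduction(1502.51, 402.60), 1099.91)
  expect_equal(absolute_reduction(568.36, 43.79), 524.57)
  expect_equal(absolute_reduction(5, 5), 0)
  expect_equal(percent_reduction(329.19, 98.42), 70.10, tolerance = 0.0001)
  expect_equal(percent_reduction(538.18, 509.93), 5.25, tolerance = 0.001)
  expect_equal(percent_reduction(7, 7), 0)
  expect_equal(percent_reduction(7, 0), 100)
  expect_error(percent_reduction(0, 1), class = "bp_error_domain")
})

test_that("percent reduction is scale invariant", {
  set.seed(3)
  for (i in 1:10) {
    a0 <- runif(1, 10, 2000)
    at <- runif(1, 0, a0)
    cc <- runif(1, 0.01, 100)
    expect_equal(percent_reduction(cc * a0, cc * at),
                 percent_reduction(a0, at))
  }
})

test_that("TBSA conversion has the right endpoints and recovers a recorded value", {
  expect_equal(tbsa_percent(0, 2), 0)
  expect_equal(tbsa_percent(1.9 * 1e4, 1.9), 100)
  # P09: sum of recorded baseline areas over five wounds, BSA from (100, 190)
  a0_sum <- 1596.06 + 2137.98 + 629.73 + 2058.89 + 323.56
  expect_equal(round(tbsa_percent(a0_sum, du_bois_bsa(100, 190))), 30)
  expect_error(tbsa_percent(10, 0), class = "bp_error_domain")
})

test_that("delta TBSA matches recorded patient values and is linear", {
  p12 <- list(
    wound_series("P12", "RLL", c(1, 3, 8, 16, 23),
                 c(1502.51, 1175.52, 941.05, 507.83, 402.60)),
    wound_series("P12", "LLL", c(1, 3, 8, 16, 23),
                 c(356.35, 156.60, 119.09, 49.81, 47.77))
  )
  bsa12 <- du_bois_bsa(90, 168)
  expect_equal(delta_tbsa_percent(p12, bsa12), 7.055, tolerance = 0.005)

  p13 <- list(
    wound_series("P13", "Torso", c(1, 4, 9, 11, 37),
                 c(568.36, 439.99, 80.83, 50.93, 43.79)),
    wound_series("P13", "LUL", c(1, 4, 9, 11, 37),
                 c(903.87, 847.21, 722.26, 530.28, 485.35))
  )
  expect_equal(delta_tbsa_percent(p13, du_bois_bsa(106, 165)), 4.464,
               tolerance = 0.005)

  # linearity: equals the sum of per-wound tbsa_percent of the reductions
  per_wound <- sum(vapply(p12, function(s) {
    tbsa_percent(s$baseline$area_cm2 - s$last$area_cm2, bsa12)
  }, 0))
  expect_equal(delta_tbsa_percent(p12, bsa12), per_wound)

  # an unchanged single wound contributes zero
  flat <- wound_series("X", "Torso", c(1, 8), c(50, 50))
  expect_equal(delta_tbsa_percent(list(flat), 2), 0)
  expect_error(delta_tbsa_percent(list(), 2), class = "bp_error_input")
})

test_that("early-phase reduction uses the first follow-up scan", {
  s <- wound_series("P12", "RLL", c(1, 3, 8, 16, 23),
                    c(1502.51, 1175.52, 941.05, 507.83, 402.60))
  expect_equal(early_phase_reduction(s), 21.76, tolerance = 0.01)
  s2 <- wound_series("P06", "RUL", c(1, 3, 11),
                     c(721.13, 260.27, 104.01))
  expect_equal(early_phase_reduction(s2), 63.91, tolerance = 0.01)
  flat <- wound_series("X", "RUL", c(1, 4), c(10, 10))
  expect_equal(early_phase_reduction(flat), 0)
  single <- wound_series("X", "RUL", 1, 10)
  expect_error(early_phase_reduction(single),
               class = "bp_error_insufficient_data")
})

test_that("daily healing rate divides by elapsed days from baseline", {
  s <- wound_series("P04", "RUL", c(1, 3), c(116.73, 94.08))
  expect_equal(daily_healing_rate(s, 1), 11.325)
  s2 <- wound_series("P09", "RLL", c(1, 11), c(2058.89, 1124.86))
  expect_equal(daily_healing_rate(s2), 93.403)
  flat <- wound_series("X", "RUL", c(1, 6), c(10, 10))
  expect_equal(daily_healing_rate(flat), 0)
  expect_error(daily_healing_rate(s, 5), class = "bp_error_input")
  expect_error(wound_series("X", "RUL", c(1, 1), c(5, 4)),
               class = "bp_error_input")
})

test_that("wound_metrics bundles the per-series metrics and flags growth", {
  s <- wound_series("P01", "RLL", c(1, 10, 15), c(329.19, 191.12, 98.42))
  wm <- wound_metrics(s)
  expect_equal(wm$delta_a_cm2, 230.77)
  expect_equal(wm$percent_reduction, 70.10, tolerance = 0.0001)
  expect_false(wm$grew)

  const <- wound_metrics(wound_series("X", "LUL", c(1, 5, 9), c(20, 20, 20)))
  expect_equal(const$delta_a_cm2, 0)
  expect_equal(const$percent_reduction, 0)
  expect_equal(const$early_phase_reduction_pct, 0)
  expect_equal(const$daily_rate_overall_cm2_per_day, 0)

  growing <- wound_metrics(wound_series("X", "LUL", c(1, 5), c(10, 15)))
  expect_lt(growing$delta_a_cm2, 0)
  expect_lt(growing$percent_reduction, 0)
  expect_true(growing$grew)
})

test_that("the data-frame method computes one row per wound", {
  obs <- burn_pilot_cohort()$observations
  wm <- wound_metrics(obs)
  expect_equal(nrow(wm), 43L)
  p01 <- wm[wm$patient_id == "P01" & wm$location == "RLL", ]
  expect_equal(p01$delta_a_cm2, 230.77)
  # percent_reduction never exceeds 100
  expect_true(all(wm$percent_reduction <= 100))
})
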