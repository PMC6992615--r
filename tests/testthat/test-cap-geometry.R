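test_that("cap height inverts the spherical-cap volume fraction", {
  # limits and symmetry
  expect_equal(cap_height_from_fraction(0, 12), 0)
  expect_equal(cap_height_from_fraction(0.5, 12), 12)
  expect_equal(cap_height_from_fraction(1, 12), 24)
  expect_equal(fraction_from_cap_height(20, 10), 1)
  expect_equal(fraction_from_cap_height(10, 10), 0.5)

  # bisection oracle on the cubic h^2 (3R - h) = 4 f R^3
  R <- 12; f <- 0.601
  lo <- 0; hi <- 2 * R
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (mid^2 * (3 * R - mid) < 4 * f * R^3) lo <- mid else hi <- mid
  }
  expect_equal(cap_height_from_fraction(f, R), (lo + hi) / 2, tolerance = 1e-10)
  expect_gt(cap_height_from_fraction(f, R), 13.6)
  expect_lt(cap_height_from_fraction(f, R), 13.7)

  # round trip across the full range, and monotonicity
  f_grid <- seq(0.01, 0.99, by = 0.01)
  h <- cap_height_from_fraction(f_grid, 11.3)
  expect_true(all(diff(h) > 0))
  expect_equal(fraction_from_cap_height(h, 11.3), f_grid, tolerance = 1e-9)

  expect_error(cap_height_from_fraction(1.2, 10), "fill fraction")
  expect_error(cap_height_from_fraction(0.5, -1), "radius")
  expect_error(fraction_from_cap_height(25, 10), "cap height")
})

test_that("meniscus plane is horizontal and holds the cap volume", {
  eye <- eye_model(25.4)
  expect_equal(meniscus_plane(eye, gas_bubble(0.5, eye))$offset_mm, 0)
  expect_equal(meniscus_plane(eye, gas_bubble(1, eye))$offset_mm, -eye$radius)
  b <- gas_bubble(0.6, eye)
  pl <- meniscus_plane(eye, b)
  expect_equal(pl$normal, c(0, 1))
  expect_equal(pl$offset_mm,
               eye$radius - cap_height_from_fraction(0.6, eye$radius))
})

test_that("analytic contact rates match dense arc sampling", {
  set.seed(42)
  for (i in 1:100) {
    eye <- eye_model(runif(1, 23, 27))
    bubble <- gas_bubble(runif(1, 0.05, 0.95), eye)
    posture <- sample(c("supine", "prone"), 1)
    ang <- runif(1, -30, 30)
    got <- analytic_contact_rates(eye, bubble, posture, ang)
    want <- oracle_contact_rates(eye, bubble, posture, ang)
    expect_true(all(abs(got$rate_pct - want) < 0.1))
  }
})

test_that("contact rates respect limits, monotonicity and the f = 0.5 complement", {
  eye <- eye_model(25.4)
  full <- analytic_contact_rates(eye, gas_bubble(1, eye), "prone", 7)
  expect_equal(full$rate_pct, rep(100, 4))
  empty <- analytic_contact_rates(eye, gas_bubble(0, eye), "supine", -7)
  expect_equal(empty$rate_pct, rep(0, 4))

  # each part's rate is non-decreasing in the fill fraction
  for (posture in c("supine", "prone")) {
    rates <- sapply(seq(0.05, 0.95, by = 0.05), function(f)
      analytic_contact_rates(eye, gas_bubble(f, eye), posture, 10)$rate_pct)
    expect_true(all(diff(t(rates)) > -1e-9))
  }

  # at f = 0.5 and no supraduction, reflecting through the horizontal plane
  # maps the supine gas cap onto the prone fluid: per-part rates complement
  half <- gas_bubble(0.5, eye)
  su <- analytic_contact_rates(eye, half, "supine", 0)
  pr <- analytic_contact_rates(eye, half, "prone", 0)
  expect_equal(su$rate_pct + pr$rate_pct, rep(100, 4), tolerance = 1e-9)
  # and the superior/inferior sides are mirror-equal within each posture
  expect_equal(su$rate_pct[1:2], su$rate_pct[3:4], tolerance = 1e-9)

  expect_error(retinal_partition(eye, equator_mm = 40), "posterior pole")
})
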