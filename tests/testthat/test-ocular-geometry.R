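test_that("slice selection matches the biometric axial length", {
  ph <- cached_phantom(0.6, "supine", 5)
  axis <- phantom_geometry(ph)$anterior
  idx <- select_slice(ph$seg, ph$eye$axial_length, axis)
  expect_equal(as.integer(idx), ph$render$truth$mid_slice)
  # the chosen slice beats every other slice in extent error
  ext <- attr(idx, "extents")
  err <- abs(ext - ph$eye$axial_length)
  expect_true(all(err[idx] <= err, na.rm = TRUE))

  # dropping the first slice shifts the selected index accordingly
  shifted <- ph$seg
  shifted$masks <- shifted$masks[-1]
  shifted$per_slice <- shifted$per_slice[-1, ]
  expect_equal(as.integer(select_slice(shifted, ph$eye$axial_length, axis)),
               ph$render$truth$mid_slice - 1L)

  expect_error(select_slice(ph$seg, 40, axis), "within 2 mm")
})

test_that("limbus is recovered from the angle landmarks within a pixel", {
  for (cfg in list(c("supine", 0), c("prone", 9.5))) {
    ph <- cached_phantom(0.6, cfg[1], as.numeric(cfg[2]))
    g <- phantom_geometry(ph)
    lb <- locate_limbus(g)
    lm <- ph$render$truth$landmarks_px
    n_img <- g$n_px; dx <- g$pixel_spacing_mm
    true_sup <- drop(gastamponade:::px_to_mm(lm["limbus_superior", , drop = FALSE],
                                             n_img, dx))
    true_inf <- drop(gastamponade:::px_to_mm(lm["limbus_inferior", , drop = FALSE],
                                             n_img, dx))
    expect_lt(sqrt(sum((lb$superior$point - true_sup)^2)), dx)
    expect_lt(sqrt(sum((lb$inferior$point - true_inf)^2)), dx)
  }
})

test_that("limbus position in the eye frame is rotation-equivariant", {
  phi_at <- function(angle) {
    ph <- cached_phantom(0.6, "supine", angle)
    locate_limbus(phantom_geometry(ph))$superior$phi
  }
  # rotating the whole scene (eye + landmarks) leaves the eye-frame angle put
  expect_lt(abs(phi_at(12) - phi_at(0)), 0.02)
})

test_that("landmarks sit at 7 and 13.5 mm of arc posterior to the limbus", {
  ph <- cached_phantom(0.6)
  g <- phantom_geometry(ph)
  lmk <- place_landmarks(g)
  par <- lmk$par
  # polyline arc-length oracle: dense cumulative chord length between the
  # returned angles must equal the nominal distances
  arc_between <- function(p1, p2) {
    grid <- seq(p1, p2, length.out = 20000)
    pts <- gastamponade:::param_point(par, grid)$point
    sum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2))
  }
  expect_lt(abs(arc_between(lmk$superior$limbus$phi, lmk$superior$ora$phi) - 7), 0.05)
  expect_lt(abs(arc_between(lmk$superior$limbus$phi, lmk$superior$equator$phi) - 13.5), 0.05)
  expect_lt(abs(arc_between(lmk$inferior$ora$phi, lmk$inferior$limbus$phi) - 7), 0.05)

  # on a near-circular globe the ora sits about 7/R radians past the limbus
  R <- ph$eye$radius
  expect_lt(abs((lmk$superior$ora$phi - lmk$superior$limbus$phi) - 7 / R), 0.03)

  expect_error(place_landmarks(g, equator_mm = 45), "shorter than")
})

test_that("the four retinal parts and the anterior remainder tile the contour", {
  ph <- cached_phantom(0.6, "prone", -5)
  g <- phantom_geometry(ph)
  part <- partition_retina(g)
  par <- attr(part, "par")
  total <- gastamponade:::param_arclen(par, -pi, pi)
  ora_sup <- part$phi_start[part$part == "superior_anterior"]
  ora_inf <- part$phi_end[part$part == "inferior_anterior"]
  remainder <- gastamponade:::param_arclen(par, ora_inf, ora_sup)
  expect_lt(abs(sum(part$length_mm) + remainder - total), 0.1)
  # superior and inferior sides are mirror-equal on a symmetric phantom
  expect_lt(abs(part$length_mm[1] - part$length_mm[3]), 0.35)
  expect_lt(abs(part$length_mm[2] - part$length_mm[4]), 0.35)
})

test_that("contact rates hit the trivial limits", {
  ph1 <- cached_phantom(1)
  g1 <- phantom_geometry(ph1)
  expect_equal(measure_contact(g1)$rate_pct, rep(100, 4), tolerance = 1e-6)
  ph0 <- cached_phantom(0)
  g0 <- phantom_geometry(ph0)
  expect_equal(measure_contact(g0)$rate_pct, rep(0, 4))
})

test_that("pixel contact rates track the analytic oracle", {
  for (cfg in list(list(f = 0.349, p = "prone", a = 15),
                   list(f = 0.708, p = "supine", a = -15),
                   list(f = 0.6, p = "supine", a = 0))) {
    ph <- cached_phantom(cfg$f, cfg$p, cfg$a)
    mc <- measure_contact(phantom_geometry(ph))
    an <- analytic_contact_rates(ph$eye, ph$bubble, cfg$p, cfg$a)
    expect_lt(max(abs(mc$rate_pct - an$rate_pct)), 3)
  }
})

test_that("measured rates are mirror-symmetric in the supraduction sign", {
  up <- measure_contact(phantom_geometry(cached_phantom(0.6, "supine", 15)))
  dn <- measure_contact(phantom_geometry(cached_phantom(0.6, "supine", -15)))
  # flipping the sign swaps the superior and inferior parts
  expect_lt(max(abs(up$rate_pct - dn$rate_pct[c(3, 4, 1, 2)])), 1)
})

test_that("supraduction angle is recovered with its sign", {
  ph <- cached_phantom(0.6, "supine", 9.5)
  expect_lt(abs(measure_supraduction(phantom_geometry(ph), "supine") - 9.5), 0.5)
  ph2 <- cached_phantom(0.588, "supine", -16.1, axial_length = 23.8)
  got <- measure_supraduction(phantom_geometry(ph2), "supine")
  expect_lt(abs(got + 16.1), 0.5)
  expect_lt(got, 0)
  ph3 <- cached_phantom(0.6, "prone", 0)
  expect_lt(abs(measure_supraduction(phantom_geometry(ph3), "prone")), 0.5)
})
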