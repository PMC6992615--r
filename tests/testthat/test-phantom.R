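test_that("rendering is bit-identical under a fixed seed", {
  eye <- eye_model(25.4)
  bubble <- gas_bubble(0.6, eye)
  p <- imaging_params(seed = 5L, noise_sd = 5)
  a <- render_stack(eye, bubble, p, "supine", 9.5)
  b <- render_stack(eye, bubble, p, "supine", 9.5)
  expect_identical(a$stack$slices, b$stack$slices)
  c <- render_stack(eye, bubble, imaging_params(seed = 6L, noise_sd = 5),
                    "supine", 9.5)
  expect_false(identical(a$stack$slices, c$stack$slices))
})

test_that("fill limits produce empty and full gas masks", {
  ph0 <- cached_phantom(0)
  expect_false(any(sapply(ph0$render$truth$gas_masks, any)))
  expect_true(any(sapply(ph0$render$truth$cavity_masks, any)))
  ph1 <- cached_phantom(1)
  expect_true(all(mapply(function(g, cav) identical(g, cav),
                         ph1$render$truth$gas_masks,
                         ph1$render$truth$cavity_masks)))
})

test_that("ground-truth areas integrate back to the fill fraction", {
  for (f in c(0.349, 0.601, 0.708)) {
    ph <- cached_phantom(f, "supine", 5)
    a <- ph$render$truth$areas
    # analytic circular-segment areas
    expect_lt(abs(100 * sum(a$gas_mm2) / sum(a$cavity_mm2) - 100 * f), 1)
    # supersampled pixel-mask areas
    expect_lt(abs(100 * sum(a$gas_px_mm2) / sum(a$cavity_px_mm2) - 100 * f), 1)
  }
})

test_that("rendering rejects impossible scenes", {
  eye <- eye_model(25.4)
  b <- gas_bubble(0.5, eye)
  expect_error(render_stack(eye, b, imaging_params(), "supine", 60),
               "supraduction")
  expect_error(render_stack(eye, b, imaging_params(fov_mm = 20), "supine", 0),
               "field of view")
})

test_that("the printed per-case table drives the phantom cohort", {
  sc <- cohort_from_table3()
  expect_length(sc, 16L)
  key <- vapply(sc, function(s) paste0(s$case, ":", s$posture), character(1))
  c6p <- sc[[match("6:prone", key)]]
  expect_equal(c6p$fill_fraction, 0.349)
  expect_equal(c6p$supraduction_deg, 9.5)
  c8s <- sc[[match("8:supine", key)]]
  expect_equal(c8s$fill_fraction, 0.690)
  expect_equal(c8s$supraduction_deg, 0)
  c1s <- sc[[match("1:supine", key)]]
  expect_equal(c1s$fill_fraction, 0.588)
  expect_equal(c1s$supraduction_deg, -16.1)
  # axial lengths come from the patient table
  expect_equal(c1s$eye$axial_length, 23.8)

  bad <- utils::read.csv(gt_table_path("table3"))
  names(bad)[2] <- "wrong"
  expect_error(cohort_from_table3(bad), "missing column")
  bad2 <- utils::read.csv(gt_table_path("table3"))
  bad2$gas_volume_prone_pct[3] <- "x"
  expect_error(cohort_from_table3(bad2), "row 3")
})

test_that("stacks round-trip through TIFF plus JSON sidecar", {
  ph <- cached_phantom(0.6, "prone", -5, noise = 5, seed = 2L)
  path <- file.path(tempdir(), "stack.tiff")
  write_image_stack(ph$render$stack, path, ph$render$truth)
  rt <- read_image_stack(path)
  expect_equal(length(rt$slices), length(ph$render$stack$slices))
  expect_equal(rt$slice_spacing_mm, 3.5)
  expect_equal(rt$posture, "prone")
  # 16-bit quantisation of a 0-255 scale
  orig <- pmin(255, pmax(0, ph$render$stack$slices[[4]]))
  expect_lt(max(abs(rt$slices[[4]] - orig)), 255 / 65535 + 1e-6)
  expect_equal(rt$sidecar$truth$fill_fraction, 0.6)
  expect_equal(rt$sidecar$truth$supraduction_deg, -5)
  unlink(c(path, paste0(path, ".json")))
})
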