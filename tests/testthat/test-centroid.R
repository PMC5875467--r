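test_that("field center is found at sub-pixel accuracy, with and without offsets", {
  # symmetric field -> center at origin
  st <- small_linac(noise = 0)
  img <- render_epid_image(st, 0)
  fc <- find_field_center(img)
  expect_lt(abs(fc$u_mm), 0.02)
  expect_lt(abs(fc$v_mm), 0.02)
  # shifting the whole acquisition is emulated by a lateral BB+field check via
  # jaw motion below; an off-center BB must not perturb the field center
  st <- small_linac(bb = room_vector(2.0, 1.0, 0), noise = 0)
  fc <- find_field_center(render_epid_image(st, 0))
  expect_lt(abs(fc$u_mm), 0.02)
})

test_that("opening one jaw moves the field center by half the jaw travel", {
  st0 <- small_linac(noise = 0)
  st1 <- small_linac(noise = 0, jaw_asymmetry_mm = 0.5)
  c0 <- find_field_center(render_epid_image(st0, 0))
  c1 <- find_field_center(render_epid_image(st1, 0))
  expect_equal(c1$u_mm - c0$u_mm, 0.25, tolerance = 0.02)
  expect_equal(c1$v_mm - c0$v_mm, 0, tolerance = 0.02)
  # collimator 180 mirrors the asymmetric jaw
  c2 <- find_field_center(render_epid_image(st1, 0, collimator_deg = 180))
  expect_equal(c2$u_mm - c0$u_mm, -0.25, tolerance = 0.02)
})

test_that("segmentation rejects images without a usable field", {
  g <- small_geometry()
  flat <- panel_image(matrix(800L, 256, 256), 0, 0, 0, g)
  expect_error(find_field_center(flat), "no radiation field")
  # field running off the panel edge: the profile never drops at the border
  px <- matrix(500L, 256, 256)
  px[, 1:150] <- 40000L
  expect_error(find_field_center(panel_image(px, 0, 0, 0, g)), "border")
})

test_that("noiseless BB recovery is within 0.01 mm across a sub-pixel grid", {
  # 5 x 5 grid of true positions spanning a bit more than one detector pixel
  offs <- seq(-0.3, 0.3, length.out = 5)
  worst <- 0
  for (du in offs) for (dv in offs) {
    st <- small_linac(bb = room_vector(1.0 + du, -0.7 + dv, 0), noise = 0)
    fit <- fit_bb_centroid(render_epid_image(st, 0))
    err <- max(abs(fit$center$u_mm - (1.0 + du)), abs(fit$center$v_mm - (-0.7 + dv)))
    worst <- max(worst, err)
  }
  expect_lt(worst, 0.01)
})

test_that("the fitted radius honors the projected BB size constraint", {
  st <- small_linac(bb = room_vector(1.25, -0.75, 0), noise = 0)
  fit <- fit_bb_centroid(render_epid_image(st, 0))
  expect_lt(abs(fit$fitted_radius_mm - 4), 0.1 * 4)
  expect_gte(fit$rms_residual_mm, 0)
  expect_gte(fit$n_edge_points, 48)
  # a wrong nominal BB size must trip the constraint check
  bad <- segmentation_params(bb_diameter_mm = 5)
  expect_error(fit_bb_centroid(render_epid_image(st, 0), bad),
               "constraint violation")
})

test_that("translating the image content translates the fit exactly", {
  st <- small_linac(bb = room_vector(0.6, 0.4, 0), noise = 0)
  img <- render_epid_image(st, 0)
  fit0 <- fit_bb_centroid(img)
  shift_px <- 4L
  px <- img$pixels
  shifted <- px
  shifted[, (1 + shift_px):ncol(px)] <- px[, 1:(ncol(px) - shift_px)]
  img2 <- panel_image(shifted, 0, 0, 0, img$geometry)
  fit1 <- fit_bb_centroid(img2)
  s <- img$geometry$pixel_pitch_mm / magnification(img$geometry)
  expect_equal(fit1$center$u_mm - fit0$center$u_mm, shift_px * s, tolerance = 5e-3)
  expect_equal(fit1$center$v_mm - fit0$center$v_mm, 0, tolerance = 5e-3)
})

test_that("the fit is invariant to global intensity scaling", {
  st <- small_linac(bb = room_vector(-0.8, 0.5, 0), noise = 0)
  img <- render_epid_image(st, 0)
  half <- panel_image(matrix(as.integer(round(img$pixels * 0.4)),
                             nrow(img$pixels)), 0, 0, 0, img$geometry)
  f1 <- fit_bb_centroid(img)
  f2 <- fit_bb_centroid(half)
  expect_equal(f1$center$u_mm, f2$center$u_mm, tolerance = 2e-3)
  expect_equal(f1$center$v_mm, f2$center$v_mm, tolerance = 2e-3)
})

test_that("an open field without a BB raises a detection error", {
  st <- small_linac(noise = 0.02, bb_contrast_frac = 0)
  expect_error(fit_bb_centroid(render_epid_image(st, 0)), "no BB shadow")
})

test_that("repeated noisy fits are repeatable within the measured bound", {
  cent <- matrix(0, 15, 2)
  for (k in 1:15) {
    st <- small_linac(bb = room_vector(0.3, -0.2, 0), noise = 0.02, seed = 100 + k)
    f <- fit_bb_centroid(render_epid_image(st, 0))
    cent[k, ] <- c(f$center$u_mm, f$center$v_mm)
  }
  expect_lt(max(apply(cent, 2, stats::sd)), 0.07)
})

test_that("the edge-based fit agrees with the intensity-weighted centroid oracle", {
  for (seed in 1:3) {
    st <- small_linac(bb = room_vector(0.9, -1.1, 0), noise = 0.02, seed = seed)
    img <- render_epid_image(st, 0)
    fit <- fit_bb_centroid(img)
    orc <- couchalign:::bb_centroid_intensity(img)
    expect_lt(abs(fit$center$u_mm - orc$u_mm), 0.05)
    expect_lt(abs(fit$center$v_mm - orc$v_mm), 0.05)
  }
})
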