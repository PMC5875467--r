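test_that("table kinematics follow the rigid-rotation law", {
  # BB on the axis: position independent of angle
  st <- small_linac(bb = room_vector(1, 0.5, 0), axis = c(1, 0.5))
  p0 <- bb_horizontal_position(st)
  p90 <- bb_horizontal_position(set_table_angle(st, 90))
  expect_equal(p0, p90, tolerance = 1e-12)
  # BB at origin, axis at (1, 0): half turn lands at (2, 0)
  st <- small_linac(axis = c(1, 0))
  expect_equal(bb_horizontal_position(set_table_angle(st, 95)),
               c(1, 0) - rotate_point(c(1, 0), 95), tolerance = 1e-12)
  st180 <- small_linac(axis = c(1, 0))
  st180$table_deg <- 180  # beyond travel limits, kinematics only
  expect_equal(bb_horizontal_position(st180), c(2, 0), tolerance = 1e-12)
  # identity at zero and distance-to-axis invariance
  st <- small_linac(bb = room_vector(0.7, -0.4, 0), axis = c(-0.3, 0.9))
  expect_equal(bb_horizontal_position(st), c(0.7, -0.4))
  for (th in c(-90, -30, 45, 90)) {
    p <- bb_horizontal_position(set_table_angle(st, th))
    expect_equal(norm2(p - c(-0.3, 0.9)), norm2(c(0.7, -0.4) - c(-0.3, 0.9)),
                 tolerance = 1e-12)
  }
  expect_error(set_table_angle(st, 120), "95")
})

test_that("rendering is deterministic under a fixed seed and draw", {
  st <- small_linac(bb = room_vector(0.4, 0.2, 0), noise = 0.02, seed = 42)
  a <- render_epid_image(st, 0, draw = 3)
  b <- render_epid_image(st, 0, draw = 3)
  expect_identical(a$pixels, b$pixels)
  c_ <- render_epid_image(st, 0, draw = 4)
  expect_false(identical(a$pixels, c_$pixels))
})

test_that("session files are bit-exact across regeneration", {
  st <- small_linac(axis = c(0.5, 0.2), noise = 0.02, seed = 8)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_rotation_session(st, angles = c(0, 30, 60), out_dir = d1)
  generate_rotation_session(st, angles = c(0, 30, 60), out_dir = d2)
  for (f in c("img_001.tif", "img_002.tif", "img_003.tif"))
    expect_identical(readBin(file.path(d1, f), "raw", 3e6),
                     readBin(file.path(d2, f), "raw", 3e6))
})

test_that("rendered images honor the contrast contract and out-of-field flag", {
  st <- small_linac(noise = 0.02)
  img <- render_epid_image(st, 0)
  px <- img$pixels
  g <- img$geometry
  s <- g$pixel_pitch_mm / magnification(g)
  ctr <- (256 + 1) / 2
  half_px <- (40 / 2) / s
  rows <- round(ctr + (-half_px:half_px) * 0.5)
  inside <- mean(px[rows, rows])
  border <- mean(px[1:10, 1:10])
  expect_gt(inside, 5 * border)
  expect_false(img$meta$extra$bb_outside_field)
  far <- small_linac(bb = room_vector(18, 0, 0))
  expect_true(render_epid_image(far, 0)$meta$extra$bb_outside_field)
})

test_that("caliper moves translate the BB exactly and compose to identity", {
  st <- small_linac(bb = room_vector(0.3, 0.3, 0.3))
  mk <- function(lat, long, vert)
    structure(list(moves = room_vector(lat, long, vert), resolution_mm = 0.05),
              class = "caliper_correction")
  st2 <- apply_caliper_move(st, mk(0.5, -0.25, 0.1))
  expect_equal(c(st2$bb_position$lat_ab_mm, st2$bb_position$long_gt_mm,
                 st2$bb_position$vert_mm), c(0.8, 0.05, 0.4))
  st3 <- apply_caliper_move(st2, mk(-0.5, 0.25, -0.1))
  expect_equal(st3$bb_position, st$bb_position)
  expect_equal(apply_caliper_move(st, mk(0, 0, 0))$bb_position, st$bb_position)
  expect_error(apply_caliper_move(st, mk(0.513, 0, 0)), "multiple")
})

test_that("screw adjustments move the rotation axis per the conversion equations", {
  st <- small_linac(axis = c(0.4, -0.2))
  same <- shifts_to_screws(adjustment_vector(0.3, 0))   # pure GT
  st2 <- apply_screw_adjustment(st, same)
  expect_equal(st2$axis_offset, c(0.4, 0.1), tolerance = 1e-12)
  zero <- shifts_to_screws(adjustment_vector(0, 0))
  expect_equal(apply_screw_adjustment(st, zero)$axis_offset, st$axis_offset)
  # noiseless closed loop drives the axis offset to (near) zero
  stc <- small_linac(axis = c(1.2, -0.8), noise = 0)
  an <- analyze_rotation(generate_rotation_session(stc))
  stc2 <- apply_screw_adjustment(stc, an$screws)
  expect_lt(norm2(stc2$axis_offset), 0.02)
})

test_that("hysteresis offsets the trajectory laterally by direction of travel", {
  st <- small_linac(axis = c(0.5, 0), hysteresis_mm = 0.2)
  ccw <- set_table_angle(st, 30)
  cw <- set_table_angle(set_table_angle(st, 60), 30)
  expect_equal(bb_horizontal_position(ccw)[1] - bb_horizontal_position(cw)[1],
               0.2, tolerance = 1e-12)
})
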