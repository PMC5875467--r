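test_that("collimator pairs cancel jaw asymmetry in the beam-axis estimate", {
  st_sym <- small_linac(noise = 0)
  st_asym <- small_linac(noise = 0, jaw_asymmetry_mm = 0.4)
  ax_sym <- beam_axis_from_pair(render_epid_image(st_sym, 0),
                                render_epid_image(st_sym, 0, collimator_deg = 180))
  ax_asym <- beam_axis_from_pair(render_epid_image(st_asym, 0),
                                 render_epid_image(st_asym, 0, collimator_deg = 180))
  expect_lt(abs(ax_asym$u_mm - ax_sym$u_mm), 0.02)
  expect_lt(abs(ax_asym$v_mm - ax_sym$v_mm), 0.02)
  expect_error(beam_axis_from_pair(render_epid_image(st_sym, 0),
                                   render_epid_image(st_sym, 90)), "gantry")
})

test_that("the 8-image solve recovers a known 3D BB offset, noiselessly", {
  st <- small_linac(bb = room_vector(0.5, -0.3, 0.2), noise = 0)
  iso <- estimate_bb_offset(generate_placement_session(st))
  expect_lt(abs(iso$offset$lat_ab_mm - 0.5), 0.02)
  expect_lt(abs(iso$offset$long_gt_mm + 0.3), 0.02)
  expect_lt(abs(iso$offset$vert_mm - 0.2), 0.02)
  expect_length(iso$per_image_residuals, 8)
  expect_lt(iso$rms_residual_mm, 0.02)
})

test_that("a BB at isocenter measures a null offset", {
  st <- small_linac(noise = 0)
  iso <- estimate_bb_offset(generate_placement_session(st))
  expect_lt(couchalign:::iso_offset_norm(iso), 0.01)
})

test_that("incomplete placement sets are rejected", {
  st <- small_linac()
  imgs <- generate_placement_session(st)
  expect_error(estimate_bb_offset(imgs[1:7]), "exactly 8")
  # replace the gantry-270 collimator-0 image by a duplicate at gantry 0
  idx <- which(vapply(imgs, function(im)
    im$meta$gantry_deg == 270 && im$meta$collimator_deg == 0, logical(1)))
  imgs[[idx]] <- imgs[[1]]
  expect_error(estimate_bb_offset(imgs), "exactly one image per")
})

test_that("the offset estimator is unbiased over random offsets", {
  set.seed(99)
  n <- 50
  errs <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    truth <- stats::runif(3, -2, 2)
    st <- small_linac(bb = room_vector(truth[1], truth[2], truth[3]), noise = 0)
    iso <- estimate_bb_offset(generate_placement_session(st))
    errs[i, ] <- c(iso$offset$lat_ab_mm, iso$offset$long_gt_mm,
                   iso$offset$vert_mm) - truth
  }
  expect_lt(max(abs(colMeans(errs))), 0.02)
})

test_that("jaw asymmetry up to 1 mm barely perturbs the recovered offset", {
  truth <- room_vector(0.8, -0.6, 0.4)
  base <- estimate_bb_offset(generate_placement_session(
    small_linac(bb = truth, noise = 0)))
  for (asym in c(0.4, 1.0)) {
    pert <- estimate_bb_offset(generate_placement_session(
      small_linac(bb = truth, noise = 0, jaw_asymmetry_mm = asym)))
    delta <- c(pert$offset$lat_ab_mm - base$offset$lat_ab_mm,
               pert$offset$long_gt_mm - base$offset$long_gt_mm,
               pert$offset$vert_mm - base$offset$vert_mm)
    expect_lt(max(abs(delta)), 0.03)
  }
})

test_that("caliper corrections negate the offset and quantize away from zero", {
  iso <- structure(list(offset = room_vector(0.5, -0.3, 0.2)), class = "iso_offset")
  corr <- compute_caliper_correction(iso, 0.05)
  expect_equal(c(corr$moves$lat_ab_mm, corr$moves$long_gt_mm, corr$moves$vert_mm),
               c(-0.5, 0.3, -0.2))
  iso2 <- structure(list(offset = room_vector(0.513, 0, 0)), class = "iso_offset")
  expect_equal(compute_caliper_correction(iso2, 0.05)$moves$lat_ab_mm, -0.50)
  # exact half-quantum ties round away from zero
  iso3 <- structure(list(offset = room_vector(-0.125, 0.125, 0)), class = "iso_offset")
  c3 <- compute_caliper_correction(iso3, 0.05)
  expect_equal(c3$moves$lat_ab_mm, 0.15)
  expect_equal(c3$moves$long_gt_mm, -0.15)
  zero <- compute_caliper_correction(
    structure(list(offset = room_vector(0, 0, 0)), class = "iso_offset"), 0.05)
  expect_equal(c(zero$moves$lat_ab_mm, zero$moves$long_gt_mm, zero$moves$vert_mm),
               c(0, 0, 0))
  expect_error(compute_caliper_correction(iso, 0), "resolution")
})

test_that("iterative placement converges and respects the fixed point", {
  # noiseless, 3 mm initial offset: within tolerance in at most 3 cycles
  st <- small_linac(bb = room_vector(2.0, -1.8, 1.2), noise = 0)
  res <- iterate_placement(st, tol_mm = 0.05, max_iter = 4)
  expect_true(res$converged)
  expect_lte(res$n_iterations, 3)
  expect_lte(couchalign:::iso_offset_norm(res$iso), 0.05)
  # already-placed BB: one measurement, no move
  st0 <- small_linac(noise = 0)
  res0 <- iterate_placement(st0, tol_mm = 0.1, max_iter = 4)
  expect_identical(res0$n_iterations, 1L)
  expect_equal(res0$state$bb_position, st0$bb_position)
  # closed-loop residual stays bounded by quantization + noise floor
  stn <- small_linac(bb = room_vector(1.3, 0.9, -0.7), noise = 0.02, seed = 17)
  resn <- iterate_placement(stn, tol_mm = 0.1, max_iter = 4)
  expect_lte(couchalign:::iso_offset_norm(resn$iso), 0.11)
})
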