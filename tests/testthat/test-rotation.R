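test_that("Kasa fit recovers exact circles", {
  f <- kasa_circle_fit(rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1)))
  expect_equal(f$center, c(0, 0), tolerance = 1e-12)
  expect_equal(f$radius_mm, 1, tolerance = 1e-12)
  expect_false(f$degenerate)

  f <- kasa_circle_fit(rbind(c(2, 1), c(1, 2), c(0, 1), c(1, 0)))
  expect_equal(f$center, c(1, 1), tolerance = 1e-12)
  expect_equal(f$radius_mm, 1, tolerance = 1e-12)
  expect_equal(f$rms_residual_mm, 0, tolerance = 1e-9)
})

test_that("Kasa fit handles degenerate and invalid inputs per contract", {
  expect_error(kasa_circle_fit(rbind(c(0, 0), c(1, 1))), "at least 3")
  # collinear points with real spread cannot determine a circle
  expect_error(kasa_circle_fit(cbind(seq(0, 1, length.out = 5), 0)),
               "degenerate geometry")
  # a tight cluster is a legitimate aligned-table outcome, flagged not thrown
  cl <- kasa_circle_fit(rbind(c(0, 0), c(0.01, 0), c(0, 0.01), c(0.01, 0.01)))
  expect_true(cl$degenerate)
  expect_equal(cl$center, c(0.005, 0.005), tolerance = 1e-12)
  expect_equal(cl$radius_mm, 0)
})

test_that("Kasa fit matches the brute-force grid-search oracle on noisy arcs", {
  set.seed(2024)
  for (i in 1:20) {
    ctr <- stats::runif(2, -1.5, 1.5)
    rad <- stats::runif(1, 0.8, 2.5)
    pts <- make_noisy_arc(ctr, rad, n = 15, sigma = 0.02)
    fit <- kasa_circle_fit(pts)
    oracle <- grid_circle_fit(pts, center_window = ctr)
    expect_lt(norm2(fit$center - oracle$center), 0.05)
  }
})

test_that("trajectories re-zero on the first image and follow the kinematic law", {
  axis <- c(1.0, 0.5)
  st <- small_linac(axis = axis, noise = 0)
  imgs <- generate_rotation_session(st, angles = c(0, 30, 60, 90, -30, -90))
  traj <- build_trajectory(imgs)
  expect_identical(c(traj$u_mm[1], traj$v_mm[1]), c(0, 0))
  # p(theta) = c - R(theta) c for a BB starting at isocenter
  for (i in seq_len(nrow(traj))) {
    expected <- axis - rotate_point(axis, traj$table_deg[i])
    expect_lt(norm2(c(traj$u_mm[i], traj$v_mm[i]) - expected), 0.02)
  }
  expect_identical(traj$direction, c("start", "ccw", "ccw", "ccw", "cw", "cw"))
})

test_that("an aligned table yields a trajectory at the noise floor", {
  st <- small_linac(axis = c(0, 0), noise = 0)
  traj <- build_trajectory(generate_rotation_session(st, angles = c(0, 45, 90, -45, -90)))
  expect_lt(max_rotational_error(traj), 0.01)
})

test_that("trajectory construction validates gantry and table preconditions", {
  st <- small_linac()
  imgs <- generate_rotation_session(st, angles = c(0, 30, 60))
  bad <- imgs
  bad[[2]] <- render_epid_image(st, gantry_deg = 90)
  expect_error(build_trajectory(bad), "gantry")
  expect_error(build_trajectory(imgs[1:2]), "at least 3")
  st2 <- set_table_angle(st, 30)
  imgs2 <- list(render_epid_image(st2, 0), imgs[[2]], imgs[[3]])
  expect_error(build_trajectory(imgs2), "table 0")
})

test_that("max rotational error is the maximum displacement norm", {
  traj <- data.frame(u_mm = c(0.2, -1.5, 0.7), v_mm = c(0, 0, 0))
  expect_equal(max_rotational_error(traj), 1.5)
  # analytic law: ideal offset d over a +/-90 sweep peaks at sqrt(2) d
  st <- small_linac(axis = c(0.6, -0.8), noise = 0)
  an <- analyze_rotation(generate_rotation_session(st))
  expect_equal(an$max_rotational_error_mm, sqrt(2) * 1.0, tolerance = 0.02)
})

test_that("the adjustment vector is the negated circle center in (GT, AB)", {
  fit <- structure(list(center = c(1.2, -0.3), radius_mm = 1.24,
                        rms_residual_mm = 0, degenerate = FALSE),
                   class = "circle_fit")
  adj <- compute_adjustment(fit)
  expect_equal(adj$y_ab_mm, -1.2)   # u component -> AB plane
  expect_equal(adj$x_gt_mm, 0.3)    # v component -> GT plane
  degen <- structure(list(center = c(0.001, 0.001), radius_mm = 0,
                          rms_residual_mm = 0, degenerate = TRUE),
                     class = "circle_fit")
  z <- compute_adjustment(degen)
  expect_equal(c(z$x_gt_mm, z$y_ab_mm), c(0, 0))
})

test_that("noiseless rotation analysis recovers the true axis offset", {
  axis <- c(-0.9, 0.35)
  st <- small_linac(axis = axis, noise = 0)
  an <- analyze_rotation(generate_rotation_session(st))
  expect_lt(norm2(an$fit$center - axis), 0.02)
  # the theta = 0 point lies on the circle by construction
  dist_origin <- abs(norm2(an$fit$center) - an$fit$radius_mm)
  expect_lt(dist_origin, 0.02)
})

test_that("repeated noisy sessions reproduce per-position scatter near the centroid noise", {
  # centroid noise floor measured on stationary repeats
  base <- sapply(1:7, function(k) {
    st <- small_linac(bb = room_vector(0, 0, 0), noise = 0.02, seed = 300 + k)
    f <- fit_bb_centroid(render_epid_image(st, 0))
    c(f$center$u_mm, f$center$v_mm)
  })
  floor_sd <- mean(apply(base, 1, stats::sd))
  angles <- c(0, 45, 90, -45, -90, 0)
  pos <- array(0, c(7, length(angles), 2))
  for (k in 1:7) {
    st <- small_linac(axis = c(0.8, 0.2), noise = 0.02, seed = 400 + 31 * k)
    traj <- build_trajectory(generate_rotation_session(st, angles = angles))
    pos[k, , ] <- cbind(traj$u_mm, traj$v_mm)
  }
  per_pos_sd <- mean(apply(pos, c(2, 3), stats::sd))
  # each trajectory point differences two independent fits, so its scatter
  # should sit near sqrt(2) x the single-fit noise floor
  expected <- sqrt(2) * floor_sd
  expect_lt(per_pos_sd, 1.5 * expected)
  expect_gt(per_pos_sd, expected / 1.5)
})
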