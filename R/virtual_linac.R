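#' Virtual linac for closed-loop validation
#'
#' Ground-truth simulator of the BB phantom, the table rotation kinematics,
#' the caliper and screw actuators, and EPID image formation. Image
#' formation is purely geometric: an open square field with Gaussian-blurred
#' penumbra, a BB shadow rendered as a blurred attenuation disk at the
#' projected BB position, Gaussian pixel noise and 16-bit quantization.
#'
#' @param bb_position [room_vector()]: true BB location relative to radiation
#'   isocenter, parameterized at table 0.
#' @param axis_offset Length-2 numeric (mm): table rotation axis in the
#'   horizontal plane, relative to isocenter, as (lateral A+, longitudinal
#'   G+).
#' @param table_deg Current table angle.
#' @param geometry A [beam_geometry()].
#' @param field_size_mm Square field side at isocenter-plane scale.
#' @param bb_diameter_mm Physical BB diameter.
#' @param noise_sigma_frac Gaussian pixel noise SD as a fraction of the
#'   open-field level.
#' @param psf_sigma_mm Gaussian edge blur at isocenter-plane scale.
#' @param bb_contrast_frac BB shadow depth as a fraction of the open-field
#'   level.
#' @param jaw_asymmetry_mm Offset applied to the +u jaw at collimator 0; the
#'   pattern is negated at collimator 180.
#' @param caliper_resolution_mm Readability quantum of the phantom-base
#'   Vernier calipers.
#' @param hysteresis_mm Optional direction-dependent lateral offset of the
#'   BB trajectory (cw vs ccw approach); 0 disables it.
#' @param seed Integer seed; identical state and seed reproduce bit-identical
#'   images.
#' @return An object of class `virtual_linac`.
#' @export
virtual_linac <- function(bb_position = room_vector(),
                          axis_offset = c(0, 0),
                          table_deg = 0,
                          geometry = beam_geometry(),
                          field_size_mm = 100,
                          bb_diameter_mm = 8,
                          noise_sigma_frac = 0.02,
                          psf_sigma_mm = 0.3,
                          bb_contrast_frac = 0.35,
                          jaw_asymmetry_mm = 0,
                          caliper_resolution_mm = 0.05,
                          hysteresis_mm = 0,
                          seed = 1L) {
  stopifnot(inherits(bb_position, "room_vector"),
            inherits(geometry, "beam_geometry"),
            length(axis_offset) == 2, all(is.finite(axis_offset)))
  if (field_size_mm <= bb_diameter_mm)
    stop("field_size_mm must exceed the projected BB diameter", call. = FALSE)
  if (noise_sigma_frac < 0 || noise_sigma_frac >= 1 ||
      bb_contrast_frac < 0 || bb_contrast_frac >= 1)
    stop("noise and contrast fractions must be in [0, 1)", call. = FALSE)
  structure(list(bb_position = bb_position,
                 axis_offset = as.numeric(axis_offset),
                 table_deg = table_deg,
                 geometry = geometry,
                 field_size_mm = field_size_mm,
                 bb_diameter_mm = bb_diameter_mm,
                 noise_sigma_frac = noise_sigma_frac,
                 psf_sigma_mm = psf_sigma_mm,
                 bb_contrast_frac = bb_contrast_frac,
                 jaw_asymmetry_mm = jaw_asymmetry_mm,
                 caliper_resolution_mm = caliper_resolution_mm,
                 hysteresis_mm = hysteresis_mm,
                 last_direction = "start",
                 seed = as.integer(seed)),
            class = "virtual_linac")
}

#' @export
print.virtual_linac <- function(x, ...) {
  cat(sprintf("<virtual_linac> BB (%+.3f, %+.3f, %+.3f) mm, axis (%+.3f, %+.3f) mm, table %g deg, noise %g%%\n",
              x$bb_position$lat_ab_mm, x$bb_position$long_gt_mm,
              x$bb_position$vert_mm, x$axis_offset[1], x$axis_offset[2],
              x$table_deg, 100 * x$noise_sigma_frac))
  invisible(x)
}

#' True horizontal BB position under the current table angle
#'
#' Rigid rotation of the tabletop about the (possibly offset) rotation axis:
#' `p(theta) = R(theta) (p0 - c) + c`, where `p0` is the BB's horizontal
#' position at table 0 and `c` the axis offset.
#'
#' @param state A [virtual_linac()].
#' @return Length-2 numeric (lateral, longitudinal) in mm.
#' @export
bb_horizontal_position <- function(state) {
  stopifnot(inherits(state, "virtual_linac"))
  p0 <- room_to_horizontal(state$bb_position)
  p <- rotate_point(p0, state$table_deg, pivot = state$axis_offset)
  if (state$hysteresis_mm != 0) {
    p[1] <- p[1] + switch(state$last_direction,
                          ccw = state$hysteresis_mm / 2,
                          cw = -state$hysteresis_mm / 2,
                          0)
  }
  p
}

#' Rotate the virtual table
#'
#' @param state A [virtual_linac()].
#' @param theta_deg Target table angle, within +/-95 degrees.
#' @return Updated state.
#' @export
set_table_angle <- function(state, theta_deg) {
  stopifnot(inherits(state, "virtual_linac"))
  if (!is.finite(theta_deg) || abs(theta_deg) > 95)
    stop("table angle must be within +/-95 degrees", call. = FALSE)
  d <- theta_deg - state$table_deg
  if (d != 0) state$last_direction <- if (d > 0) "ccw" else "cw"
  state$table_deg <- theta_deg
  state
}

#' Apply a quantized caliper move to the phantom base
#'
#' @param state A [virtual_linac()].
#' @param corr A `caliper_correction` from [compute_caliper_correction()].
#' @return Updated state with the BB translated by the commanded move.
#' @export
apply_caliper_move <- function(state, corr) {
  stopifnot(inherits(state, "virtual_linac"), inherits(corr, "caliper_correction"))
  m <- corr$moves
  res <- corr$resolution_mm
  for (comp in c("lat_ab_mm", "long_gt_mm", "vert_mm")) {
    q <- m[[comp]] / res
    if (abs(q - round(q)) > 1e-6)
      stop("caliper move ", comp, " is not a multiple of the resolution",
           call. = FALSE)
  }
  state$bb_position <- room_vector(
    lat_ab_mm = state$bb_position$lat_ab_mm + m$lat_ab_mm,
    long_gt_mm = state$bb_position$long_gt_mm + m$long_gt_mm,
    vert_mm = state$bb_position$vert_mm + m$vert_mm)
  state
}

#' Apply fixing-screw rotations to the virtual table base
#'
#' Moves the table rotation axis by the shift equivalent to the commanded
#' screw rotations. The BB, fixed to the tabletop, follows implicitly
#' whenever the table is rotated away from 0.
#'
#' @param state A [virtual_linac()].
#' @param s A `screw_adjustment` from [shifts_to_screws()].
#' @param k A [screw_constants()].
#' @return Updated state.
#' @export
apply_screw_adjustment <- function(state, s, k = screw_constants()) {
  stopifnot(inherits(state, "virtual_linac"))
  shift <- screws_to_shifts(s, k)
  state$axis_offset <- state$axis_offset + c(shift$y_ab_mm, shift$x_gt_mm)
  state
}

with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  force(code)
}

#' Render a portal image of the current virtual-linac state
#'
#' @param state A [virtual_linac()].
#' @param gantry_deg,collimator_deg Acquisition angles.
#' @param draw Integer draw index; the noise stream is derived from
#'   `state$seed` and `draw`, so identical (state, draw) pairs give
#'   bit-identical images while multi-image sessions pass distinct draws.
#' @return A [panel_image()]. If the BB projects outside the field the image
#'   is still rendered but flagged via the `bb_outside_field` metadata key.
#' @export
render_epid_image <- function(state, gantry_deg, collimator_deg = 0, draw = 0L) {
  stopifnot(inherits(state, "virtual_linac"))
  g <- state$geometry
  s <- iso_scale_mm_per_px(g)
  nr <- g$panel_rows; nc <- g$panel_cols
  cr <- (nr + 1) / 2; ccn <- (nc + 1) / 2
  u <- (seq_len(nc) - ccn) * s
  v <- -(seq_len(nr) - cr) * s
  half <- state$field_size_mm / 2
  sig <- max(state$psf_sigma_mm, 1e-6)
  asym <- state$jaw_asymmetry_mm
  col180 <- abs(((collimator_deg %% 360) + 360) %% 360 - 180) < 0.5
  u_lo <- -half - if (col180) asym else 0
  u_hi <- half + if (col180) 0 else asym
  fu <- stats::pnorm((u - u_lo) / sig) * stats::pnorm((u_hi - u) / sig)
  fv <- stats::pnorm((v + half) / sig) * stats::pnorm((half - v) / sig)
  open_level <- 40000
  base_frac <- 0.02
  field <- outer(fv, fu)

  ph <- bb_horizontal_position(state)
  p3 <- horizontal_to_room(ph, vert_mm = state$bb_position$vert_mm)
  pp <- project_room_to_panel(p3, gantry_deg %% 360, g)
  r_bb <- state$bb_diameter_mm / 2
  outside <- abs(pp$u_mm) > half - r_bb || abs(pp$v_mm) > half - r_bb
  # blurred attenuation disk, evaluated on a local patch only
  ur <- which(abs(u - pp$u_mm) <= r_bb + 6 * sig)
  vr <- which(abs(v - pp$v_mm) <= r_bb + 6 * sig)
  if (length(ur) && length(vr)) {
    rho <- sqrt(outer((v[vr] - pp$v_mm)^2, (u[ur] - pp$u_mm)^2, `+`))
    disk <- stats::pnorm((r_bb - rho) / sig)
    field[vr, ur] <- field[vr, ur] * (1 - state$bb_contrast_frac * disk)
  }
  img <- open_level * (base_frac + (1 - base_frac) * field)
  if (state$noise_sigma_frac > 0) {
    with_preserved_rng({
      set.seed((state$seed + 104729L * (as.integer(draw) %% 20011L)) %% 2147483647L)
      img <- img + stats::rnorm(length(img),
                                sd = state$noise_sigma_frac * open_level)
    })
  }
  pixels <- matrix(pmin(pmax(as.integer(round(img)), 0L), 65535L), nrow = nr)
  panel_image(pixels, gantry_deg = gantry_deg %% 360,
              collimator_deg = collimator_deg %% 360,
              table_deg = state$table_deg, geometry = g,
              machine_id = "virtual-linac",
              extra = list(bb_outside_field = outside))
}

#' Simulate a table-rotation acquisition session
#'
#' Renders one gantry-0 image per requested table angle, rotating the
#' virtual table between acquisitions.
#'
#' @param state A [virtual_linac()].
#' @param angles Table-angle sequence (degrees); the first must be 0.
#' @param out_dir Optional directory: if given, the session is written via
#'   [write_session()] and the manifest path is returned; otherwise the list
#'   of in-memory [panel_image()]s is returned.
#' @param draw_base Offset added to the per-image draw index, so consecutive
#'   sessions from one state can use disjoint noise streams.
#' @return Manifest path or list of images (see `out_dir`).
#' @export
generate_rotation_session <- function(state, angles = default_rotation_angles(),
                                      out_dir = NULL, draw_base = 0L) {
  stopifnot(inherits(state, "virtual_linac"))
  if (length(angles) < 3L) stop("at least 3 angles required", call. = FALSE)
  if (angles[1] != 0) stop("first table angle must be 0", call. = FALSE)
  images <- vector("list", length(angles))
  for (i in seq_along(angles)) {
    state <- set_table_angle(state, angles[i])
    images[[i]] <- render_epid_image(state, gantry_deg = 0, collimator_deg = 0,
                                     draw = draw_base + i)
  }
  if (is.null(out_dir)) return(images)
  write_session(images, out_dir, purpose = "table_rotation")
}

#' Simulate the 8-image isocenter-placement acquisition
#'
#' Renders images at the four cardinal gantry angles, each at collimator 0
#' and 180, with the table at 0.
#'
#' @inheritParams generate_rotation_session
#' @return List of 8 [panel_image()], or the manifest path when `out_dir` is
#'   given.
#' @export
generate_placement_session <- function(state, out_dir = NULL, draw_base = 0L) {
  stopifnot(inherits(state, "virtual_linac"))
  state <- set_table_angle(state, 0)
  combos <- expand.grid(collimator = c(0, 180), gantry = c(0, 90, 180, 270))
  images <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    images[[i]] <- render_epid_image(state, gantry_deg = combos$gantry[i],
                                     collimator_deg = combos$collimator[i],
                                     draw = draw_base + i)
  }
  if (is.null(out_dir)) return(images)
  write_session(images, out_dir, purpose = "isocenter_placement")
}
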