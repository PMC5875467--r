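#' Collimator-invariant beam axis from a collimator 0/180 image pair
#'
#' Rotating the collimator by 180 degrees maps any jaw or MLC asymmetry to
#' its negation, so the component-wise mean of the two per-image field
#' centers is the beam-axis estimate free of collimator asymmetry.
#'
#' @param img_col0,img_col180 [panel_image()]s sharing a gantry angle, at
#'   collimator 0 and 180.
#' @param params A [segmentation_params()].
#' @return A [panel_point()].
#' @export
beam_axis_from_pair <- function(img_col0, img_col180,
                                params = segmentation_params()) {
  if (abs(img_col0$meta$gantry_deg - img_col180$meta$gantry_deg) > 0.5)
    stop("images in a collimator pair must share the gantry angle", call. = FALSE)
  c0 <- find_field_center(img_col0, params)
  c180 <- find_field_center(img_col180, params)
  panel_point(u_mm = (c0$u_mm + c180$u_mm) / 2,
              v_mm = (c0$v_mm + c180$v_mm) / 2)
}

cardinal_gantries <- c(0, 90, 180, 270)

# Group a placement set into one (col0, col180) pair per cardinal gantry
# angle; errors if the 4 x 2 coverage is incomplete.
split_placement_set <- function(images) {
  if (length(images) != 8L)
    stop("isocenter placement requires exactly 8 images, got ",
         length(images), call. = FALSE)
  tb <- vapply(images, function(im) im$meta$table_deg, numeric(1))
  if (max(tb) - min(tb) > 0.5)
    stop("all placement images must share the table angle", call. = FALSE)
  keyg <- vapply(images, function(im) (round(im$meta$gantry_deg / 90) * 90) %% 360,
                 numeric(1))
  keyc <- vapply(images, function(im) (round(im$meta$collimator_deg / 180) * 180) %% 360,
                 numeric(1))
  out <- list()
  for (gd in cardinal_gantries) {
    i0 <- which(keyg == gd & keyc == 0)
    i180 <- which(keyg == gd & keyc == 180)
    if (length(i0) != 1L || length(i180) != 1L)
      stop("placement set must contain exactly one image per (gantry ", gd,
           ", collimator 0/180) pair", call. = FALSE)
    out[[as.character(gd)]] <- list(col0 = images[[i0]], col180 = images[[i180]])
  }
  out
}

#' Estimate the 3D BB offset from radiation isocenter
#'
#' From the 8-image set (four cardinal gantry angles, collimator 0 and 180
#' at each), measures the per-gantry displacement between the BB centroid
#' and the collimator-invariant beam axis, and solves the joint linear
#' least-squares system `d(gantry) = projection(offset, gantry)` for the
#' 3-component room-frame offset. The longitudinal equations are redundant
#' across gantry angles and are kept in the system with equal weight so that
#' their residuals expose longitudinal inconsistency as a QC signal.
#'
#' @param images List of 8 [panel_image()] covering gantry
#'   `{0, 90, 180, 270}` x collimator `{0, 180}`, or a session manifest path.
#' @param params A [segmentation_params()].
#' @return An object of class `iso_offset` with fields `offset`
#'   ([room_vector()], BB minus isocenter), `rms_residual_mm` and
#'   `per_image_residuals` (length 8).
#' @export
estimate_bb_offset <- function(images, params = segmentation_params()) {
  if (is.character(images)) images <- read_session(images)
  pairs <- split_placement_set(images)
  A <- NULL; b <- NULL
  meas <- list()
  for (gd in cardinal_gantries) {
    pr <- pairs[[as.character(gd)]]
    axis <- beam_axis_from_pair(pr$col0, pr$col180, params)
    bb0 <- fit_bb_centroid(pr$col0, params)$center
    bb180 <- fit_bb_centroid(pr$col180, params)$center
    bb <- panel_point((bb0$u_mm + bb180$u_mm) / 2, (bb0$v_mm + bb180$v_mm) / 2)
    du <- bb$u_mm - axis$u_mm
    dv <- bb$v_mm - axis$v_mm
    gr <- gd * pi / 180
    # unknowns: (lat, long, vert)
    A <- rbind(A, c(cos(gr), 0, sin(gr)), c(0, 1, 0))
    b <- c(b, du, dv)
    meas[[as.character(gd)]] <- list(axis = axis, bb = list(bb0, bb180))
  }
  qr_A <- qr(A)
  if (qr_A$rank < 3L)
    stop("numerical error: singular placement system", call. = FALSE)
  sol <- qr.coef(qr_A, b)
  offset <- room_vector(lat_ab_mm = sol[1], long_gt_mm = sol[2], vert_mm = sol[3])
  rms <- sqrt(mean((A %*% sol - b)^2))
  per_image <- numeric(0)
  for (gd in cardinal_gantries) {
    pred <- project_room_to_panel(offset, gd)
    m <- meas[[as.character(gd)]]
    for (bbc in m$bb) {
      du <- bbc$u_mm - m$axis$u_mm - pred$u_mm
      dv <- bbc$v_mm - m$axis$v_mm - pred$v_mm
      per_image <- c(per_image, sqrt(du^2 + dv^2))
    }
  }
  structure(list(offset = offset, rms_residual_mm = rms,
                 per_image_residuals = per_image),
            class = "iso_offset")
}

#' @export
print.iso_offset <- function(x, ...) {
  cat(sprintf("<iso_offset> BB - isocenter: lat %+.3f, long %+.3f, vert %+.3f mm (|d| = %.3f, RMS %.4f mm)\n",
              x$offset$lat_ab_mm, x$offset$long_gt_mm, x$offset$vert_mm,
              iso_offset_norm(x), x$rms_residual_mm))
  invisible(x)
}

iso_offset_norm <- function(iso) {
  sqrt(iso$offset$lat_ab_mm^2 + iso$offset$long_gt_mm^2 + iso$offset$vert_mm^2)
}

round_to_resolution <- function(x, res) {
  sign(x) * floor(abs(x) / res + 0.5 + 1e-9) * res
}

#' Caliper correction nulling a measured BB offset
#'
#' The move is the negated offset, with each component quantized to the
#' caliper resolution; exact half-quantum ties round away from zero.
#'
#' @param iso An `iso_offset` from [estimate_bb_offset()].
#' @param resolution_mm Caliper readability quantum.
#' @return An object of class `caliper_correction` with `moves`
#'   ([room_vector()]) and `resolution_mm`.
#' @export
compute_caliper_correction <- function(iso, resolution_mm = 0.05) {
  stopifnot(inherits(iso, "iso_offset"))
  if (!is.finite(resolution_mm) || resolution_mm <= 0)
    stop("resolution_mm must be positive", call. = FALSE)
  moves <- room_vector(
    lat_ab_mm = round_to_resolution(-iso$offset$lat_ab_mm, resolution_mm),
    long_gt_mm = round_to_resolution(-iso$offset$long_gt_mm, resolution_mm),
    vert_mm = round_to_resolution(-iso$offset$vert_mm, resolution_mm))
  structure(list(moves = moves, resolution_mm = resolution_mm),
            class = "caliper_correction")
}

#' Iteratively place the BB at radiation isocenter in the simulator
#'
#' Closed loop of the 8-image placement procedure: render, estimate the BB
#' offset, stop if its norm is within tolerance, otherwise apply the
#' quantized caliper correction and repeat.
#'
#' @param linac A [virtual_linac()].
#' @param params A [segmentation_params()].
#' @param tol_mm Convergence tolerance on the estimated offset norm.
#' @param max_iter Maximum number of measurement cycles.
#' @return List with `iso` (final `iso_offset`), `n_iterations`, `converged`
#'   and the final simulator `state`.
#' @export
iterate_placement <- function(linac, params = segmentation_params(),
                              tol_mm = 0.1, max_iter = 5L) {
  stopifnot(inherits(linac, "virtual_linac"), tol_mm > 0, max_iter >= 1L)
  state <- set_table_angle(linac, 0)
  iso <- NULL
  converged <- FALSE
  n <- 0L
  for (i in seq_len(max_iter)) {
    n <- i
    images <- generate_placement_session(state, draw_base = (i - 1L) * 8L)
    iso <- estimate_bb_offset(images, params)
    if (iso_offset_norm(iso) <= tol_mm) {
      converged <- TRUE
      break
    }
    if (i < max_iter) {
      corr <- compute_caliper_correction(iso, state$caliper_resolution_mm)
      state <- apply_caliper_move(state, corr)
    }
  }
  list(iso = iso, n_iterations = n, converged = converged, state = state)
}
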