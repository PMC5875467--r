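#' Default table-rotation acquisition sequence
#'
#' Fifteen table angles covering +/-90 degrees in both directions of travel,
#' with deliberate revisits of the same angle so that hysteresis between
#' clockwise and counterclockwise approach is sampled.
#'
#' @return Numeric vector of 15 angles in degrees, starting at 0.
#' @export
default_rotation_angles <- function() {
  c(0, 30, 60, 90, 60, 30, 0, -30, -60, -90, -90, -60, -30, 0, 0)
}

#' Build the BB trajectory over table rotation
#'
#' Fits the BB centroid in each gantry-0 image and expresses every position
#' relative to the first image's centroid, which defines the (0,0) origin of
#' the MV frame (the first image is taken with the BB placed at radiation
#' isocenter). Direction-of-travel labels come from the sign of successive
#' table-angle differences.
#'
#' @param images List of [panel_image()], all at gantry 0 (within 0.5 deg),
#'   first image at table 0.
#' @param params A [segmentation_params()].
#' @return An object of class `rotation_trajectory`: data frame with columns
#'   `table_deg`, `u_mm`, `v_mm`, `direction`, plus per-image QC columns
#'   `fitted_radius_mm`, `rms_residual_mm`, `n_edge_points`.
#' @export
build_trajectory <- function(images, params = segmentation_params()) {
  if (length(images) < 3L)
    stop("at least 3 images are required", call. = FALSE)
  for (i in seq_along(images)) {
    gd <- images[[i]]$meta$gantry_deg
    if (min(abs(c(gd, gd - 360))) > 0.5)
      stop("image ", i, " is at gantry ", gd, ", not gantry 0", call. = FALSE)
  }
  if (abs(images[[1]]$meta$table_deg) > 0.5)
    stop("first image must be at table 0", call. = FALSE)
  fits <- vector("list", length(images))
  for (i in seq_along(images)) {
    fits[[i]] <- tryCatch(fit_bb_centroid(images[[i]], params),
                          error = function(e)
                            stop("centroid fit failed on image ", i, ": ",
                                 conditionMessage(e), call. = FALSE))
  }
  u <- vapply(fits, function(f) f$center$u_mm, numeric(1))
  v <- vapply(fits, function(f) f$center$v_mm, numeric(1))
  tangles <- vapply(images, function(im) im$meta$table_deg, numeric(1))
  traj <- data.frame(
    table_deg = tangles,
    u_mm = u - u[1],
    v_mm = v - v[1],
    direction = direction_labels(tangles),
    fitted_radius_mm = vapply(fits, `[[`, numeric(1), "fitted_radius_mm"),
    rms_residual_mm = vapply(fits, `[[`, numeric(1), "rms_residual_mm"),
    n_edge_points = vapply(fits, `[[`, numeric(1), "n_edge_points")
  )
  structure(traj, class = c("rotation_trajectory", "data.frame"))
}

#' Algebraic least-squares (Kasa) circle fit
#'
#' Fits a circle to 2D points by linearizing `x^2 + y^2 = 2ax + 2by + c` and
#' solving for `(a, b, c)` by ordinary least squares. Duplicate points are
#' retained: the acquisition sequence deliberately revisits angles and each
#' visit is an independent measurement.
#'
#' @param points Two-column matrix or data frame of points (mm); a
#'   `rotation_trajectory` is accepted directly.
#' @return An object of class `circle_fit` with `center` (length-2 numeric),
#'   `radius_mm`, `rms_residual_mm` and a logical `degenerate` flag. When the
#'   point spread (max pairwise distance) is below 0.05 mm the fit is flagged
#'   degenerate and the centroid with radius 0 is returned instead of an
#'   error, since an aligned table legitimately produces a point cluster.
#' @export
kasa_circle_fit <- function(points) {
  if (inherits(points, "rotation_trajectory"))
    points <- cbind(points$u_mm, points$v_mm)
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    stop("at least 3 points are required for a circle fit", call. = FALSE)
  if (!all(is.finite(points))) stop("points must be finite", call. = FALSE)
  x <- points[, 1]; y <- points[, 2]
  spread <- max(dist(points))
  if (spread < 0.05) {
    ctr <- c(mean(x), mean(y))
    return(structure(list(center = ctr, radius_mm = 0,
                          rms_residual_mm = sqrt(mean((x - ctr[1])^2 + (y - ctr[2])^2)),
                          degenerate = TRUE),
                     class = "circle_fit"))
  }
  fit <- kasa_fit_xy(x, y)
  structure(list(center = fit$center, radius_mm = fit$radius,
                 rms_residual_mm = radial_rms(x, y, fit$center, fit$radius),
                 degenerate = FALSE),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("<circle_fit> center (%+.4f, %+.4f) mm, radius %.4f mm, RMS %.4f mm%s\n",
              x$center[1], x$center[2], x$radius_mm, x$rms_residual_mm,
              if (x$degenerate) " [degenerate: point cluster]" else ""))
  invisible(x)
}

#' Maximum rotational error of a trajectory
#'
#' The largest Euclidean displacement of the BB from the MV-frame origin over
#' all measured table positions.
#'
#' @param traj A `rotation_trajectory` (or data frame with `u_mm`, `v_mm`).
#' @return Maximum vector error in mm.
#' @export
max_rotational_error <- function(traj) {
  max(sqrt(traj$u_mm^2 + traj$v_mm^2))
}

#' Optimal table-base adjustment from a circle fit
#'
#' The vector from the fitted circle center back to the MV-frame origin,
#' decomposed into gun-target (from the `v` component) and transverse (from
#' the `u` component) shifts. A degenerate fit yields a zero adjustment.
#'
#' @param fit A `circle_fit` from [kasa_circle_fit()].
#' @return An [adjustment_vector()].
#' @export
compute_adjustment <- function(fit) {
  stopifnot(inherits(fit, "circle_fit"))
  if (isTRUE(fit$degenerate)) return(adjustment_vector(0, 0))
  adjustment_vector(x_gt_mm = -fit$center[2], y_ab_mm = -fit$center[1])
}

#' Analyze a table-rotation session end to end
#'
#' Runs the full rotation analysis on a list of images or a session
#' manifest: trajectory construction, Kasa circle fit (jointly over both
#' directions of travel, with per-direction centers reported as a hysteresis
#' diagnostic), maximum rotational error, the optimal adjustment and the
#' corresponding fixing-screw rotations.
#'
#' @param session List of [panel_image()] or path to a session manifest.
#' @param params A [segmentation_params()].
#' @param k A [screw_constants()].
#' @return An object of class `rotation_analysis`.
#' @export
analyze_rotation <- function(session, params = segmentation_params(),
                             k = screw_constants()) {
  images <- if (is.character(session)) read_session(session) else session
  traj <- build_trajectory(images, params)
  fit <- kasa_circle_fit(traj)
  adj <- compute_adjustment(fit)
  per_dir <- lapply(split(traj, traj$direction), function(d) {
    if (nrow(d) >= 3L) tryCatch(kasa_circle_fit(cbind(d$u_mm, d$v_mm))$center,
                                error = function(e) c(NA_real_, NA_real_))
    else c(NA_real_, NA_real_)
  })
  structure(list(trajectory = traj, fit = fit,
                 max_rotational_error_mm = max_rotational_error(traj),
                 adjustment = adj,
                 screws = shifts_to_screws(adj, k),
                 per_direction_centers = per_dir),
            class = "rotation_analysis")
}

#' @export
print.rotation_analysis <- function(x, ...) {
  cat("Table-rotation analysis\n")
  cat(sprintf("  points: %d, table range [%g, %g] deg\n",
              nrow(x$trajectory), min(x$trajectory$table_deg),
              max(x$trajectory$table_deg)))
  cat(sprintf("  maximum rotational error: %.3f mm\n", x$max_rotational_error_mm))
  cat(sprintf("  rotation-axis offset (circle center): (%+.3f, %+.3f) mm\n",
              x$fit$center[1], x$fit$center[2]))
  cat(sprintf("  adjustment: XGT %+.3f mm, YAB %+.3f mm\n",
              x$adjustment$x_gt_mm, x$adjustment$y_ab_mm))
  cat(sprintf("  screws: A-side %+.1f deg CCW, B-side %+.1f deg CW\n",
              x$screws$theta_a_deg, x$screws$theta_b_deg))
  invisible(x)
}

#' Plot a rotation trajectory with its fitted circle
#'
#' @param analysis A `rotation_analysis`.
#' @param file Optional output file (PNG or PDF chosen by extension); if
#'   `NULL`, draws on the current device.
#' @return `file`, invisibly.
#' @export
plot_trajectory <- function(analysis, file = NULL) {
  stopifnot(inherits(analysis, "rotation_analysis"))
  if (!is.null(file)) {
    if (grepl("\\.pdf$", file)) grDevices::pdf(file, width = 6, height = 6)
    else grDevices::png(file, width = 800, height = 800, res = 120)
    on.exit(grDevices::dev.off())
  }
  tr <- analysis$trajectory
  lim <- max(abs(c(tr$u_mm, tr$v_mm, analysis$fit$center)), 0.5) * 1.3
  plot(tr$u_mm, tr$v_mm, asp = 1, xlim = c(-lim, lim), ylim = c(-lim, lim),
       xlab = "u (AB) [mm]", ylab = "v (GT) [mm]",
       pch = ifelse(tr$direction == "cw", 17, ifelse(tr$direction == "ccw", 16, 15)),
       col = ifelse(tr$direction == "cw", "firebrick",
                    ifelse(tr$direction == "ccw", "steelblue", "black")),
       main = "BB displacement over table rotation")
  graphics::abline(h = 0, v = 0, col = "grey80")
  if (!analysis$fit$degenerate) {
    th <- seq(0, 2 * pi, length.out = 181)
    graphics::lines(analysis$fit$center[1] + analysis$fit$radius_mm * cos(th),
                    analysis$fit$center[2] + analysis$fit$radius_mm * sin(th),
                    col = "grey40", lty = 2)
    graphics::points(analysis$fit$center[1], analysis$fit$center[2],
                     pch = 3, col = "grey40")
  }
  graphics::legend("topright", pch = c(15, 16, 17), bty = "n",
                   col = c("black", "steelblue", "firebrick"),
                   legend = c("start", "ccw", "cw"))
  invisible(file)
}
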