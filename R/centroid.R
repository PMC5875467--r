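#' Segmentation and BB-fit parameters
#'
#' Tuning knobs for field-edge and BB-edge localization.
#'
#' @param field_level_fraction Fraction of the open-field level (above the
#'   out-of-field baseline) defining the field edge; 0.5 is the conventional
#'   50% penumbra point.
#' @param bb_level_fraction Fraction of the way from the BB core level up to
#'   the local open-field level defining the BB edge.
#' @param n_rays Number of radial edge samples cast from the BB center guess.
#' @param bb_diameter_mm Physical diameter of the ball bearing.
#' @param radius_tolerance_frac Allowed relative deviation of the
#'   free-radius circle fit from the projected BB radius; larger deviations
#'   are treated as failed detections.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(field_level_fraction = 0.5,
                                bb_level_fraction = 0.5,
                                n_rays = 64L,
                                bb_diameter_mm = 8,
                                radius_tolerance_frac = 0.10) {
  stopifnot(field_level_fraction > 0, field_level_fraction < 1,
            bb_level_fraction > 0, bb_level_fraction < 1,
            n_rays >= 8L, bb_diameter_mm > 0, radius_tolerance_frac > 0)
  structure(list(field_level_fraction = field_level_fraction,
                 bb_level_fraction = bb_level_fraction,
                 n_rays = as.integer(n_rays),
                 bb_diameter_mm = bb_diameter_mm,
                 radius_tolerance_frac = radius_tolerance_frac),
            class = "segmentation_params")
}

iso_scale_mm_per_px <- function(geometry) {
  geometry$pixel_pitch_mm / magnification(geometry)
}

# Box-mean smoothing via integral image; constant-time per pixel, used only
# to pick a robust starting pixel for the BB search.
box_smooth <- function(m, half = 2L) {
  nr <- nrow(m); nc <- ncol(m)
  S <- rbind(0, apply(m, 2, cumsum))
  S <- cbind(0, t(apply(S, 1, cumsum)))
  r <- seq_len(nr); cc <- seq_len(nc)
  r1 <- pmax(r - half, 1L); r2 <- pmin(r + half, nr)
  c1 <- pmax(cc - half, 1L); c2 <- pmin(cc + half, nc)
  # sums over [r1..r2, c1..c2] for every pixel by outer combination
  top <- S[r2 + 1L, , drop = FALSE] - S[r1, , drop = FALSE]
  out <- top[, c2 + 1L, drop = FALSE] - top[, c1, drop = FALSE]
  area <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  out / area
}

bilinear_sample <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(r, 1), nr - 1e-9)
  c <- pmin(pmax(c, 1), nc - 1e-9)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- m[cbind(r0, c0)];     i01 <- m[cbind(r0, c0 + 1L)]
  i10 <- m[cbind(r0 + 1L, c0)]; i11 <- m[cbind(r0 + 1L, c0 + 1L)]
  i00 * (1 - fr) * (1 - fc) + i01 * (1 - fr) * fc +
    i10 * fr * (1 - fc) + i11 * fr * fc
}

field_levels <- function(px) {
  qs <- stats::quantile(px, c(0.05, 0.995), names = FALSE)
  lo <- qs[1]; hi <- qs[2]
  if (!is.finite(hi) || hi <= 0 || (hi - lo) < 0.1 * max(hi, 1))
    stop("segmentation error: no radiation field detected (dynamic range too low)",
         call. = FALSE)
  mid <- (lo + hi) / 2
  list(open = mean(px[px > mid]), baseline = mean(px[px <= mid]))
}

# Outermost sub-pixel crossings of `thr` along a 1D profile.
profile_crossings <- function(prof, thr, what) {
  above <- prof >= thr
  if (!any(above))
    stop("segmentation error: no field found along central ", what, call. = FALSE)
  i1 <- which(above)[1]; i2 <- which(above)[length(which(above))]
  if (i1 == 1L || i2 == length(prof))
    stop("segmentation error: field touches the panel border", call. = FALSE)
  left <- (i1 - 1) + (thr - prof[i1 - 1]) / (prof[i1] - prof[i1 - 1])
  right <- i2 + (prof[i2] - thr) / (prof[i2] - prof[i2 + 1])
  c(left, right)
}

#' Locate the radiation-field center in a portal image
#'
#' Finds the 50% (configurable) penumbra crossings of the central row and
#' column profiles with linear sub-pixel interpolation, and returns the
#' midpoint of the crossings as the per-image beam-axis estimate, at
#' isocenter-plane scale.
#'
#' @param image A [panel_image()] containing one open rectangular field away
#'   from the panel borders.
#' @param params A [segmentation_params()].
#' @return A [panel_point()]; attributes `edges_mm` (named u_lo/u_hi/v_lo/v_hi
#'   field-edge positions) and `levels` (open, baseline, threshold) carry the
#'   segmentation context for downstream steps.
#' @export
find_field_center <- function(image, params = segmentation_params()) {
  stopifnot(inherits(image, "panel_image"), inherits(params, "segmentation_params"))
  px <- image$pixels
  storage.mode(px) <- "double"
  lv <- field_levels(px)
  thr <- lv$baseline + params$field_level_fraction * (lv$open - lv$baseline)
  nr <- nrow(px); nc <- ncol(px)
  cr <- (nr + 1) / 2; ccn <- (nc + 1) / 2
  row_prof <- px[round(cr), ]            # across columns -> u direction
  col_prof <- px[, round(ccn)]           # across rows    -> v direction
  ucross <- profile_crossings(row_prof, thr, "row")
  vcross <- profile_crossings(col_prof, thr, "column")
  s <- iso_scale_mm_per_px(image$geometry)
  u_lo <- (ucross[1] - ccn) * s; u_hi <- (ucross[2] - ccn) * s
  # rows increase toward T, so the larger row index is the smaller v
  v_hi <- -(vcross[1] - cr) * s; v_lo <- -(vcross[2] - cr) * s
  center <- panel_point(u_mm = (u_lo + u_hi) / 2, v_mm = (v_lo + v_hi) / 2)
  attr(center, "edges_mm") <- c(u_lo = u_lo, u_hi = u_hi, v_lo = v_lo, v_hi = v_hi)
  attr(center, "levels") <- c(open = lv$open, baseline = lv$baseline, threshold = thr)
  center
}

cast_bb_rays <- function(px, center_rc, n_rays, r0_px, thr, step_px = 0.2) {
  phi <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  radii <- seq(0.25 * r0_px, 1.9 * r0_px, by = step_px)
  nr <- length(radii)
  # all sample coordinates at once: rows vary along radii, cols along rays
  rr <- center_rc[1] + outer(radii, sin(phi))
  cc <- center_rc[2] + outer(radii, cos(phi))
  vals <- matrix(bilinear_sample(px, as.vector(rr), as.vector(cc)), nrow = nr)
  edge_r <- rep(NA_real_, n_rays)
  for (k in seq_len(n_rays)) {
    p <- vals[, k]
    below <- p < thr
    idx <- which(below[-nr] & !below[-1])
    if (length(idx)) {
      i <- idx[1]
      frac <- (thr - p[i]) / (p[i + 1] - p[i])
      edge_r[k] <- radii[i] + frac * step_px
    }
  }
  ok <- !is.na(edge_r)
  list(row = center_rc[1] + edge_r[ok] * sin(phi[ok]),
       col = center_rc[2] + edge_r[ok] * cos(phi[ok]),
       n_cast = n_rays, n_found = sum(ok))
}

#' Fit the BB shadow centroid with a size-constrained circle fit
#'
#' Locates the ball-bearing shadow inside the radiation field and estimates
#' its center to sub-pixel accuracy: a smoothed intensity minimum provides
#' the initial guess, radial profiles are cast from it and the BB edge is
#' located on each by sub-pixel threshold crossing, and a least-squares
#' circle with radius fixed to the projected BB radius is fitted to the edge
#' points. The free-radius fit must agree with the projected BB size within
#' `radius_tolerance_frac` or the detection is rejected. The ray casting and
#' fit are repeated once from the refined center.
#'
#' @inheritParams find_field_center
#' @return An object of class `centroid_fit` with fields `center`
#'   ([panel_point()]), `fitted_radius_mm` (free-radius fit),
#'   `rms_residual_mm` and `n_edge_points`.
#' @export
fit_bb_centroid <- function(image, params = segmentation_params()) {
  stopifnot(inherits(image, "panel_image"), inherits(params, "segmentation_params"))
  fc <- find_field_center(image, params)
  lv <- attr(fc, "levels")
  edges <- attr(fc, "edges_mm")
  px <- image$pixels
  storage.mode(px) <- "double"
  g <- image$geometry
  s <- iso_scale_mm_per_px(g)
  nr <- nrow(px); nc <- ncol(px)
  cr <- (nr + 1) / 2; ccn <- (nc + 1) / 2
  r0_mm <- params$bb_diameter_mm / 2     # projected BB radius at iso scale
  r0_px <- r0_mm / s

  # BB search region: field interior, eroded so penumbra pixels cannot win
  margin_mm <- r0_mm + 2
  col_lo <- ceiling(ccn + (edges["u_lo"] + margin_mm) / s)
  col_hi <- floor(ccn + (edges["u_hi"] - margin_mm) / s)
  row_lo <- ceiling(cr - (edges["v_hi"] - margin_mm) / s)
  row_hi <- floor(cr - (edges["v_lo"] + margin_mm) / s)
  if (col_lo >= col_hi || row_lo >= row_hi)
    stop("detection error: field too small to contain the BB", call. = FALSE)
  sub <- px[row_lo:row_hi, col_lo:col_hi, drop = FALSE]
  sm <- box_smooth(sub, half = 2L)
  core <- min(sm)
  if ((lv["open"] - core) < 0.12 * (lv["open"] - lv["baseline"]))
    stop("detection error: no BB shadow found (contrast below threshold)",
         call. = FALSE)
  # centroid of the near-minimal core rather than which.min: the shadow
  # bottom is flat in noiseless images and a single argmin would sit at its
  # rim
  near <- which(sm <= core + 0.05 * (lv["open"] - core), arr.ind = TRUE)
  guess <- c(row_lo + mean(near[, 1]) - 1, col_lo + mean(near[, 2]) - 1)
  thr <- core + params$bb_level_fraction * (lv["open"] - core)

  center_px <- guess
  fit <- NULL
  for (pass in 1:2) {
    rays <- cast_bb_rays(px, center_px, params$n_rays, r0_px, thr)
    if (rays$n_found < 0.75 * rays$n_cast)
      stop("detection error: BB edge incomplete (", rays$n_found, "/",
           rays$n_cast, " rays)", call. = FALSE)
    # edge points at iso-plane scale, relative to the panel center
    ex <- (rays$col - ccn) * s
    ey <- -(rays$row - cr) * s
    free <- kasa_fit_xy(ex, ey)
    if (abs(free$radius - r0_mm) > params$radius_tolerance_frac * r0_mm)
      stop(sprintf(
        "constraint violation: free-radius fit %.3f mm deviates from projected BB radius %.3f mm by more than %g%%",
        free$radius, r0_mm, 100 * params$radius_tolerance_frac), call. = FALSE)
    ctr <- fixed_radius_center(ex, ey, r0_mm, free$center)
    fit <- list(center = ctr, free_radius = free$radius,
                rms = radial_rms(ex, ey, ctr, r0_mm),
                n = length(ex), ex = ex, ey = ey)
    center_px <- c(cr - ctr[2] / s, ccn + ctr[1] / s)
  }
  # BB must sit fully inside the field mask
  if (any(fit$ex < edges["u_lo"] + 0.2) || any(fit$ex > edges["u_hi"] - 0.2) ||
      any(fit$ey < edges["v_lo"] + 0.2) || any(fit$ey > edges["v_hi"] - 0.2))
    stop("detection error: BB overlaps the field edge", call. = FALSE)
  structure(list(center = panel_point(fit$center[1], fit$center[2]),
                 fitted_radius_mm = fit$free_radius,
                 rms_residual_mm = fit$rms,
                 n_edge_points = fit$n,
                 field_center = fc),
            class = "centroid_fit")
}

#' @export
print.centroid_fit <- function(x, ...) {
  cat(sprintf("<centroid_fit> center (%+.4f, %+.4f) mm, radius %.3f mm, RMS %.4f mm (%d edge points)\n",
              x$center$u_mm, x$center$v_mm, x$fitted_radius_mm,
              x$rms_residual_mm, x$n_edge_points))
  invisible(x)
}

# Intensity-weighted centroid of the BB shadow; internal cross-check oracle
# for fit_bb_centroid, not part of the analysis chain.
bb_centroid_intensity <- function(image, params = segmentation_params()) {
  fc <- find_field_center(image, params)
  lv <- attr(fc, "levels")
  px <- image$pixels
  storage.mode(px) <- "double"
  g <- image$geometry
  s <- iso_scale_mm_per_px(g)
  nr <- nrow(px); nc <- ncol(px)
  cr <- (nr + 1) / 2; ccn <- (nc + 1) / 2
  fit <- fit_bb_centroid(image, params)
  r0_px <- (params$bb_diameter_mm / 2) / s
  c_px <- c(cr - fit$center$v_mm / s, ccn + fit$center$u_mm / s)
  rows <- max(1, floor(c_px[1] - 1.4 * r0_px)):min(nr, ceiling(c_px[1] + 1.4 * r0_px))
  cols <- max(1, floor(c_px[2] - 1.4 * r0_px)):min(nc, ceiling(c_px[2] + 1.4 * r0_px))
  w <- pmax(lv["open"] - px[rows, cols, drop = FALSE], 0)
  rr <- outer(rows, rep(1, length(cols)))
  cc <- outer(rep(1, length(rows)), cols)
  inside <- ((rr - c_px[1])^2 + (cc - c_px[2])^2) <= (1.3 * r0_px)^2
  w[!inside] <- 0
  wr <- sum(w * rr) / sum(w); wc <- sum(w * cc) / sum(w)
  panel_point(u_mm = (wc - ccn) * s, v_mm = -(wr - cr) * s)
}
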