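#' Beam and imaging geometry
#'
#' Describes the projection geometry of a megavoltage portal acquisition:
#' source-to-isocenter distance (SAD), source-to-imager distance (SID), the
#' physical detector pixel pitch and the panel dimensions. The magnification
#' `M = SID/SAD` converts between detector-plane and isocenter-plane
#' millimeters; all analysis coordinates in this package are expressed at the
#' isocenter plane.
#'
#' @param sad_mm Source-to-isocenter distance in mm. Must be positive.
#' @param sid_mm Source-to-imager distance in mm. Must be at least `sad_mm`.
#' @param pixel_pitch_mm Physical detector pixel pitch in mm.
#' @param panel_rows,panel_cols Panel dimensions in pixels.
#'
#' @return An object of class `beam_geometry`.
#' @export
#' @examples
#' geom <- beam_geometry()
#' magnification(geom)
beam_geometry <- function(sad_mm = 1000, sid_mm = 1600,
                          pixel_pitch_mm = 0.4,
                          panel_rows = 1024L, panel_cols = 1024L) {
  stopifnot(is.numeric(sad_mm), is.numeric(sid_mm), is.numeric(pixel_pitch_mm))
  if (!is.finite(sad_mm) || sad_mm <= 0)
    stop("sad_mm must be a positive finite number", call. = FALSE)
  if (!is.finite(sid_mm) || sid_mm < sad_mm)
    stop("sid_mm must be finite and >= sad_mm", call. = FALSE)
  if (!is.finite(pixel_pitch_mm) || pixel_pitch_mm <= 0)
    stop("pixel_pitch_mm must be positive", call. = FALSE)
  panel_rows <- as.integer(panel_rows)
  panel_cols <- as.integer(panel_cols)
  if (panel_rows < 8L || panel_cols < 8L)
    stop("panel must be at least 8 x 8 pixels", call. = FALSE)
  structure(
    list(sad_mm = sad_mm, sid_mm = sid_mm, pixel_pitch_mm = pixel_pitch_mm,
         panel_rows = panel_rows, panel_cols = panel_cols),
    class = "beam_geometry"
  )
}

#' Projection magnification SID/SAD
#'
#' @param geometry A [beam_geometry()] object.
#' @return The scalar magnification factor (>= 1).
#' @export
magnification <- function(geometry) {
  stopifnot(inherits(geometry, "beam_geometry"))
  geometry$sid_mm / geometry$sad_mm
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("<beam_geometry> SAD %g mm, SID %g mm (M = %.4f), pitch %g mm, %d x %d px\n",
              x$sad_mm, x$sid_mm, magnification(x), x$pixel_pitch_mm,
              x$panel_rows, x$panel_cols))
  invisible(x)
}

#' Room-frame vector
#'
#' A 3D offset in the linac room frame. Components follow the convention used
#' throughout the package: `lat_ab_mm` is lateral, positive toward the A side;
#' `long_gt_mm` is longitudinal, positive toward the gun (G); `vert_mm` is
#' positive upward.
#'
#' @param lat_ab_mm,long_gt_mm,vert_mm Finite components in mm.
#' @return An object of class `room_vector`.
#' @export
room_vector <- function(lat_ab_mm = 0, long_gt_mm = 0, vert_mm = 0) {
  v <- c(lat_ab_mm = as.numeric(lat_ab_mm),
         long_gt_mm = as.numeric(long_gt_mm),
         vert_mm = as.numeric(vert_mm))
  if (!all(is.finite(v))) stop("room_vector components must be finite", call. = FALSE)
  structure(as.list(v), class = "room_vector")
}

#' @export
print.room_vector <- function(x, ...) {
  cat(sprintf("<room_vector> lat(A+) %+.3f, long(G+) %+.3f, vert(up+) %+.3f mm\n",
              x$lat_ab_mm, x$long_gt_mm, x$vert_mm))
  invisible(x)
}

#' Point in the MV (panel) frame at isocenter-plane scale
#'
#' `u_mm` is the crossplane coordinate (positive toward the A side at gantry
#' 0), `v_mm` the inplane coordinate (positive toward the gun), both in
#' millimeters at the isocenter plane (detector mm divided by the
#' magnification).
#'
#' @param u_mm,v_mm Finite coordinates in mm.
#' @return An object of class `panel_point`.
#' @export
panel_point <- function(u_mm = 0, v_mm = 0) {
  u_mm <- as.numeric(u_mm); v_mm <- as.numeric(v_mm)
  if (!is.finite(u_mm) || !is.finite(v_mm))
    stop("panel_point coordinates must be finite", call. = FALSE)
  structure(list(u_mm = u_mm, v_mm = v_mm), class = "panel_point")
}

#' @export
print.panel_point <- function(x, ...) {
  cat(sprintf("<panel_point> u %+.4f, v %+.4f mm (iso plane)\n", x$u_mm, x$v_mm))
  invisible(x)
}

#' Convert a pixel offset from the panel center to isocenter-plane mm
#'
#' Rows increase toward the T side, columns toward the A side, so
#' `u = col_offset * pitch / M` and `v = -row_offset * pitch / M`.
#'
#' @param row_offset,col_offset Pixel offsets from the panel center
#'   (fractional values allowed).
#' @param geometry A [beam_geometry()].
#' @return A [panel_point()].
#' @export
#' @examples
#' g <- beam_geometry(sad_mm = 1000, sid_mm = 1600, pixel_pitch_mm = 0.4)
#' panel_px_to_iso_mm(0, 10, g)  # u = 2.5 mm
panel_px_to_iso_mm <- function(row_offset, col_offset, geometry) {
  stopifnot(inherits(geometry, "beam_geometry"))
  if (!is.finite(row_offset) || !is.finite(col_offset))
    stop("pixel offsets must be finite", call. = FALSE)
  s <- geometry$pixel_pitch_mm / magnification(geometry)
  panel_point(u_mm = col_offset * s, v_mm = -row_offset * s)
}

#' Rotate a 2D point about a pivot
#'
#' Planar rotation, counterclockwise positive when viewed from above.
#'
#' @param p Numeric length-2 point (mm).
#' @param theta_deg Rotation angle in degrees.
#' @param pivot Numeric length-2 pivot point (mm).
#' @return Numeric length-2 rotated point.
#' @export
rotate_point <- function(p, theta_deg, pivot = c(0, 0)) {
  p <- as.numeric(p); pivot <- as.numeric(pivot)
  stopifnot(length(p) == 2, length(pivot) == 2)
  if (!all(is.finite(c(p, theta_deg, pivot))))
    stop("rotate_point requires finite inputs", call. = FALSE)
  th <- theta_deg * pi / 180
  d <- p - pivot
  pivot + c(cos(th) * d[1] - sin(th) * d[2],
            sin(th) * d[1] + cos(th) * d[2])
}

#' Project a room-frame offset onto the portal image
#'
#' Projects a 3D room-frame displacement into the MV frame at a given gantry
#' angle. The longitudinal component always maps to `v`; the lateral and
#' vertical components map to `u` as `u = lat * cos(gantry) + vert *
#' sin(gantry)`; the component along the beam axis does not contribute.
#'
#' @param offset A [room_vector()].
#' @param gantry_deg Gantry angle in degrees, in `[0, 360)`.
#' @param geometry A [beam_geometry()] (kept for interface symmetry; the
#'   projection at isocenter-plane scale does not depend on it).
#' @return A [panel_point()].
#' @export
project_room_to_panel <- function(offset, gantry_deg, geometry = beam_geometry()) {
  stopifnot(inherits(offset, "room_vector"))
  if (!is.finite(gantry_deg) || gantry_deg < 0 || gantry_deg >= 360)
    stop("gantry_deg must be in [0, 360)", call. = FALSE)
  g <- gantry_deg * pi / 180
  panel_point(u_mm = offset$lat_ab_mm * cos(g) + offset$vert_mm * sin(g),
              v_mm = offset$long_gt_mm)
}

# Horizontal-plane 2D coordinates used by the table kinematics:
# x = lat (A+), y = long (G+); rotations CCW-positive viewed from above.
# At gantry 0 the MV frame coincides with this plane: (u, v) = (x, y).
room_to_horizontal <- function(v) c(v$lat_ab_mm, v$long_gt_mm)

horizontal_to_room <- function(xy, vert_mm = 0) {
  room_vector(lat_ab_mm = xy[1], long_gt_mm = xy[2], vert_mm = vert_mm)
}
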