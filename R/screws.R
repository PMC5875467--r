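#' Table-base screw conversion constants
#'
#' Millimeters of rotation-axis travel per degree of fixing-screw rotation
#' for the supported table base. Rotating both base fixing screws in the
#' same direction moves the rotation axis in the gun-target (GT) plane;
#' rotating them in opposite directions moves it in the transverse (AB)
#' plane. Defaults are the vendor constants for the Elekta Precise table
#' base; other table models may override them.
#'
#' @param k_gt_mm_per_deg GT-plane travel per degree of common-mode screw
#'   rotation.
#' @param k_ab_mm_per_deg AB-plane travel per degree of differential screw
#'   rotation.
#' @return An object of class `screw_constants`.
#' @export
screw_constants <- function(k_gt_mm_per_deg = 0.01779,
                            k_ab_mm_per_deg = 0.01843) {
  stopifnot(is.finite(k_gt_mm_per_deg), k_gt_mm_per_deg > 0,
            is.finite(k_ab_mm_per_deg), k_ab_mm_per_deg > 0)
  structure(list(k_gt_mm_per_deg = k_gt_mm_per_deg,
                 k_ab_mm_per_deg = k_ab_mm_per_deg),
            class = "screw_constants")
}

#' Prescribed rotation-axis shift
#'
#' The shift of the table rotation axis required to bring it onto radiation
#' isocenter: `x_gt_mm` in the gun-target plane (positive toward the gun)
#' and `y_ab_mm` in the transverse plane (positive toward the A side).
#'
#' @param x_gt_mm,y_ab_mm Finite shifts in mm.
#' @return An object of class `adjustment_vector`.
#' @export
adjustment_vector <- function(x_gt_mm = 0, y_ab_mm = 0) {
  x_gt_mm <- as.numeric(x_gt_mm); y_ab_mm <- as.numeric(y_ab_mm)
  if (!is.finite(x_gt_mm) || !is.finite(y_ab_mm))
    stop("adjustment components must be finite", call. = FALSE)
  structure(list(x_gt_mm = x_gt_mm, y_ab_mm = y_ab_mm),
            class = "adjustment_vector")
}

#' @export
print.adjustment_vector <- function(x, ...) {
  cat(sprintf("<adjustment_vector> XGT %+.3f mm (G+), YAB %+.3f mm (A+)\n",
              x$x_gt_mm, x$y_ab_mm))
  invisible(x)
}

#' Convert a prescribed axis shift to fixing-screw rotations
#'
#' `theta_a = XGT/k_gt + YAB/k_ab` (degrees counterclockwise on the A-side
#' fixing) and `theta_b = XGT/k_gt - YAB/k_ab` (degrees clockwise on the
#' B-side fixing). Equal rotations move the axis purely in the GT plane;
#' opposite rotations purely in the AB plane.
#'
#' @param adj An [adjustment_vector()].
#' @param k A [screw_constants()].
#' @return An object of class `screw_adjustment` with `theta_a_deg`,
#'   `theta_b_deg` and the equivalent fractional `turns`.
#' @export
shifts_to_screws <- function(adj, k = screw_constants()) {
  stopifnot(inherits(adj, "adjustment_vector"), inherits(k, "screw_constants"))
  theta_a <- adj$x_gt_mm / k$k_gt_mm_per_deg + adj$y_ab_mm / k$k_ab_mm_per_deg
  theta_b <- adj$x_gt_mm / k$k_gt_mm_per_deg - adj$y_ab_mm / k$k_ab_mm_per_deg
  structure(list(theta_a_deg = theta_a, theta_b_deg = theta_b,
                 turns = c(a = theta_a / 360, b = theta_b / 360)),
            class = "screw_adjustment")
}

#' Invert fixing-screw rotations back to the axis shift
#'
#' Analytic inverse of [shifts_to_screws()]:
#' `XGT = k_gt (theta_a + theta_b)/2`, `YAB = k_ab (theta_a - theta_b)/2`.
#'
#' @param s A `screw_adjustment` (or a list with `theta_a_deg`,
#'   `theta_b_deg`).
#' @param k A [screw_constants()].
#' @return An [adjustment_vector()].
#' @export
screws_to_shifts <- function(s, k = screw_constants()) {
  stopifnot(inherits(k, "screw_constants"))
  ta <- s$theta_a_deg; tb <- s$theta_b_deg
  if (!is.finite(ta) || !is.finite(tb))
    stop("screw rotations must be finite", call. = FALSE)
  adjustment_vector(x_gt_mm = k$k_gt_mm_per_deg * (ta + tb) / 2,
                    y_ab_mm = k$k_ab_mm_per_deg * (ta - tb) / 2)
}

#' @export
print.screw_adjustment <- function(x, ...) {
  cat(sprintf("<screw_adjustment> A-side %+.1f deg CCW (%+.3f turns), B-side %+.1f deg CW (%+.3f turns)\n",
              x$theta_a_deg, x$turns["a"] , x$theta_b_deg, x$turns["b"]))
  invisible(x)
}
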