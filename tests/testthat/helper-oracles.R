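# Independent oracles used to validate the analysis-side estimators.

# Brute-force circle fit: for each candidate center on a regular grid the
# optimal radius is the mean point-to-center distance; the oracle returns the
# grid minimizer of the summed squared radial deviation.
grid_circle_fit <- function(points, center_window, grid_mm = 0.005,
                            half_width_mm = 0.3) {
  x <- points[, 1]; y <- points[, 2]
  cx <- seq(center_window[1] - half_width_mm, center_window[1] + half_width_mm,
            by = grid_mm)
  cy <- seq(center_window[2] - half_width_mm, center_window[2] + half_width_mm,
            by = grid_mm)
  best <- c(NA, NA); best_obj <- Inf
  for (b in cy) {
    dy2 <- (y - b)^2
    for (a in cx) {
      d <- sqrt((x - a)^2 + dy2)
      obj <- sum((d - mean(d))^2)
      if (obj < best_obj) {
        best_obj <- obj
        best <- c(a, b)
      }
    }
  }
  list(center = best, objective = best_obj)
}

# Noisy arc generator for circle-fit cross-checks: points on a known circle
# over a configurable arc with radial Gaussian noise.
make_noisy_arc <- function(center, radius, n = 15, arc_deg = c(-135, 135),
                           sigma = 0.02) {
  th <- seq(arc_deg[1], arc_deg[2], length.out = n) * pi / 180
  r <- radius + stats::rnorm(n, sd = sigma)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}
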