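# Shared circle-fit machinery.
#
# The algebraic (Kasa) fit linearizes x^2 + y^2 = 2ax + 2by + c and solves
# for (a, b, c) by ordinary least squares; center (a, b), radius
# sqrt(c + a^2 + b^2). The fixed-radius variant minimizes the geometric
# objective sum((|p_i - c| - r0)^2) over the center only.

kasa_fit_xy <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  qr_A <- qr(A)
  if (qr_A$rank < 3L)
    stop("degenerate geometry: points do not determine a circle", call. = FALSE)
  coef <- qr.coef(qr_A, b)
  center <- coef[1:2]
  r2 <- coef[3] + sum(center^2)
  list(center = unname(center), radius = sqrt(max(r2, 0)))
}

# Gauss-type fixed-point iteration for the fixed-radius center: the
# stationarity condition of sum((|p_i - c| - r0)^2) is
# c = mean(p) + r0 * mean((c - p_i)/|c - p_i|).
fixed_radius_center <- function(x, y, r0, center0, max_iter = 50L, tol = 1e-10) {
  c_cur <- center0
  mp <- c(mean(x), mean(y))
  for (k in seq_len(max_iter)) {
    dx <- c_cur[1] - x; dy <- c_cur[2] - y
    d <- sqrt(dx^2 + dy^2)
    d[d < 1e-12] <- 1e-12
    c_new <- mp + r0 * c(mean(dx / d), mean(dy / d))
    if (max(abs(c_new - c_cur)) < tol) {
      c_cur <- c_new
      break
    }
    c_cur <- c_new
  }
  c_cur
}

radial_rms <- function(x, y, center, r0) {
  d <- sqrt((x - center[1])^2 + (y - center[2])^2)
  sqrt(mean((d - r0)^2))
}
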