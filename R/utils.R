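# Internal geometry helpers shared across modules.

#' @noRd
.deg2rad <- function(x) x * pi / 180

#' @noRd
.rad2deg <- function(x) x * 180 / pi

# Rotation matrix about an arbitrary unit axis (Rodrigues formula).
#' @noRd
.rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- .deg2rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Rotate points about the line through p0 and p1.
#' @noRd
.rotate_about_line <- function(xyz, p0, p1, angle_deg) {
  R <- .rotation_about_axis(p1 - p0, angle_deg)
  sweep(sweep(xyz, 2, p0) %*% t(R), 2, p0, "+")
}

#' @noRd
.rotz <- function(deg) {
  th <- .deg2rad(deg)
  matrix(c(cos(th), sin(th), 0,
           -sin(th), cos(th), 0,
           0, 0, 1), 3, 3)
}

#' @noRd
.vnorm <- function(v) sqrt(sum(v^2))

#' @noRd
.angle_deg <- function(u, v) {
  cu <- u / .vnorm(u); cv <- v / .vnorm(v)
  .rad2deg(acos(pmin(1, pmax(-1, sum(cu * cv)))))
}

# Round half away from zero (table-style rounding; base round() is
# round-half-even, which does not reproduce printed one-decimal tables).
#' @export
#' @rdname aggregate_replicates
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' @noRd
.stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Optimal rigid transform (rotation R, translation t) mapping P onto Q in
# the least-squares sense, constrained to a proper rotation (SVD method).
#' @noRd
.kabsch_rt <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = cq - as.vector(R %*% cp))
}

#' @noRd
.apply_rt <- function(X, rt) sweep(X %*% t(rt$R), 2, rt$t, "+")
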