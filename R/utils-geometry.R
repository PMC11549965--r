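# Small 3D vector helpers shared by the backbone builder and analysis code.
# All coordinates are in Angstrom unless noted otherwise.

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

vcross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Dihedral angle of four points
#'
#' Signed torsion angle p1-p2-p3-p4 using the IUPAC convention (trans = 180).
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return angle in degrees in (-180, 180].
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * vunit(b2))
  atan2(y, x) * 180 / pi
}

# Angle difference wrapped to (-180, 180]
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# Least-squares plane through points (rows of P); returns unit normal and
# RMS of point-to-plane distances.
fit_plane <- function(P) {
  ctr <- colMeans(P)
  Q <- sweep(P, 2, ctr)
  sv <- svd(Q)
  normal <- sv$v[, 3]
  d <- Q %*% normal
  list(normal = normal, center = ctr, rms = sqrt(mean(d^2)))
}

# Rotation matrix about unit axis by angle (radians), Rodrigues form.
rotation_matrix <- function(axis, theta) {
  a <- vunit(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}
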