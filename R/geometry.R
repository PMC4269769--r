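# Small 3-D geometry kit shared across modules.

vnorm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector cannot be normalised")
  v / n
}

#' Rotation matrix about an axis
#' @param axis 3-vector (need not be normalised).
#' @param angle rotation angle in radians (right-handed).
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  u <- unit_vec(axis)
  c1 <- cos(angle); s1 <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  c1 * diag(3) + s1 * ux + (1 - c1) * tcrossprod(u)
}

# Quasi-uniform directions on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Angle (radians) at vertex b of points a-b-c.
angle_at <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, cosang)))
}

# Torsion angle (radians) for points p1-p2-p3-p4, in (-pi, pi].
torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / vnorm(b2)
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# NeRF: place a new atom at bond length `bond` from c, with angle b-c-new
# equal to `angle` (radians) and torsion a-b-c-new equal to `tors` (radians).
place_atom <- function(a, b, c, bond, angle, tors) {
  bc <- unit_vec(c - b)
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- unit_vec(n)
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(angle),
         bond * sin(angle) * cos(tors),
         bond * sin(angle) * sin(tors))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Centroid of selected rows of an n x 3 matrix.
centroid <- function(xyz, idx = NULL) {
  if (!is.null(idx)) xyz <- xyz[idx, , drop = FALSE]
  colMeans(xyz)
}
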