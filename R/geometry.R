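# Low-level vector geometry shared by the generator, the perturbations and
# the metrics. All angles are degrees, all lengths Angstrom.

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector", call. = FALSE)
  v / n
}

#' Internal-coordinate atom placement (natural extension reference frame)
#'
#' Places a new atom `d` bonded to `c`, given three previously placed
#' reference positions, a bond length `|d - c|`, the bond angle d-c-b and the
#' torsion angle d-c-b-a.
#'
#' @param a,b,c 3-vectors, previously placed reference atoms.
#' @param bond bond length in Angstrom.
#' @param angle bond angle d-c-b in degrees.
#' @param torsion dihedral a-b-c-d in degrees.
#' @return 3-vector with the new position.
#' @keywords internal
#' @noRd
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unit3(c - b)
  n <- cross3(b - a, bc)
  if (vnorm(n) < 1e-10) stop("degenerate (collinear) reference frame", call. = FALSE)
  n <- unit3(n)
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), -bond * sin(ang) * sin(tor))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# Bond angle p1-p2-p3 in degrees.
angle3 <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  cc <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, cc))) * 180 / pi
}

# Signed dihedral p1-p2-p3-p4 in (-180, 180] degrees. Returns NA for
# degenerate (collinear) configurations.
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) return(NA_real_)
  m1 <- cross3(n1, unit3(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Rotation matrix from a rotation vector (axis * angle, radians).
rotvec_to_mat <- function(v) {
  theta <- vnorm(v)
  if (theta < 1e-12) return(diag(3))
  k <- v / theta
  K <- matrix(c(0, k[3L], -k[2L], -k[3L], 0, k[1L], k[2L], -k[1L], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Rotation vector from a proper rotation matrix.
mat_to_rotvec <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  theta <- acos(max(-1, min(1, ct)))
  if (theta < 1e-8) return(c(0, 0, 0))
  if (abs(pi - theta) < 1e-6) {
    # near 180 degrees: extract axis from R + I
    B <- (R + diag(3)) / 2
    k <- sqrt(pmax(diag(B), 0))
    i <- which.max(k)
    k <- B[, i] / k[i]
    return(unit3(k) * theta)
  }
  ax <- c(R[3L, 2L] - R[2L, 3L], R[1L, 3L] - R[3L, 1L], R[2L, 1L] - R[1L, 2L])
  ax / (2 * sin(theta)) * theta
}

# Deterministic "random" proper rotation from a seed-driven RNG stream.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# Apply a rigid motion to an n x 3 coordinate matrix.
apply_rigid <- function(xyz, R, t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2, -t)
}
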