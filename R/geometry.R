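## Elementary 3D geometry used across the package: torsion measurement,
## internal-coordinate (NeRF) atom placement, and rotations.
## All coordinates are in Angstrom, all angles in degrees unless noted.

DEG <- pi / 180

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Torsion angle defined by four points
#'
#' IUPAC sign convention: looking from b to c, the angle is positive when
#' d rotates clockwise relative to a. Returns degrees in (-180, 180].
#'
#' @param a,b,c,d numeric xyz vectors (Angstrom).
#' @return angle in degrees.
#' @export
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unit(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) / DEG
  wrap_angle(ang)
}

bond_angle <- function(a, b, c) {
  v1 <- unit(a - b)
  v2 <- unit(c - b)
  acos(max(-1, min(1, sum(v1 * v2)))) / DEG
}

#' Wrap angles into (-180, 180]
#' @keywords internal
wrap_angle <- function(x) {
  y <- x - 360 * floor((x + 180) / 360)
  y[y <= -180] <- y[y <= -180] + 360
  y
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Given three reference positions a-b-c, place d bonded to c with the
#' given bond length, bond angle b-c-d and torsion a-b-c-d.
#'
#' @param a,b,c reference positions.
#' @param bond length c-d (Angstrom).
#' @param angle angle b-c-d (degrees).
#' @param torsion torsion a-b-c-d (degrees).
#' @return xyz of the new atom.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  bc <- unit(c - b)
  n <- unit(vcross(b - a, bc))
  m <- vcross(n, bc)
  ang <- angle * DEG
  tor <- torsion * DEG
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

#' Rotation matrix for an angle about an axis (Rodrigues form)
#'
#' @param axis rotation axis (any length > 0).
#' @param deg rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(axis, deg) {
  u <- unit(axis)
  th <- deg * DEG
  ct <- cos(th); st <- sin(th)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  matrix(c(
    ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3L, byrow = TRUE)
}

## Apply a 3x3 rotation to an N x 3 coordinate matrix.
rotate_coords <- function(xyz, R) xyz %*% t(R)

## Row-wise torsion over a matrix of atom quadruplets (index matrix, N x 4).
torsion_rows <- function(coords, idx) {
  vapply(seq_len(nrow(idx)), function(k) {
    torsion_angle(coords[idx[k, 1L], ], coords[idx[k, 2L], ],
                  coords[idx[k, 3L], ], coords[idx[k, 4L], ])
  }, numeric(1L))
}
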