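# Small 3D geometry kernel shared by the fixture builder, the CA-geometry
# secondary-structure assignment and the hinge generator.

.vnorm <- function(v) sqrt(sum(v^2))

.vunit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

.vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# angle at B (radians) for points A-B-C
.vangle <- function(a, b, c) {
  u <- .vunit(a - b); v <- .vunit(c - b)
  acos(max(-1, min(1, sum(u * v))))
}

# signed dihedral A-B-C-D (radians, IUPAC convention)
.vdihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .vcross(b1, b2); n2 <- .vcross(b2, b3)
  m1 <- .vcross(n1, .vunit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# Natural extension of reference frame (NeRF): place atom D given the three
# preceding atoms A, B, C, the bond length |C-D|, the bond angle B-C-D and
# the dihedral A-B-C-D.
.place_atom <- function(a, b, c, length, angle_deg, dihedral_deg) {
  theta <- angle_deg * pi / 180
  chi <- dihedral_deg * pi / 180
  bc <- .vunit(c - b)
  n <- .vunit(.vcross(b - a, bc))
  m <- .vcross(n, bc)
  d_local <- length * c(-cos(theta), sin(theta) * cos(chi), -sin(theta) * sin(chi))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# Rotation matrix for a right-handed rotation of `deg` degrees about `axis`
# (Rodrigues). Used by the hinge fixture and by rigid-invariance tests.
#' Rotation matrix about an axis
#'
#' @param axis Length-3 axis vector (need not be unit).
#' @param deg Rotation angle in degrees (right-handed).
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, deg) {
  u <- .vunit(axis)
  th <- deg * pi / 180
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Apply x' = R x + t to an n x 3 coordinate matrix.
.transform_coords <- function(xyz, rotation, translation) {
  sweep(xyz %*% t(rotation), 2, -translation, "-")
}
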