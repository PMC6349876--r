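# Low-level vector geometry used throughout: all coordinates are nm,
# all angles degrees unless a helper says otherwise.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Signed dihedral angle of four points
#'
#' Returns the torsion angle a-b-c-d in degrees using the IUPAC sign
#' convention (cis = 0, trans = 180, sign by right-hand rule about b->c).
#'
#' @param a,b,c,d numeric length-3 coordinate vectors (nm).
#' @return angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(a, b, c, d) {
  b0 <- a - b
  b1 <- unit(c - b)
  b2 <- d - c
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(vcross(b1, v) * w)
  ang <- atan2(y, x) * RAD2DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

# Angle a-b-c in degrees.
bond_angle <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * RAD2DEG
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given three previously placed atoms `a`, `b`, `c`, places atom `d` at
#' bond length `length` from `c`, bond angle `angle` (b-c-d) and torsion
#' `torsion` (a-b-c-d).
#'
#' @param a,b,c numeric length-3 reference coordinates (nm).
#' @param length bond length c-d in nm.
#' @param angle bond angle b-c-d in degrees.
#' @param torsion dihedral a-b-c-d in degrees.
#' @return numeric length-3 coordinates of the new atom.
#' @export
place_atom <- function(a, b, c, length, angle, torsion) {
  th <- angle * DEG2RAD
  ph <- torsion * DEG2RAD
  d_local <- c(-length * cos(th),
               length * sin(th) * cos(ph),
               length * sin(th) * sin(ph))
  bc <- unit(c - b)
  n <- unit(vcross(b - a, bc))
  m <- vcross(n, bc)
  # columns: bc, m, n form a right-handed frame at c
  c + d_local[1L] * bc + d_local[2L] * m + d_local[3L] * n
}

# Wrap an angle in degrees to (-180, 180].
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# Smallest absolute angular difference in degrees.
angle_diff <- function(a, b) {
  d <- wrap_angle(a - b)
  d
}

#' Minimal RMSD after optimal rigid superposition (Kabsch)
#'
#' Computes the least root-mean-square deviation between two coordinate
#' sets over all proper rotations and translations, via the SVD of the
#' cross-covariance matrix with the usual reflection correction.
#'
#' @param coords_a,coords_b n x 3 matrices (nm), same n, n >= 3.
#' @return RMSD in nm.
#' @export
kabsch_rmsd <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a)
  b <- as.matrix(coords_b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets differ in size")
  if (nrow(a) < 3L) stop("need at least 3 points")
  n <- nrow(a)
  ac <- a - matrix(colMeans(a), n, 3L, byrow = TRUE)
  bc <- b - matrix(colMeans(b), n, 3L, byrow = TRUE)
  h <- crossprod(ac, bc)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  sig <- s$d
  sig[3L] <- sig[3L] * d
  e <- sum(ac * ac) + sum(bc * bc) - 2 * sum(sig)
  sqrt(max(e, 0) / n)
}

# Apply the optimal rotation of Kabsch as a matrix (used by tests and
# template construction); rotates b onto a after centering both.
kabsch_rotation <- function(a, b) {
  n <- nrow(a)
  ac <- a - matrix(colMeans(a), n, 3L, byrow = TRUE)
  bc <- b - matrix(colMeans(b), n, 3L, byrow = TRUE)
  h <- crossprod(bc, ac)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  dd <- diag(c(1, 1, d))
  s$v %*% dd %*% t(s$u)
}
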