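# Internal 3D geometry helpers (vectors are length-3 numerics).

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# angle at B of A-B-C, degrees
.angle <- function(a, b, c) {
  u <- .unit(a - b); v <- .unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# Natural extension reference frame: place atom D bonded to C, given A-B-C,
# with |CD| = bond, angle(B,C,D) = ang (deg), dihedral(A,B,C,D) = dih (deg).
.nerf <- function(a, b, c, bond, ang, dih) {
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)                  # completes right-handed frame (bc, m, n)
  th <- ang * pi / 180
  ph <- dih * pi / 180
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# pairwise squared distances between rows of two matrices
.cdist2 <- function(a, b) {
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
}

.coordMatrix <- function(atoms) {
  m <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}
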