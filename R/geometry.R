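# Small 3D geometry kernel shared by all annotation modules.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

unitv <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  a / n
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

#' Torsion (dihedral) angle between four points
#'
#' Returns the IUPAC-signed torsion angle p1-p2-p3-p4 in degrees, in
#' (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (coordinates in Angstrom).
#' @return angle in degrees.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- unitv(p3 - p2)
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(vcross(b1, v) * w)
  a <- deg(atan2(y, x))
  if (a <= -180) a <- a + 360
  a
}

# Angle p1-p2-p3 in degrees.
bond_angle <- function(p1, p2, p3) {
  u <- unitv(p1 - p2)
  v <- unitv(p3 - p2)
  deg(acos(max(-1, min(1, sum(u * v)))))
}

# Rotation matrix about an arbitrary axis (Rodrigues), theta in degrees.
rotation_about_axis <- function(axis, theta) {
  u <- unitv(axis)
  th <- rad(theta)
  ct <- cos(th)
  st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# Least-squares plane through rows of X: list(center, normal).
fit_plane <- function(X) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  list(center = ctr, normal = sv$v[, 3])
}

# Acute angle between two plane normals, degrees in [0, 90].
normal_angle <- function(n1, n2) {
  a <- deg(acos(max(-1, min(1, abs(sum(unitv(n1) * unitv(n2)))))))
  a
}

# Smallest absolute difference between two angles (degrees).
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

# Deterministic, RNG-free quasi-uniform points on the unit sphere
# (golden-section spiral lattice).
sphere_lattice <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Kabsch optimal proper rotation mapping P onto Q (n x 3 matrices,
# already paired row-wise). Returns list(R, t, rmsd) such that
# P %*% R + t approximates Q in the least-squares sense.
kabsch <- function(P, Q) {
  stopifnot(is.matrix(P), is.matrix(Q), ncol(P) == 3, ncol(Q) == 3,
            nrow(P) == nrow(Q))
  n <- nrow(P)
  if (n < 3) stop("superposition requires at least 3 paired atoms")
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  # degenerate (collinear or coincident) point sets have rank < 2
  span <- svd(Pc)$d
  if (span[2] < 1e-8 * max(span[1], 1e-12)) {
    stop("degenerate point set: paired atoms are collinear or coincident")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)   # so that Pc %*% R ~ Qc
  resid <- Qc - Pc %*% R
  rmsd <- sqrt(sum(resid^2) / n)
  list(R = R, t = cq - as.vector(cp %*% R), rmsd = rmsd)
}

# Rotation angle (degrees, [0,180]) of a 3x3 proper rotation matrix.
rotation_angle <- function(R) {
  deg(acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))))
}

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}
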