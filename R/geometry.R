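#' Rigid transforms
#'
#' A `RigidTransform` is a proper rotation (3x3, det = +1) plus a
#' translation vector in Angstrom, applied as `x %*% t(R) + t`.
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation length-3 numeric vector.
#' @return An object of class `RigidTransform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation matrix must be proper (det = +1)")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation matrix must be orthogonal")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "RigidTransform")
}

#' Apply a rigid transform to coordinates
#' @param tr RigidTransform.
#' @param x n x 3 coordinate matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(tr, x) {
  x <- matrix(as.numeric(x), ncol = 3)
  sweep(x %*% t(tr$rotation), 2, tr$translation, `+`)
}

#' Least-squares superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimizing the RMSD between
#' matched atom sets. Reflections are excluded: the returned rotation
#' always has determinant +1, even for mirrored inputs.
#'
#' @param mobile,reference Structures sharing topology over `sel`.
#' @param sel [atom_selection()]; default all-heavy.
#' @return list with `transform` (RigidTransform) and `rmsd` (Angstrom,
#'   after applying the transform to `mobile`).
#' @export
superpose <- function(mobile, reference, sel = atom_selection()) {
  m <- match_atoms(mobile, reference, sel)
  X <- coords(mobile, m$a)
  Y <- coords(reference, m$b)
  kb <- kabsch(X, Y)
  list(transform = kb$transform, rmsd = kb$rmsd)
}

# Kabsch on raw n x 3 matrices; X mobile, Y reference.
kabsch <- function(X, Y) {
  n <- nrow(X)
  if (n < 3) stop("need at least 3 matched atoms for superposition")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- crossprod(Xc, Yc)                    # 3x3 covariance
  sv <- svd(H)
  # collinearity: rank < 2 leaves the rotation underdetermined
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300))
    stop("degenerate geometry: matched atoms are collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  tvec <- cy - as.numeric(R %*% cx)
  tr <- rigid_transform(R, tvec)
  fitted <- apply_transform(tr, X)
  list(transform = tr, rmsd = sqrt(mean(rowSums((fitted - Y)^2))))
}

#' Root-mean-square deviation between two structures
#'
#' @param a,b Structures sharing topology over `sel`.
#' @param sel [atom_selection()].
#' @param fit logical; superpose `a` onto `b` first (default TRUE). With
#'   `fit = FALSE` the raw coordinate RMSD is returned.
#' @return RMSD in Angstrom.
#' @export
rmsd_between <- function(a, b, sel = atom_selection(), fit = TRUE) {
  m <- match_atoms(a, b, sel)
  X <- coords(a, m$a)
  Y <- coords(b, m$b)
  if (fit) kabsch(X, Y)$rmsd else sqrt(mean(rowSums((X - Y)^2)))
}

# Dihedral angle (degrees, in (-180, 180]) defined by four points.
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Angle (degrees) at vertex p2.
bond_angle <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# Place a fourth atom from three reference atoms and internal coordinates
# (NeRF construction): bond length to c, angle b-c-x, dihedral a-b-c-x.
place_atom <- function(a, b, c, length, angle, dih) {
  ang <- angle * pi / 180
  tor <- -dih * pi / 180   # sign matches the dihedral() convention
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-length * cos(ang),
         length * sin(ang) * cos(tor),
         length * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Rotation matrix for angle (degrees) about unit axis (Rodrigues).
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
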