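# Rigid-body geometry: quaternions, Kabsch superposition, poses, slerp.
#
# Quaternion convention: (w, x, y, z), unit norm, canonical sign w >= 0
# (the double cover q and -q describe the same rotation).

#' Normalise a quaternion to unit norm and canonical sign
#' @param q numeric length-4 `(w, x, y, z)`.
#' @return Unit quaternion with `w >= 0`.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("zero-norm quaternion")
  q <- q / n
  if (q[1] < 0) q <- -q
  q
}

#' Quaternion product `a %*% b` (rotation a after rotation b)
#' @param a,b quaternions `(w, x, y, z)`.
#' @return The product quaternion.
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Quaternion conjugate (inverse rotation for unit quaternions)
#' @param q quaternion.
#' @return Conjugated quaternion.
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Rotation matrix from a unit quaternion
#' @param q unit quaternion `(w, x, y, z)`.
#' @return 3 x 3 proper rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Unit quaternion from a proper rotation matrix
#' @param R 3 x 3 rotation matrix, `det(R) = +1`.
#' @return Unit quaternion `(w, x, y, z)` with `w >= 0`.
#' @export
quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  quat_normalize(q)
}

#' Rotation angle of a unit quaternion, in degrees
#' @param q unit quaternion.
#' @return Angle in `[0, 180]` degrees.
#' @export
quat_angle <- function(q) {
  2 * atan2(sqrt(sum(q[2:4]^2)), abs(q[1])) * 180 / pi
}

#' Angle between two orientations, in degrees
#' @param q0,q1 unit quaternions.
#' @return Rotation angle taking `q0` to `q1`, degrees in `[0, 180]`.
#' @export
quat_angle_between <- function(q0, q1) {
  quat_angle(quat_multiply(quat_conjugate(q0), q1))
}

#' Spherical linear interpolation between unit quaternions
#'
#' Constant-angular-velocity interpolation along the shortest arc; an
#' antipodal pair (`dot < 0`) is resolved by negating `q1` before
#' interpolating.
#'
#' @param q0,q1 unit quaternions.
#' @param t interpolation parameter in `[0, 1]`.
#' @return Unit quaternion; `slerp(q0, q1, 0) == q0` and
#'   `slerp(q0, q1, 1)` equals `q1` up to the sign convention.
#' @export
slerp <- function(q0, q1, t) {
  q0 <- quat_normalize(q0)
  q1 <- quat_normalize(q1)
  d <- sum(q0 * q1)
  if (d < 0) { q1 <- -q1; d <- -d }
  if (d > 1 - 1e-12) {
    out <- q0 + t * (q1 - q0)  # nearly parallel: linear is exact enough
    return(quat_normalize(out))
  }
  th <- acos(pmin(1, d))
  out <- (sin((1 - t) * th) * q0 + sin(t * th) * q1) / sin(th)
  quat_normalize(out)
}

#' Affine interpolation of centres
#' @param c0,c1 3-vectors.
#' @param t parameter in `[0, 1]`.
#' @return `(1 - t) * c0 + t * c1`.
#' @export
lerp_center <- function(c0, c1, t) (1 - t) * c0 + t * c1

#' Create a RigidPose
#' @param center 3-vector (Angstrom).
#' @param q unit quaternion (normalised and sign-canonicalised on input).
#' @return An object of class `RigidPose`.
#' @export
rigid_pose <- function(center = c(0, 0, 0), q = c(1, 0, 0, 0)) {
  structure(list(center = as.numeric(center), q = quat_normalize(q)),
            class = "RigidPose")
}

#' @export
print.RigidPose <- function(x, ...) {
  cat(sprintf("RigidPose: center (%.3f, %.3f, %.3f), angle %.3f deg\n",
              x$center[1], x$center[2], x$center[3], quat_angle(x$q)))
  invisible(x)
}

#' Optimal weighted superposition (Kabsch, via SVD)
#'
#' Finds the proper rotation and translation minimising the weighted RMSD of
#' `mobile` onto `reference`.  The returned pose maps centred reference
#' coordinates into the mobile frame; `xyz_fit` are the mobile coordinates
#' after superposition onto the reference.
#'
#' @param mobile,reference n x 3 coordinate matrices, `n >= 3`, not all
#'   collinear.
#' @param weights optional per-atom non-negative weights.
#' @return List with `rotation` (3 x 3, applied to centred mobile), `pose`
#'   (a [rigid_pose()] holding the mobile centroid and the orientation of the
#'   mobile relative to the reference), `rmsd` (Angstrom) and `xyz_fit`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference))
    stop("point counts differ")
  n <- nrow(mobile)
  if (n < 3) stop("degenerate geometry: need at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  X <- sweep(mobile, 2, cm)
  Y <- sweep(reference, 2, cr)
  # collinearity check on the mobile cloud
  sv_check <- svd(X * sqrt(w))$d
  if (sv_check[2] < 1e-9 * max(sv_check[1], 1))
    stop("degenerate geometry: points are (nearly) collinear")
  H <- t(X * w) %*% Y      # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)     # rotation applied to centred mobile
  Xr <- X %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((Xr - Y)^2)))
  xyz_fit <- sweep(Xr, 2, cr, FUN = "+")
  pose <- rigid_pose(center = cm, q = quat_from_matrix(t(R)))
  list(rotation = R, pose = pose, rmsd = rmsd, xyz_fit = xyz_fit)
}

#' Weighted/unweighted RMSD between two coordinate sets (no superposition)
#' @param a,b n x 3 matrices.
#' @param weights optional per-atom weights.
#' @return RMSD in Angstrom.
#' @export
rmsd_raw <- function(a, b, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(a))
  w <- weights / sum(weights)
  sqrt(sum(w * rowSums((as.matrix(a) - as.matrix(b))^2)))
}

#' Rigid pose of a conformation relative to a reference
#'
#' The pose `p` is defined so that applying `p` to the centred reference
#' selection ([apply_pose()]) reproduces the conformation's selected atoms:
#' `center` is the selection centroid of `conf` and `q` the optimal rotation
#' taking the centred reference onto the centred conformation.
#'
#' @param conf a [conformation()] (or bare coordinate matrix).
#' @param ref reference [conformation()] (or matrix).
#' @param sel selection applied to both (default: all atoms).
#' @return A [rigid_pose()].
#' @export
pose_of <- function(conf, ref, sel = NULL) {
  xc <- if (inherits(conf, "Conformation")) conf$xyz else as.matrix(conf)
  xr <- if (inherits(ref, "Conformation")) ref$xyz else as.matrix(ref)
  idx <- resolve_selection(sel, nrow(xc))
  fit <- kabsch_superpose(xr[idx, , drop = FALSE], xc[idx, , drop = FALSE])
  # fit$rotation takes centred reference onto centred conf
  rigid_pose(center = colMeans(xc[idx, , drop = FALSE]),
             q = quat_from_matrix(fit$rotation))
}

#' Apply a rigid pose to centred coordinates
#' @param xyz_centered n x 3 matrix with zero centroid.
#' @param pose a [rigid_pose()].
#' @return Rotated and translated coordinates.
#' @export
apply_pose <- function(xyz_centered, pose) {
  R <- quat_to_matrix(pose$q)
  sweep(as.matrix(xyz_centered) %*% t(R), 2, pose$center, FUN = "+")
}
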