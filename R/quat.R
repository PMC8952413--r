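## Quaternion rotation algebra.
##
## Quaternions are stored scalar-first as numeric vectors c(w, x, y, z), or as
## n x 4 matrices for time series (one row per frame). q and -q denote the
## same rotation; every angle computation below is invariant to that sign.

#' Construct a unit quaternion
#'
#' Builds a scalar-first unit quaternion `c(w, x, y, z)`. The components are
#' renormalized on construction; a zero or non-finite quaternion is rejected.
#'
#' @param w,x,y,z Real components, scalar (`w`) first.
#' @return A numeric vector of length 4 with unit norm.
#' @examples
#' quat(1, 0, 0, 0)            # identity rotation
#' quat(1, 0, 0, 1)            # 90 degrees about z (renormalized)
#' @export
quat <- function(w, x = 0, y = 0, z = 0) {
  if (length(w) == 4 && missing(x)) {
    q <- as.numeric(w)
  } else {
    q <- c(w, x, y, z)
  }
  quat_normalize(q)
}

#' Identity quaternion
#' @return The unit quaternion `c(1, 0, 0, 0)`.
#' @export
quat_identity <- function() c(1, 0, 0, 0)

#' Quaternion from an axis and an angle
#'
#' @param axis Rotation axis, length-3 numeric (need not be unit length).
#' @param angle_deg Rotation angle in degrees.
#' @return A unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  stopifnot(length(axis) == 3, all(is.finite(axis)), is.finite(angle_deg))
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("rotation axis must be non-zero")
  half <- angle_deg * pi / 360
  c(cos(half), sin(half) * axis / n)
}

## Coerce a vector or n x 4 matrix to an n x 4 row matrix.
as_quat_matrix <- function(q) {
  if (is.matrix(q)) {
    if (ncol(q) != 4) stop("quaternion matrix must have 4 columns (w, x, y, z)")
    q
  } else {
    if (length(q) != 4) stop("a quaternion has 4 components (w, x, y, z)")
    matrix(q, nrow = 1)
  }
}

#' Renormalize quaternions to unit norm
#'
#' @param q A length-4 vector or an n x 4 matrix of quaternions.
#' @return The input scaled row-wise to unit norm. Zero or non-finite rows
#'   are rejected with an error.
#' @export
quat_normalize <- function(q) {
  m <- as_quat_matrix(q)
  if (!all(is.finite(m))) stop("quaternion components must be finite")
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm < 1e-12)) stop("cannot normalize a zero quaternion")
  out <- m / nrm
  if (!is.matrix(q)) out <- drop(out)
  out
}

#' Quaternion (Hamilton) product
#'
#' Composes two rotations: `qmul(a, b)` applies `b` first, then `a`, matching
#' the rotation-matrix product `quat_to_matrix(a) %*% quat_to_matrix(b)`.
#' Inputs may be single quaternions or aligned n x 4 matrices (rows are
#' multiplied pairwise; a single quaternion is recycled against a matrix).
#'
#' @param a,b Unit quaternions (length-4 vectors or n x 4 matrices).
#' @return The renormalized composition, in the shape of the larger input.
#' @export
qmul <- function(a, b) {
  am <- as_quat_matrix(a)
  bm <- as_quat_matrix(b)
  if (!all(is.finite(am)) || !all(is.finite(bm)))
    stop("quaternion components must be finite")
  n <- max(nrow(am), nrow(bm))
  if (nrow(am) == 1 && n > 1) am <- am[rep(1, n), , drop = FALSE]
  if (nrow(bm) == 1 && n > 1) bm <- bm[rep(1, n), , drop = FALSE]
  if (nrow(am) != nrow(bm)) stop("quaternion series lengths differ")
  w <- am[, 1] * bm[, 1] - am[, 2] * bm[, 2] - am[, 3] * bm[, 3] - am[, 4] * bm[, 4]
  x <- am[, 1] * bm[, 2] + am[, 2] * bm[, 1] + am[, 3] * bm[, 4] - am[, 4] * bm[, 3]
  y <- am[, 1] * bm[, 3] - am[, 2] * bm[, 4] + am[, 3] * bm[, 1] + am[, 4] * bm[, 2]
  z <- am[, 1] * bm[, 4] + am[, 2] * bm[, 3] - am[, 3] * bm[, 2] + am[, 4] * bm[, 1]
  out <- quat_normalize(cbind(w, x, y, z))
  dimnames(out) <- NULL
  if (!is.matrix(a) && !is.matrix(b)) out <- drop(out)
  out
}

#' Quaternion inverse (conjugate)
#'
#' For unit quaternions the inverse is the conjugate:
#' `qmul(q, qinv(q))` is the identity rotation.
#'
#' @param q A unit quaternion or n x 4 matrix of them.
#' @return The inverse rotation(s), same shape as the input.
#' @export
qinv <- function(q) {
  m <- as_quat_matrix(quat_normalize(q))
  out <- cbind(m[, 1], -m[, 2], -m[, 3], -m[, 4])
  dimnames(out) <- NULL
  if (!is.matrix(q)) out <- drop(out)
  out
}

#' Relative rotation angle between orientations
#'
#' The geodesic angle theta = (360 / pi) * acos(clamp(|<a, b>|, 0, 1)) in
#' degrees, in the range 0 to 180. The absolute value of the inner product
#' makes the angle invariant to the quaternion double cover (q vs -q).
#'
#' @param a,b Unit quaternions or aligned n x 4 matrices.
#' @return Angle(s) in degrees; a scalar for single quaternions, a vector for
#'   series.
#' @export
angle_between <- function(a, b) {
  am <- as_quat_matrix(quat_normalize(a))
  bm <- as_quat_matrix(quat_normalize(b))
  n <- max(nrow(am), nrow(bm))
  if (nrow(am) == 1 && n > 1) am <- am[rep(1, n), , drop = FALSE]
  if (nrow(bm) == 1 && n > 1) bm <- bm[rep(1, n), , drop = FALSE]
  if (nrow(am) != nrow(bm)) stop("quaternion series lengths differ")
  d <- pmin(pmax(abs(rowSums(am * bm)), 0), 1)
  drop((360 / pi) * acos(d))
}

#' Average of unit quaternions
#'
#' The eigenvector average (Markley method): the mean rotation is the
#' principal eigenvector of the sum of outer products `q q^T`, which is
#' invariant to a sign flip of any input quaternion.
#'
#' @param qs A list of unit quaternions, or an n x 4 matrix with one
#'   quaternion per row.
#' @param weights Optional non-negative weights, one per quaternion.
#' @return The average unit quaternion (sign chosen with non-negative `w`).
#' @export
quat_average <- function(qs, weights = NULL) {
  if (is.list(qs)) {
    if (length(qs) == 0) stop("cannot average an empty set of quaternions")
    qs <- do.call(rbind, lapply(qs, as.numeric))
  }
  m <- as_quat_matrix(qs)
  if (nrow(m) == 0) stop("cannot average an empty set of quaternions")
  m <- quat_normalize(m)
  if (is.null(weights)) weights <- rep(1, nrow(m))
  stopifnot(length(weights) == nrow(m), all(weights >= 0), sum(weights) > 0)
  A <- crossprod(m * sqrt(weights))  # sum_i w_i q_i q_i^T
  ev <- eigen(A, symmetric = TRUE)
  q <- ev$vectors[, 1]
  if (q[1] < 0) q <- -q
  quat_normalize(q)
}

#' Convert a unit quaternion to a rotation matrix
#'
#' @param q A unit quaternion (scalar-first).
#' @return A 3 x 3 rotation matrix (orthonormal, determinant +1).
#' @export
quat_to_matrix <- function(q) {
  q <- quat_normalize(as.numeric(as_quat_matrix(q)[1, ]))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Convert a rotation matrix to a unit quaternion
#'
#' Uses Shepperd's branch selection for numerical stability. The matrix must
#' be orthonormal with determinant +1; deviations beyond `tol` are rejected
#' with a report of the measured error.
#'
#' @param M A 3 x 3 rotation matrix.
#' @param tol Orthonormality / determinant tolerance.
#' @return A unit quaternion `c(w, x, y, z)` with `w >= 0`.
#' @export
quat_from_matrix <- function(M, tol = 1e-6) {
  stopifnot(is.matrix(M), all(dim(M) == c(3, 3)), all(is.finite(M)))
  orth_err <- max(abs(crossprod(M) - diag(3)))
  det_err <- abs(det(M) - 1)
  if (orth_err > tol || det_err > tol) {
    stop(sprintf(
      "not a rotation matrix: orthonormality error %.3g, determinant error %.3g (tolerance %.3g)",
      orth_err, det_err, tol))
  }
  tr <- sum(diag(M))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (M[3, 2] - M[2, 3]) / s,
           (M[1, 3] - M[3, 1]) / s,
           (M[2, 1] - M[1, 2]) / s)
  } else if (M[1, 1] > M[2, 2] && M[1, 1] > M[3, 3]) {
    s <- sqrt(1 + M[1, 1] - M[2, 2] - M[3, 3]) * 2
    q <- c((M[3, 2] - M[2, 3]) / s,
           0.25 * s,
           (M[1, 2] + M[2, 1]) / s,
           (M[1, 3] + M[3, 1]) / s)
  } else if (M[2, 2] > M[3, 3]) {
    s <- sqrt(1 + M[2, 2] - M[1, 1] - M[3, 3]) * 2
    q <- c((M[1, 3] - M[3, 1]) / s,
           (M[1, 2] + M[2, 1]) / s,
           0.25 * s,
           (M[2, 3] + M[3, 2]) / s)
  } else {
    s <- sqrt(1 + M[3, 3] - M[1, 1] - M[2, 2]) * 2
    q <- c((M[2, 1] - M[1, 2]) / s,
           (M[1, 3] + M[3, 1]) / s,
           (M[2, 3] + M[3, 2]) / s,
           0.25 * s)
  }
  if (q[1] < 0) q <- -q
  quat_normalize(q)
}

#' Rotate 3-vectors by quaternions
#'
#' Applies the rotation(s) `q` to the vector(s) `v` without forming rotation
#' matrices. Rows are paired; a single quaternion or vector is recycled.
#'
#' @param q A unit quaternion or n x 4 matrix.
#' @param v A length-3 vector or n x 3 matrix.
#' @return The rotated vector(s), same shape as `v` (or expanded to n x 3).
#' @export
quat_rotate <- function(q, v) {
  qm <- as_quat_matrix(quat_normalize(q))
  vm <- if (is.matrix(v)) v else matrix(v, nrow = 1)
  if (ncol(vm) != 3) stop("vectors must have 3 components")
  n <- max(nrow(qm), nrow(vm))
  if (nrow(qm) == 1 && n > 1) qm <- qm[rep(1, n), , drop = FALSE]
  if (nrow(vm) == 1 && n > 1) vm <- vm[rep(1, n), , drop = FALSE]
  if (nrow(qm) != nrow(vm)) stop("series lengths differ")
  w <- qm[, 1]; u <- qm[, 2:4, drop = FALSE]
  ## v' = v + 2 w (u x v) + 2 u x (u x v)
  uxv <- cbind(u[, 2] * vm[, 3] - u[, 3] * vm[, 2],
               u[, 3] * vm[, 1] - u[, 1] * vm[, 3],
               u[, 1] * vm[, 2] - u[, 2] * vm[, 1])
  t2 <- uxv * 2
  uxt <- cbind(u[, 2] * t2[, 3] - u[, 3] * t2[, 2],
               u[, 3] * t2[, 1] - u[, 1] * t2[, 3],
               u[, 1] * t2[, 2] - u[, 2] * t2[, 1])
  out <- vm + w * t2 + uxt
  dimnames(out) <- NULL
  if (!is.matrix(v) && !is.matrix(q)) out <- drop(out)
  out
}
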