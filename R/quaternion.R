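#' Quaternion and rotation-matrix utilities
#'
#' Orientation samples are stored as unit quaternions in scalar-first
#' (w, x, y, z) Hamilton convention. These helpers convert between the
#' quaternion and 3x3 direction-cosine (rotation matrix) representations and
#' implement the small algebra the kinematics layer needs. All functions are
#' vectorised over rows: a quaternion set is an n x 4 numeric matrix, a
#' rotation set an array of dim c(3, 3, n).
#'
#' @param q numeric matrix with 4 columns (w, x, y, z), one row per sample.
#' @name quaternion-tools
NULL

#' @describeIn quaternion-tools Normalize each row to unit norm.
#' @export
quat_normalize <- function(q) {
  q <- as.matrix(q)
  nrm <- sqrt(rowSums(q^2))
  if (any(nrm < 1e-12)) {
    stop_tremorkin("cannot normalize a zero quaternion")
  }
  q / nrm
}

#' @describeIn quaternion-tools Hamilton product of row-aligned quaternion sets.
#' @param p numeric matrix with 4 columns, same number of rows as `q`.
#' @export
quat_multiply <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  cbind(
    p[, 1] * q[, 1] - p[, 2] * q[, 2] - p[, 3] * q[, 3] - p[, 4] * q[, 4],
    p[, 1] * q[, 2] + p[, 2] * q[, 1] + p[, 3] * q[, 4] - p[, 4] * q[, 3],
    p[, 1] * q[, 3] - p[, 2] * q[, 4] + p[, 3] * q[, 1] + p[, 4] * q[, 2],
    p[, 1] * q[, 4] + p[, 2] * q[, 3] - p[, 3] * q[, 2] + p[, 4] * q[, 1]
  )
}

#' @describeIn quaternion-tools Conjugate (w, -x, -y, -z).
#' @export
quat_conjugate <- function(q) {
  q <- as.matrix(q)
  cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4])
}

#' @describeIn quaternion-tools Convert unit quaternions to rotation matrices.
#' @export
quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  n <- nrow(q)
  out <- array(0, dim = c(3, 3, n))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  out[1, 1, ] <- 1 - 2 * (y^2 + z^2)
  out[1, 2, ] <- 2 * (x * y - w * z)
  out[1, 3, ] <- 2 * (x * z + w * y)
  out[2, 1, ] <- 2 * (x * y + w * z)
  out[2, 2, ] <- 1 - 2 * (x^2 + z^2)
  out[2, 3, ] <- 2 * (y * z - w * x)
  out[3, 1, ] <- 2 * (x * z - w * y)
  out[3, 2, ] <- 2 * (y * z + w * x)
  out[3, 3, ] <- 1 - 2 * (x^2 + y^2)
  out
}

#' @describeIn quaternion-tools Convert rotation matrices (3 x 3 x n array) to
#'   unit quaternions via Shepperd's method; the sign is fixed so consecutive
#'   samples stay in the same hemisphere.
#' @param R array of dim c(3, 3, n) of rotation matrices.
#' @export
matrix_to_quat <- function(R) {
  if (length(dim(R)) == 2) R <- array(R, dim = c(3, 3, 1))
  n <- dim(R)[3]
  q <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    m <- R[, , i]
    tr <- m[1, 1] + m[2, 2] + m[3, 3]
    if (tr > 0) {
      s <- sqrt(tr + 1) * 2
      q[i, ] <- c(s / 4, (m[3, 2] - m[2, 3]) / s,
                  (m[1, 3] - m[3, 1]) / s, (m[2, 1] - m[1, 2]) / s)
    } else {
      k <- which.max(c(m[1, 1], m[2, 2], m[3, 3]))
      if (k == 1) {
        s <- sqrt(1 + m[1, 1] - m[2, 2] - m[3, 3]) * 2
        q[i, ] <- c((m[3, 2] - m[2, 3]) / s, s / 4,
                    (m[1, 2] + m[2, 1]) / s, (m[1, 3] + m[3, 1]) / s)
      } else if (k == 2) {
        s <- sqrt(1 + m[2, 2] - m[1, 1] - m[3, 3]) * 2
        q[i, ] <- c((m[1, 3] - m[3, 1]) / s, (m[1, 2] + m[2, 1]) / s,
                    s / 4, (m[2, 3] + m[3, 2]) / s)
      } else {
        s <- sqrt(1 + m[3, 3] - m[1, 1] - m[2, 2]) * 2
        q[i, ] <- c((m[2, 1] - m[1, 2]) / s, (m[1, 3] + m[3, 1]) / s,
                    (m[2, 3] + m[3, 2]) / s, s / 4)
      }
    }
  }
  q <- quat_normalize(q)
  # hemisphere continuity: flip rows whose dot with the previous row is < 0
  if (n > 1) {
    for (i in 2:n) {
      if (sum(q[i, ] * q[i - 1, ]) < 0) q[i, ] <- -q[i, ]
    }
  }
  q
}

#' @describeIn quaternion-tools Rotation matrix for a rotation of `angle`
#'   radians about unit `axis` (right-handed).
#' @param axis length-3 numeric, need not be normalized.
#' @param angle rotation angle in radians.
#' @export
axis_angle_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# project an almost-orthonormal matrix back onto SO(3) via polar decomposition
reorthonormalize <- function(m) {
  s <- svd(m)
  r <- s$u %*% t(s$v)
  if (det(r) < 0) {
    s$u[, 3] <- -s$u[, 3]
    r <- s$u %*% t(s$v)
  }
  r
}
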