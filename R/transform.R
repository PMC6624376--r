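## Rigid-body transforms parameterized by unit quaternions.
##
## A transform rotates coordinates about a stated center and then translates:
## x' = R(q) (x - center) + center + t.  Rotating about the moving molecule's
## centroid (rather than the lab origin) keeps rotation and translation
## parameters decoupled during optimization.

#' Construct a rigid transform
#'
#' @param quaternion length-4 numeric `(w, x, y, z)`; normalized internally.
#' @param translation length-3 numeric, Angstrom.
#' @param center rotation center, Angstrom (default origin).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(quaternion = c(1, 0, 0, 0),
                            translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  q <- as.numeric(quaternion)
  stopifnot(length(q) == 4, length(translation) == 3, length(center) == 3)
  nq <- sqrt(sum(q^2))
  if (!is.finite(nq) || nq < 1e-12) stop("degenerate quaternion")
  structure(list(q = q / nq, t = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid transform q = (%.4f, %.4f, %.4f, %.4f), t = (%.3f, %.3f, %.3f) A>\n",
              x$q[1], x$q[2], x$q[3], x$q[4], x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

#' Rotation matrix of a unit quaternion
#' @param q length-4 numeric `(w, x, y, z)`.
#' @return 3x3 rotation matrix.
#' @export
quaternion_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

matrix_to_quaternion <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q / sqrt(sum(q^2))
}

#' Apply a rigid transform to coordinates
#' @param transform a `rigid_transform`.
#' @param xyz n x 3 coordinate matrix (or a `molecule`).
#' @return transformed coordinates (or molecule).
#' @export
apply_transform <- function(transform, xyz) {
  if (inherits(xyz, "molecule")) {
    return(set_coords(xyz, apply_transform(transform, coords(xyz))))
  }
  xyz <- as.matrix(xyz)
  R <- quaternion_to_matrix(transform$q)
  shifted <- sweep(xyz, 2, transform$center)
  sweep(shifted %*% t(R), 2, transform$center + transform$t, FUN = "+")
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return the inverse `rigid_transform` (same rotation center convention).
#' @export
invert_transform <- function(transform) {
  R <- quaternion_to_matrix(transform$q)
  ## x' = R(x - c) + c + t  =>  x = R^T (x' - c - t) + c
  ## expressed about the same center c: x = Rinv (x' - c) + c + tinv with
  ## tinv = Rinv %*% (-t)
  qinv <- c(transform$q[1], -transform$q[2:4])
  tinv <- as.numeric(t(R) %*% (-transform$t))
  rigid_transform(qinv, tinv, transform$center)
}

random_unit_quaternion <- function(n = 1) {
  m <- matrix(rnorm(4 * n), ncol = 4)
  m / sqrt(rowSums(m^2))
}
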