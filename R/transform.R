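#' Rigid transforms about a pivot
#'
#' A rigid transform is parameterized by three Euler rotations in degrees about
#' the sagittal (x), coronal (y) and transverse (z) axes, applied in the fixed
#' order sagittal -> coronal -> transverse about a stated pivot point, followed
#' by a translation in mm:
#' \deqn{p' = R (p - v) + v + t}
#' where \eqn{R = R_z R_y R_x}, \eqn{v} is the pivot and \eqn{t} the
#' translation. The coordinate frame is right-handed and patient-like:
#' x = left, y = posterior, z = toward the head, all in mm.
#'
#' @param euler_deg numeric length 3: rotations (sagittal, coronal, transverse)
#'   in degrees.
#' @param translation numeric length 3, mm.
#' @param pivot numeric length 3, mm; the point the rotations act about.
#' @return An object of class `rigid_transform`.
#' @examples
#' t1 <- rigid_transform(c(10, 0, 0), c(1, 2, 3))
#' pts <- matrix(rnorm(30), ncol = 3)
#' max(abs(transform_points(invert_transform(t1), transform_points(t1, pts)) - pts))
#' @export
rigid_transform <- function(euler_deg = c(0, 0, 0),
                            translation = c(0, 0, 0),
                            pivot = c(0, 0, 0)) {
  stopifnot(length(euler_deg) == 3, length(translation) == 3, length(pivot) == 3)
  if (!all(is.finite(c(euler_deg, translation, pivot)))) {
    abort("rigid_transform parameters must be finite", class = "emmfuse_error")
  }
  structure(
    list(
      euler_deg = as.numeric(euler_deg),
      translation = as.numeric(translation),
      pivot = as.numeric(pivot),
      rotation = euler_to_matrix(euler_deg)
    ),
    class = "rigid_transform"
  )
}

#' Build a rigid transform directly from a rotation matrix
#'
#' @param rotation 3x3 orthonormal rotation matrix (det +1).
#' @inheritParams rigid_transform
#' @return A `rigid_transform` whose Euler angles are recovered from `rotation`.
#' @export
rigid_transform_from_matrix <- function(rotation, translation = c(0, 0, 0),
                                        pivot = c(0, 0, 0)) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)))
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    abort("rotation must be a proper orthonormal matrix", class = "emmfuse_error")
  }
  t <- rigid_transform(matrix_to_euler(rotation), translation, pivot)
  t$rotation <- rotation  # keep the exact matrix, not the re-synthesized one
  t
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat(sprintf("  euler (sag, cor, trans) deg: %8.3f %8.3f %8.3f\n",
              x$euler_deg[1], x$euler_deg[2], x$euler_deg[3]))
  cat(sprintf("  translation mm:              %8.3f %8.3f %8.3f\n",
              x$translation[1], x$translation[2], x$translation[3]))
  cat(sprintf("  pivot mm:                    %8.3f %8.3f %8.3f\n",
              x$pivot[1], x$pivot[2], x$pivot[3]))
  invisible(x)
}

#' Euler angles (degrees) to rotation matrix
#'
#' Order: sagittal (x), then coronal (y), then transverse (z):
#' `R = Rz %*% Ry %*% Rx`.
#'
#' @param euler_deg numeric length 3.
#' @return 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(euler_deg) {
  a <- euler_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Rotation matrix to Euler angles (degrees)
#'
#' Inverse of [euler_to_matrix()]; returns angles in (-180, 180], coronal in
#' [-90, 90].
#'
#' @param R 3x3 rotation matrix.
#' @return numeric length 3 (sagittal, coronal, transverse) in degrees.
#' @export
matrix_to_euler <- function(R) {
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  coronal <- asin(sy)
  if (abs(abs(sy) - 1) < 1e-12) {
    # gimbal lock: fold transverse into sagittal
    sagittal <- atan2(-R[2, 3], R[2, 2])
    transverse <- 0
  } else {
    sagittal <- atan2(R[3, 2], R[3, 3])
    transverse <- atan2(R[2, 1], R[1, 1])
  }
  c(sagittal, coronal, transverse) * 180 / pi
}

#' Apply a rigid transform to points
#'
#' @param transform a `rigid_transform`.
#' @param points an n x 3 matrix, a length-3 vector, or a data frame with
#'   columns `x`, `y`, `z` (other columns pass through).
#' @return Same shape as `points`, transformed.
#' @export
transform_points <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (is.data.frame(points)) {
    m <- as.matrix(points[, c("x", "y", "z")])
    m2 <- transform_points(transform, m)
    points$x <- m2[, 1]; points$y <- m2[, 2]; points$z <- m2[, 3]
    return(points)
  }
  vec <- is.null(dim(points))
  m <- if (vec) matrix(points, ncol = 3) else as.matrix(points)
  ctr <- sweep(m, 2, transform$pivot)
  out <- ctr %*% t(transform$rotation)
  out <- sweep(out, 2, transform$pivot + transform$translation, "+")
  if (vec) drop(out) else out
}

#' Invert a rigid transform
#'
#' @param transform a `rigid_transform`.
#' @return The inverse `rigid_transform` (same pivot).
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform_from_matrix(Rt, -drop(Rt %*% transform$translation),
                              transform$pivot)
}

#' Re-express a rigid transform about a different pivot
#'
#' The returned transform maps every point identically to the input; only the
#' (pivot, translation) parameterization changes.
#'
#' @param transform a `rigid_transform`.
#' @param pivot new pivot, length-3.
#' @return A `rigid_transform` with the requested pivot.
#' @export
repivot_transform <- function(transform, pivot) {
  # p' = R(p - v) + v + t = R(p - v') + v' + [t + (R - I)(v' - v)]
  d <- as.numeric(pivot) - transform$pivot
  t2 <- transform$translation + drop(transform$rotation %*% d) - d
  rigid_transform_from_matrix(transform$rotation, t2, as.numeric(pivot))
}

#' Compose rigid transforms (right-to-left)
#'
#' `compose_transforms(t2, t1)` returns the transform equivalent to applying
#' `t1` first, then `t2`. Any number of transforms may be given; all are
#' re-expressed about the pivot of the *last* argument (the first applied).
#'
#' @param ... `rigid_transform` objects, outermost first.
#' @return A single `rigid_transform`.
#' @export
compose_transforms <- function(...) {
  ts <- list(...)
  stopifnot(length(ts) >= 1)
  pivot <- ts[[length(ts)]]$pivot
  ts <- lapply(ts, repivot_transform, pivot = pivot)
  out <- ts[[length(ts)]]
  if (length(ts) > 1) {
    for (i in rev(seq_len(length(ts) - 1))) {
      t2 <- ts[[i]]
      R <- t2$rotation %*% out$rotation
      tr <- drop(t2$rotation %*% out$translation) + t2$translation
      out <- rigid_transform_from_matrix(R, tr, pivot)
    }
  }
  out
}

# Shipped frame conventions: rotation matrices taking the EMM acquisition frame
# into the MRI patient frame. The mapping-system frame is not standardized in
# any public document, so the table is configuration, not inference.
.axis_conventions <- list(
  identity = diag(3),
  swap_yz = matrix(c(1, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3, byrow = TRUE),
  flip_xz = diag(c(-1, 1, -1))
)

#' Constant frame-swap rotation between mapping and MRI coordinate systems
#'
#' Returns the fixed, data-independent rotation that aligns the electroanatomic
#' mapping frame with the MRI patient frame, by named convention. `"swap_yz"`
#' maps y -> -z, z -> y (rotation rows (1,0,0), (0,0,1), (0,-1,0)).
#'
#' @param convention one of `"identity"`, `"swap_yz"`, `"flip_xz"`.
#' @return A `rigid_transform` with zero translation and pivot at the origin.
#' @export
standard_axes_transform <- function(convention = "identity") {
  if (!is.character(convention) || length(convention) != 1 ||
      !convention %in% names(.axis_conventions)) {
    abort(
      sprintf("unknown axis convention '%s'; available: %s",
              as.character(convention)[1],
              paste(names(.axis_conventions), collapse = ", ")),
      class = "emmfuse_format_error"
    )
  }
  rigid_transform_from_matrix(.axis_conventions[[convention]])
}
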