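# Internal representation of a reference frame: a 4 x 3 numeric matrix.
# Row 1 is the origin (nm); rows 2-4 are the x, y, z axis unit vectors of the
# triad expressed in laboratory coordinates.  z points along the helix axis
# toward the 3' end of the reference strand, x toward the major groove.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Construct a base-pair reference frame
#'
#' A frame is stored as a 4 x 3 numeric matrix: row 1 the origin in nm and
#' rows 2-4 the x, y, z axis unit vectors.  The triad must be orthonormal
#' and right-handed.
#'
#' @param origin Numeric 3-vector, nm.
#' @param triad 3 x 3 matrix whose rows are the x, y, z axis vectors.
#' @return A 4 x 3 frame matrix.
#' @examples
#' new_frame(c(0, 0, 0), diag(3))
#' @export
new_frame <- function(origin = c(0, 0, 0), triad = diag(3)) {
  stopifnot(length(origin) == 3, is.matrix(triad), all(dim(triad) == c(3, 3)))
  f <- rbind(as.numeric(origin), triad)
  dimnames(f) <- NULL
  assert_frame(f)
  f
}

frame_origin <- function(f) f[1, ]
frame_triad  <- function(f) f[2:4, , drop = FALSE]

#' Validate a frame
#'
#' Checks that the triad rows are unit length, mutually orthogonal and
#' right-handed (determinant +1).
#'
#' @param f 4 x 3 frame matrix.
#' @param tol Tolerance on orthonormality deviations.
#' @return Invisibly `TRUE`; signals an error for an invalid frame.
#' @export
assert_frame <- function(f, tol = 1e-9) {
  if (!is.matrix(f) || !all(dim(f) == c(4, 3)) || !all(is.finite(f)))
    stop("invalid frame: expected a finite 4 x 3 matrix")
  tr <- f[2:4, , drop = FALSE]
  g <- tr %*% t(tr)
  if (max(abs(g - diag(3))) > tol)
    stop("invalid frame: triad not orthonormal within tolerance ", tol)
  if (abs(det(tr) - 1) > 10 * tol)
    stop("invalid frame: triad not right-handed (det != +1)")
  invisible(TRUE)
}

is_valid_triad <- function(tr, tol = 1e-6) {
  is.matrix(tr) && all(dim(tr) == c(3, 3)) && all(is.finite(tr)) &&
    max(abs(tr %*% t(tr) - diag(3))) <= tol && det(tr) > 0
}

#' Re-orthonormalize a triad
#'
#' Modified Gram-Schmidt starting from the z axis, used to control floating
#' point drift after long chains of composed rotations.
#'
#' @param tr 3 x 3 triad matrix (rows x, y, z).
#' @return Orthonormal right-handed triad closest in the Gram-Schmidt sense.
#' @export
orthonormalize_triad <- function(tr) {
  z <- tr[3, ]; z <- z / sqrt(sum(z^2))
  x <- tr[1, ] - sum(tr[1, ] * z) * z
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  rbind(x, y, z, deparse.level = 0)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

#' Rotation matrix from a rotation vector
#'
#' Rodrigues' formula.  The rotation vector is `angle * axis` in radians.
#'
#' @param v Rotation vector, radians.
#' @return 3 x 3 rotation matrix `R` such that `R %*% u` rotates `u`.
#' @export
rotation_matrix <- function(v) {
  th <- sqrt(sum(v^2))
  K <- skew3(v)             # hat(v): K %*% u = v x u
  if (th < 1e-10) {
    diag(3) + K + 0.5 * (K %*% K)
  } else {
    diag(3) + (sin(th) / th) * K + ((1 - cos(th)) / th^2) * (K %*% K)
  }
}

# Principal logarithm of a rotation matrix -> rotation vector (radians).
# Handles the small-angle and near-pi regimes separately.
rotation_log <- function(R) {
  ctheta <- (sum(diag(R)) - 1) / 2
  ctheta <- min(1, max(-1, ctheta))
  th <- acos(ctheta)
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (th < 1e-7) {
    # series: th/(2 sin th) ~ 1/2 (1 + th^2/6)
    return(0.5 * (1 + th^2 / 6) * w)
  }
  if (pi - th < 1e-7) {
    # axis from the symmetric part; sign fixed with the skew part when possible
    B <- (R + diag(3)) / 2
    u <- sqrt(pmax(diag(B), 0))
    k <- which.max(u)
    u[-k] <- B[k, -k] / u[k]
    u <- u / sqrt(sum(u^2))
    if (sum(u * w) < 0) u <- -u
    return(th * u)
  }
  (th / (2 * sin(th))) * w
}

#' Rotation vector between two triads
#'
#' Axis-angle vector of the relative rotation carrying triad `a` onto triad
#' `b`, with components expressed in the `a`-frame basis.
#'
#' @param a,b 3 x 3 triad matrices (rows x, y, z) or 4 x 3 frames.
#' @param degrees Return degrees (default) or radians.
#' @return 3-vector `phi * u`, `|result| <= 180` degrees.
#' @export
rotation_vector <- function(a, b, degrees = TRUE) {
  if (is.matrix(a) && nrow(a) == 4) a <- frame_triad(a)
  if (is.matrix(b) && nrow(b) == 4) b <- frame_triad(b)
  if (!is_valid_triad(a) || !is_valid_triad(b))
    stop("invalid frame: triads must be orthonormal and right-handed")
  # column-axis convention: A = t(a); relative rotation in a-basis = A^T B
  v <- rotation_log(a %*% t(b))
  if (degrees) v * RAD2DEG else v
}

#' Mid-frame of two frames
#'
#' The frame whose triad is `a`'s triad composed with half the relative
#' rotation onto `b`, and whose origin is the midpoint of the two origins.
#' The mid-frame underlies the symmetric definition of the rigid base-pair
#' parameters.
#'
#' @param a,b 4 x 3 frame matrices.
#' @return 4 x 3 frame matrix.
#' @export
midframe <- function(a, b) {
  v <- rotation_vector(frame_triad(a), frame_triad(b), degrees = FALSE)
  th <- sqrt(sum(v^2))
  if (pi - th < 1e-9)
    stop("ambiguous mid-frame: relative rotation is exactly 180 degrees")
  Rh <- rotation_matrix(v / 2)
  # columns-axes: A_mid = A %*% Rh  => triad_mid = t(Rh) %*% triad_a
  tm <- t(Rh) %*% frame_triad(a)
  rbind((frame_origin(a) + frame_origin(b)) / 2, tm, deparse.level = 0)
}

#' Step parameters between two consecutive frames
#'
#' Returns the 6-vector (shift, slide, rise, tilt, roll, twist): the origin
#' difference and the relative rotation vector, both resolved in the
#' mid-frame basis.  Translations in nm, rotations in degrees.
#'
#' @param a,b 4 x 3 frame matrices (frame `a` precedes `b` along 5'->3').
#' @return Named numeric 6-vector.
#' @export
step_from_frames <- function(a, b) {
  v <- rotation_vector(frame_triad(a), frame_triad(b), degrees = FALSE)
  th <- sqrt(sum(v^2))
  if (pi - th < 1e-9)
    stop("ambiguous mid-frame: relative rotation is exactly 180 degrees")
  Rh <- rotation_matrix(v / 2)
  tm <- t(Rh) %*% frame_triad(a)            # mid triad, rows x,y,z
  tr <- as.numeric(tm %*% (frame_origin(b) - frame_origin(a)))
  # the rotation axis is invariant under the half rotation, so the a-basis
  # components of v are already its mid-frame components
  out <- c(tr, v * RAD2DEG)
  names(out) <- c("shift", "slide", "rise", "tilt", "roll", "twist")
  out
}

#' Frame reached by applying a step to a frame
#'
#' Exact inverse of [step_from_frames()].
#'
#' @param a 4 x 3 frame matrix.
#' @param s Step 6-vector (shift, slide, rise in nm; tilt, roll, twist in
#'   degrees).
#' @return 4 x 3 frame matrix `b` with `step_from_frames(a, b) == s`.
#' @export
frames_from_step <- function(a, s) {
  s <- as.numeric(s)
  if (length(s) != 6 || !all(is.finite(s))) stop("step must be a finite 6-vector")
  v <- s[4:6] * DEG2RAD
  if (sqrt(sum(v^2)) >= pi)
    stop("step rotation magnitude must be < 180 degrees")
  Rh <- rotation_matrix(v / 2)
  Rf <- rotation_matrix(v)
  ta <- frame_triad(a)
  tm <- t(Rh) %*% ta
  tb <- t(Rf) %*% ta
  ob <- frame_origin(a) + as.numeric(t(tm) %*% s[1:3])
  rbind(ob, tb, deparse.level = 0)
}

# Rotate a triad about its own z axis by ang degrees (x, y rows rotate).
rotate_triad_about_z <- function(tr, ang) {
  a <- ang * DEG2RAD
  x <- cos(a) * tr[1, ] + sin(a) * tr[2, ]
  y <- -sin(a) * tr[1, ] + cos(a) * tr[2, ]
  rbind(x, y, tr[3, ], deparse.level = 0)
}

# Rotate a set of points (n x 3) about an axis through `point` with unit
# direction `axis` by `ang` degrees.
rotate_points_about_axis <- function(pts, point, axis, ang) {
  axis <- axis / sqrt(sum(axis^2))
  R <- rotation_matrix(axis * ang * DEG2RAD)
  sweep(sweep(pts, 2, point) %*% t(R), 2, point, `+`)
}
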