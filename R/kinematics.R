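#' Euler-angle orientation of a measurement frame
#'
#' Orientations relating the instrument (LDV) frame to anatomical frames are
#' recorded as three intrinsic rotations in degrees. Two conventions are
#' supported and must be named explicitly:
#' * `"measured_order"` — azimuth about z, then elevation about the new x,
#'   then rotation about the new y (the order the angles are measured on the
#'   bench);
#' * `"zyx"` — the same orientation re-expressed as rotations about z, then
#'   the new y, then the new x.
#'
#' All frames are right-handed; a positive angle is counter-clockwise when
#' looking down the rotation axis towards the origin.
#'
#' @param azimuth,elevation,rotation Angles in degrees. Under `"zyx"` they
#'   are the z, y and x rotations respectively.
#' @param order `"measured_order"` or `"zyx"`; never inferred.
#' @return A list of class `euler_angles`.
#' @export
euler_angles <- function(azimuth, elevation, rotation,
                         order = c("measured_order", "zyx")) {
  order <- match.arg(order)
  ang <- c(azimuth = azimuth, elevation = elevation, rotation = rotation)
  if (any(!is.finite(ang))) stop("angles must be finite", call. = FALSE)
  structure(list(
    azimuth = azimuth, elevation = elevation,
    rotation = rotation, order = order
  ), class = "euler_angles")
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Rotation matrix from Euler angles
#'
#' Composes the intrinsic rotations of an [euler_angles()] object into a
#' single proper rotation matrix (right-multiplication: each subsequent
#' rotation is about the already-rotated axis).
#'
#' @param angles An [euler_angles()] object.
#' @return A 3x3 orthonormal matrix with determinant +1.
#' @examples
#' rotation_from_angles(euler_angles(0, 0, 0, "zyx")) # identity
#' @export
rotation_from_angles <- function(angles) {
  stopifnot(inherits(angles, "euler_angles"))
  switch(angles$order,
    measured_order = rot_z(angles$azimuth) %*% rot_x(angles$elevation) %*%
      rot_y(angles$rotation),
    zyx = rot_z(angles$azimuth) %*% rot_y(angles$elevation) %*%
      rot_x(angles$rotation),
    stop("unknown order tag: ", angles$order, call. = FALSE)
  )
}

#' Re-express an orientation in Z-Y-X order
#'
#' Extracts, at full numerical precision, the intrinsic z-y-x angles that
#' reproduce the same rotation matrix as the input orientation. Useful to
#' convert bench-measured angle sets into the z-y-x convention.
#'
#' @param x An [euler_angles()] object or a 3x3 rotation matrix.
#' @return An [euler_angles()] object with `order = "zyx"`.
#' @export
as_zyx <- function(x) {
  R <- if (inherits(x, "euler_angles")) rotation_from_angles(x) else x
  stopifnot(is.matrix(R), all(dim(R) == 3))
  b <- asin(pmin(1, pmax(-1, -R[3, 1])))
  a <- atan2(R[2, 1], R[1, 1])
  c <- atan2(R[3, 2], R[3, 3])
  euler_angles(a * 180 / pi, b * 180 / pi, c * 180 / pi, order = "zyx")
}

#' Unit direction vector in a named frame
#'
#' @param x,y,z Components (any non-zero scale; normalised internally).
#' @param frame `"ldv"` (instrument) or `"anatomical"`.
#' @return A list of class `direction3` with a unit `vector` and `frame`.
#' @export
direction3 <- function(x, y, z, frame = c("ldv", "anatomical")) {
  frame <- match.arg(frame)
  v <- c(x, y, z)
  n <- sqrt(sum(v^2))
  if (!is.finite(n) || n < 1e-12) stop("direction vector has zero norm", call. = FALSE)
  structure(list(vector = v / n, frame = frame), class = "direction3")
}

#' Piston direction implied by an orientation
#'
#' The direction the orientation maps the instrument z-axis onto — the axis
#' along which the virtual 3D-LDV fixture embeds piston motion.
#'
#' @param angles An [euler_angles()] object.
#' @return A [direction3()] in the `"ldv"` frame.
#' @export
piston_direction <- function(angles) {
  d <- as.numeric(rotation_from_angles(angles) %*% c(0, 0, 1))
  direction3(d[1], d[2], d[3], frame = "ldv")
}

#' Project 3D velocity components onto a 1D piston direction
#'
#' Complex scalar product of the three measured components with a unit
#' direction, per frequency: the anatomically relevant 1D velocity that a
#' perfectly aligned single-beam instrument would have measured.
#'
#' @param v3 An `me_velocity3d` tibble (see [synthesize_ldv_3d()]).
#' @param direction A [direction3()] in the same frame as `v3`.
#' @param target_label,specimen_id Labels stamped on the output.
#' @return An [me_spectrum].
#' @export
project_to_piston <- function(v3, direction, target_label = "projected",
                              specimen_id = "synthetic") {
  stopifnot(inherits(direction, "direction3"))
  frame <- attr(v3, "frame") %||% "ldv"
  if (!identical(frame, direction$frame)) {
    stop("frame mismatch: velocities are in '", frame,
      "', direction in '", direction$frame, "'",
      call. = FALSE
    )
  }
  d <- direction$vector
  z <- v3$vx * d[1] + v3$vy * d[2] + v3$vz * d[3]
  spectrum_from_complex(v3$frequency_hz, z,
    target_label = target_label, specimen_id = specimen_id
  )
}

#' Unit normal of the plane through three points
#'
#' Normal of the plane spanned by three non-collinear landmarks (e.g. points
#' on the tympanic ring defining the eardrum plane). The sign is chosen so
#' the normal points towards `toward` when given.
#'
#' @param p1,p2,p3 Numeric length-3 positions (mm).
#' @param toward Optional reference point; the normal is flipped, if needed,
#'   to point into the half-space containing it.
#' @param frame Frame label for the result.
#' @param tol Minimum parallelogram area (mm^2) below which the points are
#'   treated as collinear.
#' @return A [direction3()].
#' @export
normal_from_three_points <- function(p1, p2, p3, toward = NULL,
                                     frame = "anatomical", tol = 1e-9) {
  u <- p2 - p1
  w <- p3 - p1
  n <- c(
    u[2] * w[3] - u[3] * w[2],
    u[3] * w[1] - u[1] * w[3],
    u[1] * w[2] - u[2] * w[1]
  )
  if (sqrt(sum(n^2)) < tol) {
    stop("points are collinear (triangle area below tolerance)", call. = FALSE)
  }
  n <- n / sqrt(sum(n^2))
  if (!is.null(toward) && sum(n * (toward - p1)) < 0) n <- -n
  direction3(n[1], n[2], n[3], frame = frame)
}

#' Single-beam cosine correction
#'
#' The legacy 1D-LDV practice: a beam misaligned by `theta` from the piston
#' direction measures the piston velocity attenuated by `cos(theta)`; the
#' correction divides the magnitude by `cos(theta)`, leaving phase
#' untouched. Valid only when the off-axis motion is negligible.
#'
#' @param v_measured An [me_spectrum] measured along the misaligned beam.
#' @param theta Beam-to-piston angle in degrees, `|theta| < 90`.
#' @return The corrected spectrum.
#' @export
legacy_cos_correction <- function(v_measured, theta) {
  if (!is.finite(theta) || abs(theta) >= 90) {
    stop("`theta` must satisfy |theta| < 90 degrees", call. = FALSE)
  }
  out <- v_measured
  out$magnitude <- v_measured$magnitude / cos(theta * pi / 180)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
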