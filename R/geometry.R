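# Conventions used throughout:
#   * Device Coordinate System (DCS): origin at the display centre, x along
#     the display rows, y along the columns (towards the front camera),
#     z from the display towards the subject; the display plane is z = 0.
#   * Angles cross the public API in degrees; radians are internal only.
#   * Positions are millimetres in the DCS; directions are unit vectors.

.deg <- function(x) x * pi / 180
.undeg <- function(x) x * 180 / pi

.clamp1 <- function(x) pmin(1, pmax(-1, x))

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.rg_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "rollgaze_error")))
}

#' Unit direction vectors in device coordinates
#'
#' A direction is a dimensionless unit vector (norm 1 within 1e-12) with
#' components in the Device Coordinate System. `direction3()` builds one from
#' components, `as_direction3()` normalises an arbitrary length-3 numeric.
#'
#' @param x,y,z Numeric components.
#' @param v A length-3 numeric vector.
#' @return A length-3 numeric unit vector.
#' @examples
#' direction3(0, 0, -1)
#' as_direction3(c(2, 0, -2))
#' @export
direction3 <- function(x, y, z) as_direction3(c(x, y, z))

#' @rdname direction3
#' @export
as_direction3 <- function(v) {
  v <- as.numeric(v)
  if (length(v) != 3L || !all(is.finite(v)))
    .rg_stop("a direction needs exactly 3 finite components",
             "rollgaze_bad_vector")
  n <- sqrt(sum(v * v))
  if (n < 1e-9)
    .rg_stop("cannot normalise a (near-)zero vector", "rollgaze_bad_vector")
  v / n
}

#' Points in device coordinates
#'
#' A point is a length-3 numeric position in millimetres in the DCS. Used for
#' the pupil centre `p` and the centre of corneal curvature `c`.
#'
#' @param x,y,z Coordinates in mm.
#' @return A length-3 numeric vector (mm).
#' @export
point3 <- function(x, y, z) {
  v <- as.numeric(c(x, y, z))
  if (length(v) != 3L || !all(is.finite(v)))
    .rg_stop("a point needs exactly 3 finite components", "rollgaze_bad_vector")
  v
}

#' Gaze angles of the eye
#'
#' Horizontal (yaw, `theta`) and vertical (pitch, `phi`) angles of the eye's
#' optical axis with respect to the device frame, in degrees. The spherical
#' parameterisation is degenerate at |phi| = 90 deg, which is rejected.
#'
#' @param theta Yaw in degrees.
#' @param phi Pitch in degrees; must satisfy |phi| < 90.
#' @return An object of class `"eye_angles"`.
#' @export
eye_angles <- function(theta, phi) {
  theta <- as.numeric(theta); phi <- as.numeric(phi)
  if (!is.finite(theta) || !is.finite(phi))
    .rg_stop("angles must be finite", "rollgaze_bad_vector")
  if (abs(phi) >= 90)
    .rg_stop("pitch parameterisation is degenerate at |phi| >= 90 deg",
             "rollgaze_degenerate_pitch")
  structure(list(theta = theta, phi = phi), class = "eye_angles")
}

#' Subject-specific optical-visual axis offsets
#'
#' The visual axis (through the fovea) is offset from the optical axis by
#' fixed, subject-specific horizontal (`alpha`) and vertical (`beta`) angles,
#' often called the kappa angle. These are constant in the eye-fixed frame.
#' Adult offsets span a few degrees; values beyond +/-10 deg are rejected as
#' physiologically implausible.
#'
#' @param alpha Horizontal offset in degrees, |alpha| <= 10.
#' @param beta Vertical offset in degrees, |beta| <= 10.
#' @return An object of class `"subject_eye_params"`.
#' @examples
#' subject_eye_params(3, 1.5) # an average adult eye
#' @export
subject_eye_params <- function(alpha, beta) {
  alpha <- as.numeric(alpha); beta <- as.numeric(beta)
  if (!is.finite(alpha) || !is.finite(beta))
    .rg_stop("offsets must be finite", "rollgaze_invalid_params")
  if (abs(alpha) > 10 || abs(beta) > 10)
    .rg_stop("optical-visual axis offsets beyond +/-10 deg are not plausible",
             "rollgaze_invalid_params")
  structure(list(alpha = alpha, beta = beta), class = "subject_eye_params")
}

#' @export
print.subject_eye_params <- function(x, ...) {
  cat(sprintf("<subject_eye_params> alpha = %g deg, beta = %g deg\n",
              x$alpha, x$beta))
  invisible(x)
}

.as_subject_params <- function(x) {
  if (inherits(x, "subject_eye_params")) return(x)
  if (is.list(x) && all(c("alpha", "beta") %in% names(x)))
    return(subject_eye_params(x$alpha, x$beta))
  if (is.numeric(x) && length(x) == 2L)
    return(subject_eye_params(x[1L], x[2L]))
  .rg_stop("cannot interpret object as subject eye parameters",
           "rollgaze_invalid_params")
}

.as_eye_angles <- function(x) {
  if (inherits(x, "eye_angles")) return(x)
  if (is.list(x) && all(c("theta", "phi") %in% names(x)))
    return(eye_angles(x$theta, x$phi))
  if (is.numeric(x) && length(x) == 2L)
    return(eye_angles(x[1L], x[2L]))
  .rg_stop("cannot interpret object as eye angles", "rollgaze_bad_vector")
}

#' Display geometry
#'
#' The display plane is fixed at z = 0 in the DCS with its origin at the
#' display centre; `width` extends along x and `height` along y. Defaults
#' describe a 5-inch phone panel.
#'
#' @param width,height Display size in mm; both positive.
#' @return An object of class `"screen"`.
#' @export
screen_geometry <- function(width = 110, height = 62) {
  width <- as.numeric(width); height <- as.numeric(height)
  if (!is.finite(width) || !is.finite(height) || width <= 0 || height <= 0)
    .rg_stop("screen width and height must be positive", "rollgaze_bad_screen")
  structure(list(width = width, height = height), class = "screen")
}

#' @export
print.screen <- function(x, ...) {
  cat(sprintf("<screen> %g x %g mm, plane z = 0, origin at centre\n",
              x$width, x$height))
  invisible(x)
}

#' Optical axis from gaze angles
#'
#' The optical axis omega of the eye expressed in the DCS from yaw/pitch:
#' omega = (sin(theta)cos(phi), sin(phi), -cos(theta)cos(phi)). A frontal
#' gaze (theta = phi = 0) points straight into the display, omega = (0,0,-1).
#'
#' @param angles An [eye_angles()] object (degrees).
#' @return A unit direction (length-3 numeric).
#' @export
optical_axis_from_angles <- function(angles) {
  angles <- .as_eye_angles(angles)
  th <- .deg(angles$theta); ph <- .deg(angles$phi)
  as_direction3(c(sin(th) * cos(ph), sin(ph), -cos(th) * cos(ph)))
}

#' Gaze angles from an optical-axis direction
#'
#' Inverse of [optical_axis_from_angles()]. Undefined (gimbal lock) when the
#' axis is within 1e-9 of the device column axis (0, +/-1, 0).
#'
#' @param omega A unit direction.
#' @return An [eye_angles()] object.
#' @export
angles_from_direction <- function(omega) {
  omega <- as_direction3(omega)
  if (abs(omega[2L]) >= 1 - 1e-9)
    .rg_stop("yaw is undefined when the axis is (0, +/-1, 0) (gimbal lock)",
             "rollgaze_gimbal")
  phi <- asin(.clamp1(omega[2L]))
  theta <- atan2(omega[1L], -omega[3L])
  eye_angles(.undeg(theta), .undeg(phi))
}

#' Optical axis from pupil and cornea centres
#'
#' The optical axis is the line through the centre of corneal curvature `c`
#' and the pupil centre `p`: omega = (p - c) / ||p - c||.
#'
#' @param p Pupil centre, mm in DCS.
#' @param c_pos Centre of corneal curvature, mm in DCS.
#' @return A unit direction from `c_pos` towards `p`.
#' @export
optical_axis_from_pc <- function(p, c_pos) {
  d <- as.numeric(p) - as.numeric(c_pos)
  if (sqrt(sum(d * d)) <= 1e-9)
    .rg_stop("pupil centre and cornea centre coincide; axis undefined",
             "rollgaze_coincident_points")
  as_direction3(d)
}

#' Visual axis in the eye-fixed frame
#'
#' In the eye coordinate system (ECS; z_eye along the optical axis, pointing
#' out of the eye) the visual axis is constant:
#' nu_ECS = (sin(alpha)cos(beta), sin(beta), cos(alpha)cos(beta)).
#'
#' @param params A [subject_eye_params()] object.
#' @return A unit direction in ECS components.
#' @export
visual_axis_in_ecs <- function(params) {
  params <- .as_subject_params(params)
  a <- .deg(params$alpha); b <- .deg(params$beta)
  c(sin(a) * cos(b), sin(b), cos(a) * cos(b))
}

#' Eye-coordinate-system basis in device coordinates
#'
#' Builds the basis (x_eye, y_eye, z_eye) of the eye-fixed frame expressed in
#' the DCS, for a given optical axis and relative-roll angle `lam`. The zero
#' roll frame is anchored to the device column axis y_device = (0,1,0):
#' x_eye(0) = normalize(omega x y_device), y_eye(0) = x_eye(0) x z_eye, and a
#' roll by `lam` rotates x_eye/y_eye about z_eye = omega:
#' x_eye = cos(lam) x_eye(0) + sin(lam) y_eye(0),
#' y_eye = -sin(lam) x_eye(0) + cos(lam) y_eye(0).
#'
#' For a frontal axis omega = (0,0,-1) and lam = 0 this yields the columns
#' (1,0,0), (0,1,0), (0,0,-1). The construction is degenerate when the
#' optical axis is parallel to the device column axis.
#'
#' @param omega Optical axis, unit direction in DCS.
#' @param lam Relative roll angle (R-Roll) in degrees.
#' @return A 3x3 matrix of class `"ecs_frame"` with columns `x_eye`, `y_eye`,
#'   `z_eye` (the rotation taking ECS components to DCS components).
#' @export
ecs_frame <- function(omega, lam = 0) {
  omega <- as.numeric(omega)
  if (length(omega) != 3L || !all(is.finite(omega)))
    .rg_stop("a direction needs exactly 3 finite components",
             "rollgaze_bad_vector")
  n <- sqrt(sum(omega * omega))
  if (n < 1e-9)
    .rg_stop("cannot normalise a (near-)zero vector", "rollgaze_bad_vector")
  # keep an already-unit input bit-identical so z_eye == omega exactly
  if (abs(n - 1) > 1e-12) omega <- omega / n
  y_dev <- c(0, 1, 0)
  x0 <- .cross3(omega, y_dev)
  n <- sqrt(sum(x0 * x0))
  if (n < 1e-9)
    .rg_stop("optical axis parallel to the device column axis: frame undefined",
             "rollgaze_degenerate_frame")
  x0 <- x0 / n
  y0 <- .cross3(x0, omega)
  l <- .deg(lam)
  x <- cos(l) * x0 + sin(l) * y0
  y <- -sin(l) * x0 + cos(l) * y0
  m <- cbind(x_eye = x, y_eye = y, z_eye = omega)
  structure(m, class = c("ecs_frame", "matrix", "array"), lambda_deg = lam)
}

#' Visual axis in device coordinates
#'
#' Rotates the eye-fixed visual axis into the DCS:
#' nu_DCS = R_ECS->DCS(omega, lam) * nu_ECS.
#'
#' @inheritParams ecs_frame
#' @param params A [subject_eye_params()] object.
#' @return A unit direction in DCS.
#' @export
visual_axis_in_dcs <- function(omega, params, lam = 0) {
  fr <- ecs_frame(omega, lam)
  nu <- as.numeric(unclass(fr) %*% visual_axis_in_ecs(params))
  as_direction3(nu)
}

#' Visual axis from additive Euler offsets
#'
#' The desktop-model parameterisation that simply adds the offsets to the
#' gaze angles: nu = (sin(theta+alpha)cos(phi+beta), sin(phi+beta),
#' -cos(theta+alpha)cos(phi+beta)). Kept for cross-checks: it agrees exactly
#' with [visual_axis_in_dcs()] at zero pitch and zero roll, and to second
#' order elsewhere.
#'
#' @param angles An [eye_angles()] object (degrees).
#' @param params A [subject_eye_params()] object.
#' @return A unit direction in DCS.
#' @export
visual_axis_euler <- function(angles, params) {
  angles <- .as_eye_angles(angles)
  params <- .as_subject_params(params)
  th <- angles$theta + params$alpha
  ph <- angles$phi + params$beta
  if (abs(ph) >= 90)
    .rg_stop("pitch + beta reaches the degenerate |angle| >= 90 deg",
             "rollgaze_degenerate_pitch")
  th <- .deg(th); ph <- .deg(ph)
  as_direction3(c(sin(th) * cos(ph), sin(ph), -cos(th) * cos(ph)))
}

#' Point of gaze on the display plane
#'
#' Intersects the ray from the cornea centre `c_pos` along the visual axis
#' `nu` with the display plane z = 0. The intersection is returned even when
#' it lies outside the physical display; the `on_screen` attribute carries
#' the bounds flag (NA when no screen is supplied).
#'
#' @param c_pos Cornea centre, mm in DCS, with positive z.
#' @param nu Visual axis, unit direction with nu_z < 0 (towards the display).
#' @param screen Optional [screen_geometry()] for the bounds flag.
#' @return Named numeric `c(x, y)` in mm with attribute `on_screen`.
#' @examples
#' pog_on_screen(point3(0, 0, 300), direction3(0, 0, -1))
#' @export
pog_on_screen <- function(c_pos, nu, screen = NULL) {
  c_pos <- as.numeric(c_pos)
  if (c_pos[3L] <= 0)
    .rg_stop("eye must be in front of the display (c_z > 0)",
             "rollgaze_bad_eye_position")
  nu <- as_direction3(nu)
  if (nu[3L] >= -1e-9)
    .rg_stop("visual axis does not intersect the display (nu_z >= 0)",
             "rollgaze_no_intersection")
  t <- -c_pos[3L] / nu[3L]
  px <- c_pos[1L] + t * nu[1L]
  py <- c_pos[2L] + t * nu[2L]
  on <- NA
  if (!is.null(screen)) {
    stopifnot(inherits(screen, "screen"))
    on <- abs(px) <= screen$width / 2 && abs(py) <= screen$height / 2
  }
  structure(c(x = px, y = py), on_screen = on)
}
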