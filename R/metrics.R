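# Evaluation harness: per-frame PoG estimation with (method 2) or without
# (method 1) roll compensation, and the fixation-accuracy metrics used to
# summarise sessions: per-target mean distance, per-roll aggregates in mm
# and degrees, 95% enclosing radius and distinct-target capacity.

# Vectorised eye-frame construction for n frames. pm/cm are n x 3 matrices
# of pupil and cornea positions, lam is a length-n vector of roll angles in
# degrees. Returns the rolled basis and a validity mask instead of raising:
# frames with a degenerate axis or frame are flagged invalid.
.frame_basis_rows <- function(pm, cm, lam) {
  d <- pm - cm
  dn <- sqrt(rowSums(d * d))
  valid <- is.finite(dn) & dn > 1e-9
  dn[!valid] <- NA_real_
  omega <- d / dn
  # omega x (0,1,0) = (-omega_z, 0, omega_x)
  x0 <- cbind(-omega[, 3L], 0, omega[, 1L])
  xn <- sqrt(rowSums(x0 * x0))
  valid <- valid & is.finite(xn) & xn > 1e-9
  xn[xn <= 1e-9 | !is.finite(xn)] <- NA_real_
  x0 <- x0 / xn
  # y0 = x0 x omega (rowwise cross product)
  y0 <- cbind(x0[, 2L] * omega[, 3L] - x0[, 3L] * omega[, 2L],
              x0[, 3L] * omega[, 1L] - x0[, 1L] * omega[, 3L],
              x0[, 1L] * omega[, 2L] - x0[, 2L] * omega[, 1L])
  cl <- cos(.deg(lam)); sl <- sin(.deg(lam))
  list(x = cl * x0 + sl * y0,
       y = -sl * x0 + cl * y0,
       z = omega,
       valid = valid)
}

# PoG for all frames given a basis, cornea positions and offsets (degrees).
# Frames whose visual axis does not point at the display are invalidated.
.pog_rows <- function(basis, cm, alpha, beta) {
  a <- .deg(alpha); b <- .deg(beta)
  nu <- sin(a) * cos(b) * basis$x + sin(b) * basis$y +
    cos(a) * cos(b) * basis$z
  valid <- basis$valid & is.finite(nu[, 3L]) & nu[, 3L] < -1e-9
  t <- -cm[, 3L] / nu[, 3L]
  list(x = cm[, 1L] + t * nu[, 1L],
       y = cm[, 2L] + t * nu[, 2L],
       valid = valid)
}

.session_params <- function(session, params) {
  if (is.null(params)) params <- session$subject_calibrated
  if (is.null(params))
    .rg_stop("no calibrated subject parameters: run estimate_alpha_beta()/apply_subject() or pass params",
             "rollgaze_missing_params")
  .as_subject_params(params)
}

#' Per-frame PoG estimation for a session
#'
#' Estimates the point of gaze for every frame of a session. The optical
#' axis is reconstructed from the pupil and cornea centres; the roll used to
#' rotate the eye frame is 0 for method 1 (no compensation) and the measured
#' roll (`lam_measured_deg`) for method 2 (roll compensation). Frames where
#' the geometry is degenerate (coincident features, axis along the device
#' column, axis not pointing at the display) are flagged invalid rather than
#' raising.
#'
#' @param session A `"gaze_session"`.
#' @param params Subject offsets; defaults to the session's calibrated
#'   parameters (see [apply_subject()]).
#' @param method 1 (assume roll 0) or 2 (use the measured roll).
#' @return Data frame: `frame`, `roll_deg`, `target_id`, `x`, `y` (mm),
#'   `method`, `valid`.
#' @export
estimate_pog <- function(session, params = NULL, method = 2) {
  stopifnot(inherits(session, "gaze_session"))
  if (!method %in% c(1, 2))
    .rg_stop("method must be 1 or 2", "rollgaze_bad_method")
  params <- .session_params(session, params)
  s <- session$samples
  pm <- as.matrix(s[, c("p_x", "p_y", "p_z")])
  cm <- as.matrix(s[, c("c_x", "c_y", "c_z")])
  lam <- if (method == 2) s$lam_measured_deg else rep(0, nrow(s))
  basis <- .frame_basis_rows(pm, cm, lam)
  pog <- .pog_rows(basis, cm, params$alpha, params$beta)
  data.frame(frame = s$frame, roll_deg = s$roll_deg,
             target_id = s$target_id,
             x = ifelse(pog$valid, pog$x, NA_real_),
             y = ifelse(pog$valid, pog$y, NA_real_),
             method = as.integer(method), valid = pog$valid)
}

#' Convert an on-screen distance to visual angle
#'
#' @param err_mm Distance on the display, mm.
#' @param distance Viewing distance, mm, positive.
#' @return Angle in degrees: atan(err_mm / distance).
#' @export
mm_to_degrees <- function(err_mm, distance) {
  if (any(distance <= 0))
    .rg_stop("viewing distance must be positive", "rollgaze_bad_distance")
  .undeg(atan(err_mm / distance))
}

#' Mean distance of PoG estimates from a fixation target
#'
#' The per-target error of the protocol: the mean Euclidean distance between
#' the valid PoG estimates and the target position.
#'
#' @param estimates Data frame with columns `x`, `y`, `valid` (as returned
#'   by [estimate_pog()]).
#' @param target Length-2 numeric, target (x, y) in mm.
#' @return Mean distance in mm.
#' @export
per_target_error <- function(estimates, target) {
  e <- estimates[estimates$valid, , drop = FALSE]
  if (nrow(e) == 0L)
    .rg_stop("no valid PoG estimates for this target",
             "rollgaze_no_valid_estimates")
  mean(sqrt((e$x - target[1L])^2 + (e$y - target[2L])^2))
}

#' 95% enclosing radius around a fixation target
#'
#' Radius of the circle centred on the target containing 95% of the valid
#' PoG estimates, computed as the 95th percentile (linear interpolation) of
#' the distances. A proxy for how densely selectable targets can be packed.
#'
#' @inheritParams per_target_error
#' @param prob Coverage probability, default 0.95.
#' @return Radius in mm.
#' @export
radius_95 <- function(estimates, target, prob = 0.95) {
  e <- estimates[estimates$valid, , drop = FALSE]
  if (nrow(e) < 20L)
    .rg_stop("need at least 20 valid estimates for a stable percentile",
             "rollgaze_too_few_samples")
  d <- sqrt((e$x - target[1L])^2 + (e$y - target[2L])^2)
  stats::quantile(d, prob, type = 7, names = FALSE)
}

#' Distinct selectable targets on a display
#'
#' Number of fixation targets that fit on the display when each needs an
#' exclusive square cell of side equal to the 95% enclosing radius:
#' floor(width / radius) * floor(height / radius). A grid-packing
#' interpretation of target capacity.
#'
#' @param radius Enclosing radius in mm, positive.
#' @param screen A [screen_geometry()].
#' @return Integer count.
#' @export
distinct_targets <- function(radius, screen = screen_geometry()) {
  if (radius <= 0)
    .rg_stop("radius must be positive", "rollgaze_bad_radius")
  as.integer(floor(screen$width / radius) * floor(screen$height / radius))
}

#' Session error report
#'
#' Summarises a session the way fixation-accuracy tables are reported:
#' per-roll, per-target mean distances; per-roll aggregates as the
#' unweighted mean over targets, in mm and (via the nominal viewing
#' distance) in degrees; the per-roll 95% enclosing radius pooled over
#' targets; and frame counts.
#'
#' @inheritParams estimate_pog
#' @return A list of class `"gaze_error_report"`: `per_target` (data frame
#'   `roll_deg`, `target_id`, `n_valid`, `err_mm`), `per_roll` (data frame
#'   `roll_deg`, `err_mm`, `err_deg`, `radius_95_mm`, `n_valid`, `n_total`),
#'   plus `method` and `distance`.
#' @export
error_report <- function(session, params = NULL, method = 2) {
  est <- estimate_pog(session, params, method)
  s <- session$samples
  d <- sqrt((est$x - s$target_x_mm)^2 + (est$y - s$target_y_mm)^2)
  key <- interaction(s$roll_deg, s$target_id, drop = TRUE)
  per_target <- do.call(rbind, lapply(split(seq_len(nrow(s)), key), function(i) {
    ok <- est$valid[i]
    data.frame(roll_deg = s$roll_deg[i][1L],
               target_id = s$target_id[i][1L],
               n_valid = sum(ok),
               err_mm = if (any(ok)) mean(d[i][ok]) else NA_real_)
  }))
  per_target <- per_target[order(per_target$roll_deg, per_target$target_id), ]
  rownames(per_target) <- NULL
  per_roll <- do.call(rbind, lapply(split(seq_len(nrow(s)), s$roll_deg), function(i) {
    ok <- est$valid[i]
    pt <- per_target[per_target$roll_deg == s$roll_deg[i][1L], ]
    err_mm <- mean(pt$err_mm)
    r95 <- if (sum(ok) >= 20L)
      stats::quantile(d[i][ok], 0.95, type = 7, names = FALSE) else NA_real_
    data.frame(roll_deg = s$roll_deg[i][1L],
               err_mm = err_mm,
               err_deg = mm_to_degrees(err_mm, session$viewing_distance),
               radius_95_mm = r95,
               n_valid = sum(ok),
               n_total = length(i))
  }))
  rownames(per_roll) <- NULL
  structure(list(per_target = per_target, per_roll = per_roll,
                 method = as.integer(method),
                 distance = session$viewing_distance),
            class = "gaze_error_report")
}

#' @export
print.gaze_error_report <- function(x, digits = 2, ...) {
  cat(sprintf("Gaze-estimation error report (method %d, %g mm viewing distance)\n",
              x$method, x$distance))
  pr <- x$per_roll
  pr$err_mm <- round(pr$err_mm, digits)
  pr$err_deg <- round(pr$err_deg, digits)
  pr$radius_95_mm <- round(pr$radius_95_mm, digits)
  print(pr, row.names = FALSE)
  invisible(x)
}
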