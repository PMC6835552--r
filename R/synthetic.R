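# Forward simulator for fixation sessions. Emulates the chin-rest protocol:
# the eye sits on the device axis at a fixed viewing distance, the device is
# set to a series of roll angles, and the subject fixates a set of known
# on-screen targets for a block of frames each. Ground truth is exact by
# construction (the optical axis is solved so that the forward model lands
# the visual axis on the target); measurement imperfections enter as iid
# Gaussian noise on the pupil/cornea positions and on the measured roll.

#' Noise configuration for simulated sessions
#'
#' `feature_sigma` is the per-component standard deviation (mm) of the
#' Gaussian noise added to the pupil-centre and cornea-centre positions,
#' emulating feature-extraction error in the eye images. The default
#' 0.035 mm, propagated through the 4 mm pupil-cornea baseline, gives a mean
#' radial PoG error of roughly 0.9 deg, the magnitude of the roll-compensated
#' baseline in hand-held infrared trackers. `tracker_sigma` (degrees) is the
#' head-tracker noise on the measured roll; practical trackers stay below
#' 1 deg.
#'
#' @param feature_sigma Non-negative, mm.
#' @param tracker_sigma Non-negative, degrees.
#' @param seed Optional integer seed; recorded in the session for
#'   reproducibility.
#' @return A list of class `"noise_config"`.
#' @export
noise_config <- function(feature_sigma = 0.035, tracker_sigma = 0.5,
                         seed = NULL) {
  if (feature_sigma < 0 || tracker_sigma < 0)
    .rg_stop("noise standard deviations must be non-negative",
             "rollgaze_bad_noise")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(feature_sigma = feature_sigma,
                 tracker_sigma = tracker_sigma,
                 seed = seed),
            class = "noise_config")
}

#' Ocular counter-roll
#'
#' When the head tilts relative to gravity the eyes torsionally counter-roll
#' part of the way back; the gain of this reflex is below 0.1, so a subject
#' lying down (90 deg tilt) may show up to 9 deg of counter-roll.
#'
#' @param head_tilt_wrt_gravity Head tilt relative to gravity, degrees.
#' @param gain Counter-roll gain, in `[0, 0.1]`.
#' @return Counter-roll angle in degrees.
#' @export
counter_roll <- function(head_tilt_wrt_gravity, gain) {
  if (any(gain < 0 | gain > 0.1))
    .rg_stop("counter-roll gain must lie in [0, 0.1]", "rollgaze_bad_gain")
  gain * head_tilt_wrt_gravity
}

#' Effective relative roll between eye and device
#'
#' The relative roll (R-Roll) seen by the gaze model combines the device
#' roll with respect to the head and the eye's counter-roll driven by head
#' tilt relative to gravity: lam = device_roll - gain * head_tilt. Under a
#' chin rest the head stays upright and lam equals the set device roll.
#'
#' @param device_roll_wrt_head Degrees.
#' @param head_tilt_wrt_gravity Degrees.
#' @param gain Counter-roll gain, in `[0, 0.1]`.
#' @return Effective roll in degrees.
#' @export
effective_roll <- function(device_roll_wrt_head, head_tilt_wrt_gravity = 0,
                           gain = 0) {
  device_roll_wrt_head - counter_roll(head_tilt_wrt_gravity, gain)
}

#' Default fixation-target layout
#'
#' Five targets: the display centre plus four points at 70% of the half
#' width/height, mirroring the centre + corners layout used in fixation
#' protocols on phone-sized displays.
#'
#' @param screen A [screen_geometry()] object.
#' @return Data frame with columns `target_id`, `x_mm`, `y_mm`.
#' @export
default_targets <- function(screen = screen_geometry()) {
  dx <- 0.35 * screen$width
  dy <- 0.35 * screen$height
  data.frame(target_id = c("C", "TL", "TR", "BL", "BR"),
             x_mm = c(0, -dx, dx, -dx, dx),
             y_mm = c(0, dy, dy, -dy, -dy))
}

#' Fixation protocol description
#'
#' @param rolls Set device roll angles in degrees; default the 0/45/90
#'   schedule of the benchmark protocol.
#' @param frames_per_target Frames recorded per target (default 150, i.e.
#'   5 s at 30 Hz).
#' @param targets Data frame `target_id`, `x_mm`, `y_mm`; default
#'   [default_targets()].
#' @return A list of class `"fixation_protocol"`.
#' @export
fixation_protocol <- function(rolls = c(0, 45, 90), frames_per_target = 150,
                              targets = NULL) {
  if (frames_per_target < 1)
    .rg_stop("need at least one frame per target", "rollgaze_bad_protocol")
  structure(list(rolls = as.numeric(rolls),
                 frames_per_target = as.integer(frames_per_target),
                 targets = targets),
            class = "fixation_protocol")
}

#' Solve the optical axis that fixates a target
#'
#' Inverse of the forward model: finds the optical axis omega such that the
#' visual axis derived from it (given the subject offsets and roll) lands on
#' the requested display target. Fixed-point iteration starting from the
#' straight line eye-to-target, omega_{k+1} = normalize(omega_k - (nu_k -
#' nu*)), where nu* is the required visual-axis direction; contraction is
#' of order sin(kappa), so a handful of iterations suffices for
#' physiological offsets.
#'
#' @param c_pos Cornea centre, mm in DCS, z > 0.
#' @param target Length-2 numeric, target (x, y) in mm on the display plane.
#' @param params A [subject_eye_params()] object.
#' @param lam Relative roll in degrees.
#' @param tol Convergence tolerance on omega (max component change).
#' @param max_iter Iteration cap.
#' @return The optical-axis unit direction.
#' @export
solve_optical_axis_for_target <- function(c_pos, target, params, lam = 0,
                                          tol = 1e-10, max_iter = 50L) {
  c_pos <- as.numeric(c_pos)
  if (c_pos[3L] <= 0)
    .rg_stop("eye must be in front of the display (c_z > 0)",
             "rollgaze_bad_eye_position")
  params <- .as_subject_params(params)
  nu_star <- as_direction3(c(target[1L], target[2L], 0) - c_pos)
  omega <- nu_star
  for (i in seq_len(max_iter)) {
    nu <- visual_axis_in_dcs(omega, params, lam)
    omega_new <- as_direction3(omega - (nu - nu_star))
    if (max(abs(omega_new - omega)) < tol) {
      return(omega_new)
    }
    omega <- omega_new
  }
  .rg_stop("optical-axis solve did not converge", "rollgaze_no_convergence")
}

#' Simulate a fixation session
#'
#' Generates per-frame pupil-centre and cornea-centre positions for a
#' subject fixating each protocol target at each set roll angle. For every
#' (roll, target) block the true optical axis is obtained with
#' [solve_optical_axis_for_target()], the pupil centre is placed `d_pc` mm
#' along it from the cornea centre, and per-frame Gaussian noise is applied
#' to both positions and to the measured roll. Deterministic under a fixed
#' `noise$seed`.
#'
#' @param params True subject offsets ([subject_eye_params()]).
#' @param protocol A [fixation_protocol()].
#' @param screen A [screen_geometry()].
#' @param viewing_distance Eye-to-display distance in mm (default 300, the
#'   chin-rest distance of the benchmark protocol).
#' @param noise A [noise_config()].
#' @param eye_position Cornea-centre position, mm in DCS; default on-axis at
#'   the viewing distance.
#' @param d_pc Pupil-cornea distance along the optical axis, mm (default 4;
#'   the axis direction is normalised, so this only scales noise
#'   sensitivity).
#' @param head_tilt_wrt_gravity,counter_roll_gain Counter-roll model inputs;
#'   defaults describe the chin-rest condition (no tilt, no counter-roll).
#' @return A list of class `"gaze_session"` with elements `samples` (one row
#'   per frame), `targets`, `screen`, `viewing_distance`, `subject_truth`,
#'   `subject_calibrated` (NULL until [apply_subject()]), `protocol`,
#'   `noise`, `d_pc`, `eye_position`.
#' @examples
#' s <- simulate_session(subject_eye_params(3, 1.5),
#'                       noise = noise_config(seed = 1))
#' nrow(s$samples) # 5 targets x 3 rolls x 150 frames
#' @export
simulate_session <- function(params,
                             protocol = fixation_protocol(),
                             screen = screen_geometry(),
                             viewing_distance = 300,
                             noise = noise_config(),
                             eye_position = NULL,
                             d_pc = 4,
                             head_tilt_wrt_gravity = 0,
                             counter_roll_gain = 0) {
  params <- .as_subject_params(params)
  stopifnot(inherits(protocol, "fixation_protocol"),
            inherits(screen, "screen"), inherits(noise, "noise_config"))
  if (viewing_distance <= 0)
    .rg_stop("viewing distance must be positive", "rollgaze_bad_distance")
  if (d_pc <= 0)
    .rg_stop("pupil-cornea distance must be positive", "rollgaze_bad_protocol")
  targets <- protocol$targets
  if (is.null(targets)) targets <- default_targets(screen)
  if (any(abs(targets$x_mm) > screen$width / 2) ||
      any(abs(targets$y_mm) > screen$height / 2))
    .rg_stop("all fixation targets must lie on the screen",
             "rollgaze_bad_protocol")
  if (is.null(eye_position)) eye_position <- c(0, 0, viewing_distance)
  eye_position <- point3(eye_position[1L], eye_position[2L], eye_position[3L])

  if (!is.null(noise$seed)) set.seed(noise$seed)
  n <- protocol$frames_per_target
  blocks <- vector("list", length(protocol$rolls) * nrow(targets))
  bi <- 0L
  frame0 <- 0L
  for (roll in protocol$rolls) {
    lam_true <- effective_roll(roll, head_tilt_wrt_gravity, counter_roll_gain)
    for (ti in seq_len(nrow(targets))) {
      omega <- solve_optical_axis_for_target(
        eye_position, c(targets$x_mm[ti], targets$y_mm[ti]), params, lam_true)
      p0 <- eye_position + d_pc * omega
      pn <- matrix(rep(p0, each = n), nrow = n) +
        noise$feature_sigma * matrix(stats::rnorm(3L * n), nrow = n)
      cn <- matrix(rep(eye_position, each = n), nrow = n) +
        noise$feature_sigma * matrix(stats::rnorm(3L * n), nrow = n)
      lam_meas <- lam_true + noise$tracker_sigma * stats::rnorm(n)
      bi <- bi + 1L
      blocks[[bi]] <- data.frame(
        frame = frame0 + seq_len(n),
        roll_deg = roll,
        target_id = targets$target_id[ti],
        target_x_mm = targets$x_mm[ti],
        target_y_mm = targets$y_mm[ti],
        p_x = pn[, 1L], p_y = pn[, 2L], p_z = pn[, 3L],
        c_x = cn[, 1L], c_y = cn[, 2L], c_z = cn[, 3L],
        lam_true_deg = lam_true,
        lam_measured_deg = lam_meas)
      frame0 <- frame0 + n
    }
  }
  structure(list(samples = do.call(rbind, blocks),
                 targets = targets,
                 screen = screen,
                 viewing_distance = viewing_distance,
                 subject_truth = params,
                 subject_calibrated = NULL,
                 protocol = protocol,
                 noise = noise,
                 d_pc = d_pc,
                 eye_position = eye_position),
            class = "gaze_session")
}

#' @export
print.gaze_session <- function(x, ...) {
  cat(sprintf(paste0("<gaze_session> %d frames | %d targets | rolls: %s deg",
                     " | distance %g mm\n"),
              nrow(x$samples), nrow(x$targets),
      paste(unique(x$samples$roll_deg), collapse = "/"),
      x$viewing_distance))
  if (!is.null(x$subject_truth))
    cat(sprintf("  truth: alpha = %g, beta = %g deg\n",
                x$subject_truth$alpha, x$subject_truth$beta))
  if (!is.null(x$subject_calibrated))
    cat(sprintf("  calibrated: alpha = %.3f, beta = %.3f deg\n",
                x$subject_calibrated$alpha, x$subject_calibrated$beta))
  invisible(x)
}
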