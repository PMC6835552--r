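# Subject calibration: recover the optical-visual axis offsets (alpha,
# beta) from a session in which the subject fixates known targets at a
# known (usually zero) roll. The loss is the sum of squared on-screen
# distances between the model PoG and the target, matching how fixation
# accuracy is scored; minimised by Levenberg-Marquardt with box bounds.

#' Estimate the optical-visual axis offsets from a calibration session
#'
#' For each sample the optical axis is reconstructed from the (noisy) pupil
#' and cornea centres and the eye frame is built at the calibration roll
#' `lam_cal`; (alpha, beta) are then fit by nonlinear least squares on the
#' on-screen residuals between the model PoG and the fixated target.
#' Samples with degenerate geometry, or whose zero-offset PoG falls more
#' than three screen diagonals from the target (pathological noise draws),
#' are dropped and counted.
#'
#' @param session A `"gaze_session"` with known targets.
#' @param lam_cal Roll angle during calibration, degrees (the protocol
#'   calibrates at roll 0).
#' @return A list of class `"calibration_result"`: `params`
#'   ([subject_eye_params()]), `rms_residual` (mm), `n_samples_used`,
#'   `n_dropped`, `converged`, `objective_initial`, `objective_final`.
#' @examples
#' s <- simulate_session(subject_eye_params(3, 1.5),
#'                       protocol = fixation_protocol(rolls = 0,
#'                                                    frames_per_target = 20),
#'                       noise = noise_config(seed = 7))
#' estimate_alpha_beta(s)
#' @export
estimate_alpha_beta <- function(session, lam_cal = 0) {
  stopifnot(inherits(session, "gaze_session"))
  s <- session$samples
  if (nrow(s) == 0L)
    .rg_stop("session has no samples", "rollgaze_empty_session")
  pm <- as.matrix(s[, c("p_x", "p_y", "p_z")])
  cm <- as.matrix(s[, c("c_x", "c_y", "c_z")])
  basis <- .frame_basis_rows(pm, cm, rep(lam_cal, nrow(s)))
  tx <- s$target_x_mm; ty <- s$target_y_mm

  # outlier guard: PoG at zero offsets (nu = omega) vs own target
  pog0 <- .pog_rows(basis, cm, 0, 0)
  diag3 <- 3 * sqrt(session$screen$width^2 + session$screen$height^2)
  keep <- basis$valid & pog0$valid &
    sqrt((pog0$x - tx)^2 + (pog0$y - ty)^2) <= diag3
  n_dropped <- sum(!keep)
  if (length(unique(s$target_id[keep])) < 2L)
    .rg_stop("calibration needs valid samples on at least 2 distinct targets",
             "rollgaze_insufficient_targets")
  kb <- lapply(basis[c("x", "y", "z")], function(m) m[keep, , drop = FALSE])
  kb$valid <- basis$valid[keep]
  kc <- cm[keep, , drop = FALSE]
  ktx <- tx[keep]; kty <- ty[keep]

  resid_fn <- function(par) {
    pog <- .pog_rows(kb, kc, par[1L], par[2L])
    # frames pushed off the display direction during a step get a large,
    # smooth penalty instead of NaN so the optimizer can back off
    bad <- !pog$valid
    rx <- pog$x - ktx
    ry <- pog$y - kty
    rx[bad] <- 1e6; ry[bad] <- 1e6
    c(rx, ry)
  }
  fit <- minpack.lm::nls.lm(
    par = c(alpha = 0, beta = 0), fn = resid_fn,
    lower = c(-10, -10), upper = c(10, 10),
    control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                         maxiter = 200))
  r0 <- resid_fn(c(0, 0))
  rF <- resid_fn(fit$par)
  n <- sum(keep)
  structure(list(params = subject_eye_params(fit$par[["alpha"]],
                                             fit$par[["beta"]]),
                 rms_residual = sqrt(sum(rF^2) / n),
                 n_samples_used = n,
                 n_dropped = n_dropped,
                 converged = fit$info %in% 1:3,
                 objective_initial = sum(r0^2),
                 objective_final = sum(rF^2)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(paste0("<calibration_result> alpha = %.4f deg, beta = %.4f deg\n",
                     "  rms residual = %.4g mm over %d samples (%d dropped)%s\n"),
              x$params$alpha, x$params$beta, x$rms_residual,
              x$n_samples_used, x$n_dropped,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Attach calibrated subject parameters to a session
#'
#' Downstream estimation ([estimate_pog()], [error_report()]) picks up the
#' session's calibrated parameters when none are passed explicitly.
#' Re-attaching overwrites the previous values (with a message).
#'
#' @param params [subject_eye_params()] or a `"calibration_result"`.
#' @param session A `"gaze_session"` with at least one sample.
#' @return The session with `subject_calibrated` set.
#' @export
apply_subject <- function(params, session) {
  stopifnot(inherits(session, "gaze_session"))
  if (nrow(session$samples) == 0L)
    .rg_stop("cannot attach parameters to an empty session",
             "rollgaze_empty_session")
  if (inherits(params, "calibration_result")) params <- params$params
  params <- .as_subject_params(params)
  if (!is.null(session$subject_calibrated))
    message("overwriting previously attached subject parameters")
  session$subject_calibrated <- params
  session
}
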