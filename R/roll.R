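# Roll-induced PoG error law. With pitch and yaw at zero, a relative roll
# lam rotates the visual axis about the optical axis; the angle delta between
# the rolled and unrolled visual axes depends only on lam and the offsets
# (alpha, beta). The rotation-matrix path is the normative ground truth; the
# closed form is its algebraic simplification and is validated against it.

#' Roll-induced angular error via the rotation-matrix path
#'
#' Angular difference (degrees) between the visual axis computed with
#' relative roll `lam` and with roll 0, for a frontal optical axis
#' (pitch = yaw = 0): delta = angle(R(lam) nu_ECS, R(0) nu_ECS).
#' This is the error committed by a PoG estimator that assumes the roll
#' is zero when it is in fact `lam`.
#'
#' @param params A [subject_eye_params()] object.
#' @param lam Relative roll angle(s), degrees. Vectorised.
#' @return Numeric vector of delta in degrees, in `[0, 180]`.
#' @examples
#' delta_matrix(subject_eye_params(3, 1.5), 90) # ~4.7 deg for an average eye
#' @export
delta_matrix <- function(params, lam) {
  params <- .as_subject_params(params)
  omega <- c(0, 0, -1)
  nu0 <- visual_axis_in_dcs(omega, params, 0)
  vapply(lam, function(l) {
    nu <- visual_axis_in_dcs(omega, params, l)
    # atan2 of (||cross||, dot) is stable near 0 and 180 deg, where acos
    # of the dot product loses half its digits
    cr <- .cross3(nu, nu0)
    .undeg(atan2(sqrt(sum(cr * cr)), sum(nu * nu0)))
  }, numeric(1L))
}

#' Roll-induced angular error, closed form
#'
#' Closed-form equivalent of [delta_matrix()]:
#' cos(delta) = cos(lam) + (1 - cos(lam)) cos^2(alpha) cos^2(beta).
#' Writing kappa for the total optical-visual offset
#' (cos(kappa) = cos(alpha)cos(beta)) this is the chord formula for two
#' directions at polar angle kappa separated by azimuth lam about the roll
#' axis; it is independent of the gaze direction.
#'
#' @inheritParams delta_matrix
#' @return Numeric vector of delta in degrees.
#' @export
delta_closed_form <- function(params, lam) {
  params <- .as_subject_params(params)
  k <- (cos(.deg(params$alpha)) * cos(.deg(params$beta)))^2
  # half-angle form of cos(delta) = cos(lam) + (1 - cos(lam)) k:
  # sin(delta/2) = |sin(lam/2)| sin(kappa), numerically stable at small delta
  sin_kappa <- sqrt(pmax(0, 1 - k))
  .undeg(2 * asin(.clamp1(abs(sin(.deg(lam) / 2)) * sin_kappa)))
}

#' Roll-error curve over a grid of roll angles
#'
#' @inheritParams delta_matrix
#' @param lambda_grid Roll angles in degrees, within `[-180, 180]`.
#' @return A data frame with columns `alpha_deg`, `beta_deg`, `lambda_deg`,
#'   `delta_deg`, suitable for CSV export and plotting.
#' @export
delta_curve <- function(params, lambda_grid = seq(0, 180, by = 1)) {
  params <- .as_subject_params(params)
  lambda_grid <- as.numeric(lambda_grid)
  if (any(!is.finite(lambda_grid)) || any(abs(lambda_grid) > 180))
    .rg_stop("roll grid must lie within [-180, 180] degrees",
             "rollgaze_bad_grid")
  data.frame(alpha_deg = params$alpha,
             beta_deg = params$beta,
             lambda_deg = lambda_grid,
             delta_deg = delta_matrix(params, lambda_grid))
}

#' Sensitivity of the roll error to roll-measurement error
#'
#' Central finite difference (delta(lam + 0.5) - delta(lam - 0.5)) / 1 deg:
#' the change in visual-axis direction per degree of error in the measured
#' roll. For an average eye near lam = 90 deg this is about 0.04 deg/deg,
#' which is why modest head-tracker noise (< 1 deg) barely affects the PoG.
#'
#' @inheritParams delta_matrix
#' @param step Half-width of the finite difference, degrees.
#' @return Sensitivity in degrees of delta per degree of lam.
#' @export
roll_sensitivity <- function(params, lam, step = 0.5) {
  (delta_matrix(params, lam + step) - delta_matrix(params, lam - step)) /
    (2 * step)
}

#' On-screen shift corresponding to an angular error
#'
#' Projects an angular visual-axis error onto the display:
#' shift = viewing_distance * tan(delta).
#'
#' @param delta Angular error in degrees, `0 <= delta < 90`.
#' @param viewing_distance Eye-to-display distance in mm, positive.
#' @return Shift in mm.
#' @examples
#' pog_shift_mm(4.74, 300) # ~25 mm: a third of a phone display width
#' @export
pog_shift_mm <- function(delta, viewing_distance) {
  if (any(viewing_distance <= 0))
    .rg_stop("viewing distance must be positive", "rollgaze_bad_distance")
  if (any(delta < 0 | delta >= 90))
    .rg_stop("delta must be in [0, 90) degrees", "rollgaze_bad_grid")
  viewing_distance * tan(.deg(delta))
}

#' Predicted-vs-measured roll-error table
#'
#' Evaluates the roll-error law for a set of subjects at the given roll
#' angles and, when measured values are supplied, derives the comparison
#' statistics: per-cell absolute differences, their mean, and the Pearson
#' correlation of the measured error at `cor_lambda` against both the total
#' offset magnitude sqrt(alpha^2 + beta^2) and the predicted error.
#'
#' @param subjects Data frame with columns `subject`, `alpha`, `beta`
#'   (degrees), e.g. [benchmark_subjects()].
#' @param lams Roll angles in degrees.
#' @param measured Optional data frame with columns `subject`, `lambda_deg`,
#'   `delta_measured_deg`, e.g. [benchmark_roll_deltas()].
#' @param cor_lambda Roll angle (degrees) at which the correlations are
#'   computed; must be one of `lams` values present in `measured`.
#' @return A list of class `"delta_table"`: `table` (long data frame with
#'   `delta_theory_deg` and, if available, `delta_measured_deg`, `abs_diff_deg`),
#'   `mean_abs_diff_deg`, `cor_vs_offset`, `cor_vs_theory` (NULL without
#'   measured data).
#' @export
delta_table <- function(subjects, lams, measured = NULL, cor_lambda = 90) {
  stopifnot(is.data.frame(subjects), nrow(subjects) >= 1L, length(lams) >= 1L)
  if (!all(c("subject", "alpha", "beta") %in% names(subjects)))
    .rg_stop("subjects needs columns subject, alpha, beta",
             "rollgaze_missing_column")
  tab <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
    pars <- subject_eye_params(subjects$alpha[i], subjects$beta[i])
    data.frame(subject = subjects$subject[i],
               alpha_deg = pars$alpha, beta_deg = pars$beta,
               lambda_deg = as.numeric(lams),
               delta_theory_deg = delta_matrix(pars, lams))
  }))
  out <- list(table = tab, mean_abs_diff_deg = NULL,
              cor_vs_offset = NULL, cor_vs_theory = NULL)
  if (!is.null(measured)) {
    if (!all(c("subject", "lambda_deg", "delta_measured_deg") %in%
             names(measured)))
      .rg_stop("measured needs columns subject, lambda_deg, delta_measured_deg",
               "rollgaze_missing_column")
    tab <- merge(tab, measured, by = c("subject", "lambda_deg"),
                 all.x = TRUE, sort = FALSE)
    tab <- tab[order(tab$subject, tab$lambda_deg), ]
    rownames(tab) <- NULL
    tab$abs_diff_deg <- abs(tab$delta_theory_deg - tab$delta_measured_deg)
    out$table <- tab
    out$mean_abs_diff_deg <- mean(tab$abs_diff_deg, na.rm = TRUE)
    at <- tab[!is.na(tab$delta_measured_deg) & tab$lambda_deg == cor_lambda, ]
    if (nrow(at) >= 3L) {
      offset <- sqrt(at$alpha_deg^2 + at$beta_deg^2)
      out$cor_vs_offset <- stats::cor(at$delta_measured_deg, offset)
      out$cor_vs_theory <- stats::cor(at$delta_measured_deg,
                                      at$delta_theory_deg)
    }
  }
  class(out) <- "delta_table"
  out
}

#' @export
print.delta_table <- function(x, digits = 2, ...) {
  cat("Roll-induced PoG error: predicted vs measured\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1L))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  if (!is.null(x$mean_abs_diff_deg))
    cat(sprintf("mean |theory - measured| = %.*f deg\n", digits,
                x$mean_abs_diff_deg))
  if (!is.null(x$cor_vs_offset))
    cat(sprintf("cor(measured, sqrt(alpha^2+beta^2)) = %.*f; cor(measured, theory) = %.*f\n",
                digits, x$cor_vs_offset, digits, x$cor_vs_theory))
  invisible(x)
}
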