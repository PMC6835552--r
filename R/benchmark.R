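# Reference measurements from a published four-subject evaluation of a
# prototype infrared smartphone eye tracker (chin rest, 30 cm viewing
# distance, set relative-roll angles of 0/45/90 deg, five fixation targets).
# Bundled so that predicted-vs-measured comparisons and the study's summary
# statistics are reproducible without the recorded videos.

#' Benchmark subjects: calibrated optical-visual axis offsets
#'
#' Per-subject magnitudes of the horizontal (`alpha`) and vertical (`beta`)
#' offsets between the optical and visual axes, in degrees, as calibrated in
#' a four-subject evaluation of a prototype infrared smartphone gaze tracker.
#'
#' @return Data frame with columns `subject`, `alpha`, `beta`.
#' @seealso [benchmark_roll_deltas()], [benchmark_gaze_errors()], [delta_table()]
#' @export
benchmark_subjects <- function() {
  data.frame(subject = c("01", "02", "03", "04"),
             alpha = c(1.73, 1.21, 1.78, 2.67),
             beta  = c(0.50, 0.28, 0.92, 0.25))
}

#' Benchmark measured roll-induced PoG differences
#'
#' Experimentally measured angular differences (degrees) between PoG
#' estimation with the measured relative roll and with roll assumed zero,
#' for the [benchmark_subjects()] at set rolls of 45 and 90 degrees.
#'
#' @return Data frame with columns `subject`, `lambda_deg`,
#'   `delta_measured_deg`.
#' @export
benchmark_roll_deltas <- function() {
  data.frame(subject = rep(c("01", "02", "03", "04"), each = 2L),
             lambda_deg = rep(c(45, 90), 4L),
             delta_measured_deg = c(1.22, 2.08,
                                    0.86, 1.76,
                                    1.36, 2.72,
                                    1.81, 2.78))
}

#' Benchmark per-subject gaze-estimation errors
#'
#' Average gaze-estimation error per subject, estimation method and set roll
#' angle from the same evaluation: method 2 uses the measured relative roll,
#' method 1 assumes roll 0. Errors are reported both as mean on-screen
#' distance (mm) and as visual angle (degrees) at the 300 mm viewing
#' distance.
#'
#' @return Data frame with columns `subject`, `method`, `roll_deg`,
#'   `err_mm`, `err_deg`.
#' @export
benchmark_gaze_errors <- function() {
  subj <- rep(c("01", "02", "03", "04"), each = 6L)
  method <- rep(rep(c(2L, 1L), each = 3L), 4L)
  roll <- rep(c(0, 45, 90), 8L)
  err_mm <- c(5.07, 4.70, 5.05,   4.91, 11.11, 15.96,
              3.73, 4.55, 5.18,   3.52,  9.08, 14.39,
              3.15, 4.77, 4.12,   3.14, 11.91, 18.42,
              7.23, 5.94, 10.05,  7.31, 15.44, 24.66)
  err_deg <- c(0.96, 0.89, 0.96,  0.93, 2.12, 2.75,
               0.71, 0.86, 0.98,  0.67, 1.73, 2.74,
               0.60, 0.91, 0.78,  0.59, 2.27, 3.51,
               1.38, 1.13, 1.91,  1.39, 2.94, 4.69)
  data.frame(subject = subj, method = method, roll_deg = roll,
             err_mm = err_mm, err_deg = err_deg)
}
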