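# Simulation configuration files (JSON, or YAML when the yaml package is
# available). All keys optional; missing keys fall back to the protocol
# defaults documented in simulate_session().

#' Read a simulation configuration
#'
#' Recognised keys: `screen` (`width_mm`, `height_mm`),
#' `viewing_distance_mm`, `targets` (list/data frame of `target_id`,
#' `x_mm`, `y_mm`), `rolls_deg`, `frames_per_target`, `alpha_deg`,
#' `beta_deg`, `feature_sigma_mm`, `tracker_sigma_deg`, `seed`, `d_pc_mm`,
#' `head_tilt_deg`, `counter_roll_gain`.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A named list of configuration values.
#' @export
read_sim_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      .rg_stop("the yaml package is needed to read YAML configs",
               "rollgaze_missing_dep")
    cfg <- yaml::read_yaml(path)
  } else {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.list(cfg))
    .rg_stop("configuration must be a mapping of keys to values",
             "rollgaze_bad_config")
  cfg
}

#' Simulate a session from a configuration list
#'
#' @param cfg A list as returned by [read_sim_config()].
#' @return A `"gaze_session"` (see [simulate_session()]).
#' @export
simulate_from_config <- function(cfg) {
  screen <- if (is.null(cfg$screen)) screen_geometry() else
    screen_geometry(cfg$screen$width_mm, cfg$screen$height_mm)
  targets <- if (is.null(cfg$targets)) NULL else
    as.data.frame(cfg$targets)
  protocol <- fixation_protocol(
    rolls = if (is.null(cfg$rolls_deg)) c(0, 45, 90) else cfg$rolls_deg,
    frames_per_target = if (is.null(cfg$frames_per_target)) 150 else
      cfg$frames_per_target,
    targets = targets)
  noise <- noise_config(
    feature_sigma = if (is.null(cfg$feature_sigma_mm)) 0.035 else
      cfg$feature_sigma_mm,
    tracker_sigma = if (is.null(cfg$tracker_sigma_deg)) 0.5 else
      cfg$tracker_sigma_deg,
    seed = cfg$seed)
  simulate_session(
    params = subject_eye_params(
      if (is.null(cfg$alpha_deg)) 3 else cfg$alpha_deg,
      if (is.null(cfg$beta_deg)) 1.5 else cfg$beta_deg),
    protocol = protocol,
    screen = screen,
    viewing_distance = if (is.null(cfg$viewing_distance_mm)) 300 else
      cfg$viewing_distance_mm,
    noise = noise,
    d_pc = if (is.null(cfg$d_pc_mm)) 4 else cfg$d_pc_mm,
    head_tilt_wrt_gravity = if (is.null(cfg$head_tilt_deg)) 0 else
      cfg$head_tilt_deg,
    counter_roll_gain = if (is.null(cfg$counter_roll_gain)) 0 else
      cfg$counter_roll_gain)
}
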