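# Session CSV format: '#'-prefixed 'key: value' metadata header lines
# followed by one CSV row per frame. Numeric fields are written with 17
# significant digits so a write/read cycle is lossless at double precision,
# and the byte stream is a pure function of the session (determinism
# contract for seeded simulations).

.session_columns <- c("frame", "target_id", "target_x_mm", "target_y_mm",
                      "p_x", "p_y", "p_z", "c_x", "c_y", "c_z",
                      "lam_true_deg", "lam_measured_deg")

.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[x == round(x) & abs(x) < 1e15] <- sprintf("%g", x[x == round(x) &
                                                          abs(x) < 1e15])
  out
}

#' Write a session to CSV
#'
#' @param session A `"gaze_session"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_session()] for the schema.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "gaze_session"))
  s <- session$samples
  meta <- c(
    "# gaze-session-csv v1",
    sprintf("# screen_width_mm: %s", .fmt_num(session$screen$width)),
    sprintf("# screen_height_mm: %s", .fmt_num(session$screen$height)),
    sprintf("# viewing_distance_mm: %s", .fmt_num(session$viewing_distance)),
    sprintf("# d_pc_mm: %s", .fmt_num(session$d_pc)))
  if (!is.null(session$noise$seed))
    meta <- c(meta, sprintf("# seed: %d", session$noise$seed))
  if (!is.null(session$subject_truth))
    meta <- c(meta,
              sprintf("# alpha_true_deg: %s", .fmt_num(session$subject_truth$alpha)),
              sprintf("# beta_true_deg: %s", .fmt_num(session$subject_truth$beta)))
  if (!is.null(session$subject_calibrated))
    meta <- c(meta,
              sprintf("# alpha_cal_deg: %s", .fmt_num(session$subject_calibrated$alpha)),
              sprintf("# beta_cal_deg: %s", .fmt_num(session$subject_calibrated$beta)))
  cols <- c("frame", "roll_deg", "target_id", "target_x_mm", "target_y_mm",
            "p_x", "p_y", "p_z", "c_x", "c_y", "c_z",
            "lam_true_deg", "lam_measured_deg")
  body <- s[, cols]
  num <- vapply(body, is.numeric, logical(1L))
  body[num] <- lapply(body[num], .fmt_num)
  lines <- c(meta, paste(cols, collapse = ","),
             do.call(paste, c(unname(as.list(body)), sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a session from CSV
#'
#' Reads the session format written by [write_session()]: metadata header
#' lines (`# key: value`) followed by per-frame rows. Required columns are
#' `frame`, `target_id`, `target_x_mm`, `target_y_mm`, `p_x`, `p_y`, `p_z`,
#' `c_x`, `c_y`, `c_z`, `lam_true_deg`, `lam_measured_deg`; the optional
#' `roll_deg` column (nominal set roll of each protocol block) defaults to
#' `lam_true_deg`. Malformed rows are reported with their line number.
#'
#' @param path Input file path.
#' @return A `"gaze_session"` (with `subject_truth`/`subject_calibrated`
#'   populated from the metadata when present).
#' @export
read_session <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L)
    .rg_stop("empty session file", "rollgaze_empty_session")
  is_meta <- grepl("^#", lines)
  n_meta <- match(FALSE, is_meta, nomatch = length(lines) + 1L) - 1L
  meta <- list()
  for (ln in lines[seq_len(n_meta)]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_0-9]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- m[3L]
  }
  body <- lines[-seq_len(n_meta)]
  if (length(body) < 2L)
    .rg_stop("session file has no data rows", "rollgaze_empty_session")
  df <- tryCatch(
    utils::read.csv(text = body, stringsAsFactors = FALSE,
                    colClasses = NA),
    error = function(e) .rg_stop(paste0("cannot parse session CSV: ",
                                        conditionMessage(e)),
                                 "rollgaze_malformed_row"))
  missing_cols <- setdiff(.session_columns, names(df))
  if (length(missing_cols) > 0L)
    .rg_stop(paste0("session file is missing required column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "rollgaze_missing_column")
  if (!"roll_deg" %in% names(df)) df$roll_deg <- df$lam_true_deg
  num_cols <- setdiff(c(.session_columns, "roll_deg"), "target_id")
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L)
      .rg_stop(sprintf("non-numeric or non-finite value in column '%s' at line %d",
                       col, n_meta + 1L + bad[1L]),
               "rollgaze_malformed_row")
    df[[col]] <- v
  }
  df$target_id <- as.character(df$target_id)

  getnum <- function(key, default) {
    if (is.null(meta[[key]])) default else as.numeric(meta[[key]])
  }
  screen <- screen_geometry(getnum("screen_width_mm", 110),
                            getnum("screen_height_mm", 62))
  targets <- unique(df[, c("target_id", "target_x_mm", "target_y_mm")])
  names(targets) <- c("target_id", "x_mm", "y_mm")
  rownames(targets) <- NULL
  truth <- if (!is.null(meta$alpha_true_deg))
    subject_eye_params(as.numeric(meta$alpha_true_deg),
                       as.numeric(meta$beta_true_deg)) else NULL
  calib <- if (!is.null(meta$alpha_cal_deg))
    subject_eye_params(as.numeric(meta$alpha_cal_deg),
                       as.numeric(meta$beta_cal_deg)) else NULL
  seed <- if (!is.null(meta$seed)) as.integer(meta$seed) else NULL
  rolls <- unique(df$roll_deg)
  frames_per_target <- nrow(df) /
    max(1L, nrow(unique(df[, c("roll_deg", "target_id")])))
  structure(list(samples = df[, c("frame", "roll_deg", "target_id",
                                  "target_x_mm", "target_y_mm",
                                  "p_x", "p_y", "p_z",
                                  "c_x", "c_y", "c_z",
                                  "lam_true_deg", "lam_measured_deg")],
                 targets = targets,
                 screen = screen,
                 viewing_distance = getnum("viewing_distance_mm", 300),
                 subject_truth = truth,
                 subject_calibrated = calib,
                 protocol = fixation_protocol(
                   rolls = rolls,
                   frames_per_target = max(1L, round(frames_per_target)),
                   targets = targets),
                 noise = noise_config(seed = seed),
                 d_pc = getnum("d_pc_mm", 4),
                 eye_position = NULL),
            class = "gaze_session")
}
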