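test_that("per-frame estimation flags degenerate frames instead of failing", {
  s <- tiny_session(frames = 2)
  # flip one frame's pupil to the far side: optical axis points away
  s$samples$p_z[1] <- s$samples$c_z[1] + 4
  s$samples$p_x[1] <- s$samples$c_x[1]
  s$samples$p_y[1] <- s$samples$c_y[1]
  est <- estimate_pog(s, avg_eye(), method = 2)
  expect_false(est$valid[1])
  expect_true(all(est$valid[-1]))
  expect_true(is.na(est$x[1]))
  expect_error(estimate_pog(s, avg_eye(), method = 3),
               class = "rollgaze_bad_method")
  expect_error(estimate_pog(s, NULL, 2), class = "rollgaze_missing_params")
})

test_that("distance-to-angle conversion matches the benchmark's convention", {
  expect_equal(mm_to_degrees(5.07, 300), 0.97, tolerance = 0.005)
  expect_equal(mm_to_degrees(0, 123), 0)
  expect_equal(mm_to_degrees(300, 300), 45)
  expect_error(mm_to_degrees(5, 0), class = "rollgaze_bad_distance")
})

test_that("per-target error is the mean distance over valid estimates", {
  est <- data.frame(x = c(3, -3), y = c(4, -4), valid = TRUE)
  expect_equal(per_target_error(est, c(0, 0)), 5)
  expect_equal(per_target_error(data.frame(x = 1, y = 2, valid = TRUE),
                                c(1, 2)), 0)
  mixed <- data.frame(x = c(3, 100), y = c(4, 100), valid = c(TRUE, FALSE))
  expect_equal(per_target_error(mixed, c(0, 0)), 5)
  expect_error(per_target_error(data.frame(x = 1, y = 1, valid = FALSE),
                                c(0, 0)),
               class = "rollgaze_no_valid_estimates")
})

test_that("95% enclosing radius is the interpolated distance percentile", {
  th <- seq_len(100) * 0.7
  est <- data.frame(x = (1:100) * cos(th), y = (1:100) * sin(th),
                    valid = TRUE)
  expect_equal(radius_95(est, c(0, 0)), 95.05)
  # rotation of the cloud about the target leaves the radius unchanged
  rot <- 1.1
  est2 <- data.frame(x = est$x * cos(rot) - est$y * sin(rot),
                     y = est$x * sin(rot) + est$y * cos(rot),
                     valid = TRUE)
  expect_equal(radius_95(est2, c(0, 0)), radius_95(est, c(0, 0)),
               tolerance = 1e-9)
  tight <- data.frame(x = rep(5, 25), y = rep(-2, 25), valid = TRUE)
  expect_equal(radius_95(tight, c(5, -2)), 0)
  expect_error(radius_95(est[1:10, ], c(0, 0)),
               class = "rollgaze_too_few_samples")
})

test_that("distinct-target capacity follows the grid-packing rule", {
  scr <- screen_geometry(110, 62)
  expect_equal(distinct_targets(12, scr), 45L)
  expect_equal(distinct_targets(70, scr), 0L)
  radii <- c(5, 10, 20, 40, 80)
  counts <- vapply(radii, distinct_targets, integer(1), screen = scr)
  expect_true(all(diff(counts) <= 0))
  expect_error(distinct_targets(0, scr), class = "rollgaze_bad_radius")
})

test_that("error reports aggregate per-target means and convert to degrees", {
  s <- tiny_session(frames = 25)
  rep2 <- error_report(s, avg_eye(), method = 2)
  expect_lt(max(rep2$per_roll$err_mm), 1e-6)
  expect_equal(rep2$per_roll$n_valid, rep(125L, 3))

  rep1 <- error_report(s, avg_eye(), method = 1)
  # aggregate = unweighted mean over targets
  for (r in rep1$per_roll$roll_deg) {
    pt <- rep1$per_target[rep1$per_target$roll_deg == r, ]
    agg <- rep1$per_roll[rep1$per_roll$roll_deg == r, ]
    expect_equal(agg$err_mm, mean(pt$err_mm), tolerance = 1e-12)
    expect_equal(agg$err_deg, mm_to_degrees(agg$err_mm, 300),
                 tolerance = 1e-12)
  }
  # centre target: planar angular error equals the roll-error law exactly
  delta90 <- delta_matrix(avg_eye(), 90)
  ctr <- rep1$per_target[rep1$per_target$roll_deg == 90 &
                           rep1$per_target$target_id == "C", ]
  expect_equal(mm_to_degrees(ctr$err_mm, 300), delta90, tolerance = 1e-6)
  # aggregate over eccentric targets stays close to the law
  agg90 <- rep1$per_roll$err_deg[rep1$per_roll$roll_deg == 90]
  expect_lt(abs(agg90 - delta90), 0.2)
  # the true ray angle equals the law at every target and frame
  est1 <- estimate_pog(s, avg_eye(), 1)
  i90 <- which(s$samples$roll_deg == 90)
  for (i in i90[seq(1, length(i90), by = 40)]) {
    cp <- unlist(s$samples[i, c("c_x", "c_y", "c_z")])
    ray_est <- c(est1$x[i], est1$y[i], 0) - cp
    ray_tgt <- c(s$samples$target_x_mm[i], s$samples$target_y_mm[i], 0) - cp
    expect_equal(vec_angle_deg(ray_est, ray_tgt), delta90, tolerance = 1e-9)
  }
})

test_that("session CSV survives a lossless round trip", {
  s <- tiny_session(frames = 3, feature_sigma = 0.05, tracker_sigma = 0.5,
                    seed = 31)
  s <- apply_subject(subject_eye_params(2.9, 1.4), s)
  f <- tempfile(fileext = ".csv")
  write_session(s, f)
  s2 <- read_session(f)
  num <- setdiff(names(s$samples), "target_id")
  expect_equal(s2$samples[num], s$samples[num], tolerance = 1e-15)
  expect_identical(s2$samples$target_id, s$samples$target_id)
  expect_equal(s2$screen$width, s$screen$width)
  expect_equal(s2$viewing_distance, s$viewing_distance)
  expect_equal(s2$subject_truth$alpha, 3)
  expect_equal(s2$subject_calibrated$alpha, 2.9)
  # estimates computed from the re-read session are identical
  e1 <- estimate_pog(s, method = 2)
  e2 <- estimate_pog(s2, method = 2)
  expect_equal(e2$x, e1$x, tolerance = 1e-12)
})

test_that("session reader reports schema violations precisely", {
  s <- tiny_session(frames = 2)
  f <- tempfile(fileext = ".csv")
  write_session(s, f)
  lines <- readLines(f)

  header_at <- grep("^frame,", lines)
  drop_lam <- sub(",lam_measured_deg", "", lines[header_at])
  bad <- lines
  bad[header_at] <- drop_lam
  bad[-seq_len(header_at)] <- sub(",[^,]*$", "", bad[-seq_len(header_at)])
  f2 <- tempfile(fileext = ".csv")
  writeLines(bad, f2)
  expect_error(read_session(f2), "lam_measured_deg",
               class = "rollgaze_missing_column")

  f3 <- tempfile(fileext = ".csv")
  writeLines(character(0), f3)
  expect_error(read_session(f3), class = "rollgaze_empty_session")

  bad_row <- lines
  bad_row[header_at + 2L] <- sub("^([0-9]+),[-0-9.e+]+", "\\1,oops",
                                 bad_row[header_at + 2L])
  f4 <- tempfile(fileext = ".csv")
  writeLines(bad_row, f4)
  err <- tryCatch(read_session(f4), error = function(e) e)
  expect_s3_class(err, "rollgaze_malformed_row")
  expect_match(conditionMessage(err), as.character(header_at + 2L))
})
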