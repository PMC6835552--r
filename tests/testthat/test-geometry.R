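test_that("optical axis from gaze angles matches the spherical form and round-trips", {
  expect_equal(optical_axis_from_angles(eye_angles(0, 0)), c(0, 0, -1))
  expect_equal(optical_axis_from_angles(eye_angles(90, 0)), c(1, 0, 0))
  expect_equal(optical_axis_from_angles(eye_angles(30, 0)),
               c(sin(pi / 6), 0, -cos(pi / 6)))

  set.seed(11)
  for (i in 1:50) {
    th <- runif(1, -170, 170); ph <- runif(1, -85, 85)
    ang <- angles_from_direction(optical_axis_from_angles(eye_angles(th, ph)))
    expect_equal(ang$theta, th, tolerance = 1e-9)
    expect_equal(ang$phi, ph, tolerance = 1e-9)
  }
  expect_error(eye_angles(0, 90), class = "rollgaze_degenerate_pitch")
  expect_error(angles_from_direction(c(0, 1, 0)), class = "rollgaze_gimbal")
})

test_that("optical axis from pupil/cornea centres is the normalised difference", {
  expect_equal(optical_axis_from_pc(point3(0, 0, 296), point3(0, 0, 300)),
               c(0, 0, -1))
  expect_equal(optical_axis_from_pc(point3(2, 0, 298), point3(0, 0, 300)),
               c(1, 0, -1) / sqrt(2))
  expect_error(optical_axis_from_pc(point3(1, 2, 3), point3(1, 2, 3)),
               class = "rollgaze_coincident_points")
})

test_that("eye-frame visual axis follows the kappa offsets", {
  expect_equal(visual_axis_in_ecs(subject_eye_params(0, 0)), c(0, 0, 1))
  a <- 3 * pi / 180; b <- 1.5 * pi / 180
  nu <- visual_axis_in_ecs(subject_eye_params(3, 1.5))
  expect_equal(nu, c(sin(a) * cos(b), sin(b), cos(a) * cos(b)),
               tolerance = 1e-12)
  expect_equal(nu, c(0.05232, 0.02618, 0.99829), tolerance = 1e-4)
  nun <- visual_axis_in_ecs(subject_eye_params(-3, 1.5))
  expect_equal(nun, nu * c(-1, 1, 1), tolerance = 1e-12)
  expect_error(subject_eye_params(11, 0), class = "rollgaze_invalid_params")
})

test_that("eye coordinate frame reproduces the frontal rotation matrices", {
  fr0 <- ecs_frame(c(0, 0, -1), 0)
  expect_equal(unname(unclass(fr0)),
               cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, -1)),
               ignore_attr = TRUE)
  fr90 <- ecs_frame(c(0, 0, -1), 90)
  expect_equal(unname(unclass(fr90)),
               cbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, -1)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(ecs_frame(c(0, 1, 0), 30), class = "rollgaze_degenerate_frame")
})

test_that("eye coordinate frame is orthonormal with z on the optical axis, and rolls compose", {
  set.seed(12)
  for (i in 1:40) {
    omega <- as_direction3(c(runif(1, -1, 1), runif(1, -0.7, 0.7),
                             runif(1, -1, -0.2)))
    l1 <- runif(1, -180, 180); l2 <- runif(1, -180, 180)
    fr <- unclass(ecs_frame(omega, l1))
    g <- crossprod(fr)
    expect_lt(max(abs(g - diag(3))), 1e-9)
    expect_identical(fr[, "z_eye"], omega)
    # y_eye = x_eye x z_eye (handedness convention)
    xz <- unname(c(fr[2, 1] * fr[3, 3] - fr[3, 1] * fr[2, 3],
                   fr[3, 1] * fr[1, 3] - fr[1, 1] * fr[3, 3],
                   fr[1, 1] * fr[2, 3] - fr[2, 1] * fr[1, 3]))
    expect_equal(unname(fr[, "y_eye"]), xz, tolerance = 1e-12)
    # rolling by l1 then l2 equals rolling by l1 + l2
    f1 <- unclass(ecs_frame(omega, l1))
    c2 <- cos(l2 * pi / 180); s2 <- sin(l2 * pi / 180)
    x12 <- c2 * f1[, "x_eye"] + s2 * f1[, "y_eye"]
    y12 <- -s2 * f1[, "x_eye"] + c2 * f1[, "y_eye"]
    f12 <- unclass(ecs_frame(omega, l1 + l2))
    expect_equal(unname(f12[, "x_eye"]), unname(x12), tolerance = 1e-9)
    expect_equal(unname(f12[, "y_eye"]), unname(y12), tolerance = 1e-9)
  }
})

test_that("visual axis in device coordinates rotates the kappa offset with roll", {
  p <- subject_eye_params(3, 1.5)
  nu0 <- visual_axis_in_dcs(c(0, 0, -1), p, 0)
  expect_equal(nu0, c(0.05232, 0.02618, -0.99829), tolerance = 1e-4)
  nu90 <- visual_axis_in_dcs(c(0, 0, -1), p, 90)
  expect_equal(nu90, c(-0.02618, 0.05232, -0.99829), tolerance = 1e-4)
  # the rolled and unrolled axes subtend the roll-error angle, ~4.7 deg
  expect_equal(vec_angle_deg(nu0, nu90), 4.7, tolerance = 0.05)
})

test_that("additive Euler parameterisation agrees with the frame path", {
  p <- subject_eye_params(3, 1.5)
  expect_equal(visual_axis_euler(eye_angles(0, 0), subject_eye_params(0, 0)),
               c(0, 0, -1))
  expect_equal(visual_axis_euler(eye_angles(0, 0), p),
               visual_axis_in_dcs(c(0, 0, -1), p, 0), tolerance = 1e-12)
  # exact agreement at zero pitch, any yaw
  for (th in seq(-75, 75, by = 15)) {
    omega <- optical_axis_from_angles(eye_angles(th, 0))
    expect_equal(visual_axis_in_dcs(omega, p, 0),
                 visual_axis_euler(eye_angles(th, 0), p), tolerance = 1e-12)
  }
  # second-order agreement for modest pitch; the worst case over this box
  # sits at its corner and is 0.127 deg
  set.seed(13)
  for (i in 1:40) {
    th <- runif(1, -10, 10); ph <- runif(1, -10, 10)
    a <- runif(1, -5, 5); b <- runif(1, -3, 3)
    omega <- optical_axis_from_angles(eye_angles(th, ph))
    d <- vec_angle_deg(visual_axis_in_dcs(omega, subject_eye_params(a, b), 0),
                       visual_axis_euler(eye_angles(th, ph),
                                         subject_eye_params(a, b)))
    expect_lt(d, 0.15)
  }
  expect_error(visual_axis_euler(eye_angles(0, 89), subject_eye_params(2, 2)),
               class = "rollgaze_degenerate_pitch")
})

test_that("PoG is the ray-display intersection and is ray-consistent", {
  scr <- screen_geometry()
  expect_equal(as.numeric(pog_on_screen(point3(0, 0, 300), c(0, 0, -1), scr)),
               c(0, 0))
  nu <- as_direction3(c(0.05232, 0.02618, -0.99829))
  g <- pog_on_screen(point3(0, 0, 300), nu)
  expect_equal(as.numeric(g), c(15.72, 7.87), tolerance = 0.01)
  expect_error(pog_on_screen(point3(0, 0, 300), c(0, 0, 1)),
               class = "rollgaze_no_intersection")
  # off-screen intersections are flagged, not clamped
  far <- pog_on_screen(point3(0, 0, 300), as_direction3(c(0.5, 0, -0.5)), scr)
  expect_false(attr(far, "on_screen"))
  expect_gt(far[["x"]], scr$width / 2)
  # re-deriving the direction c -> (PoG, 0) recovers nu
  set.seed(14)
  for (i in 1:30) {
    cp <- point3(runif(1, -20, 20), runif(1, -20, 20), runif(1, 200, 400))
    nu <- as_direction3(c(runif(1, -0.3, 0.3), runif(1, -0.3, 0.3), -1))
    g <- pog_on_screen(cp, nu)
    back <- as_direction3(c(g[["x"]], g[["y"]], 0) - cp)
    expect_equal(back, nu, tolerance = 1e-9)
  }
})

test_that("directions are unit norm and degenerate vectors are rejected", {
  set.seed(15)
  for (i in 1:20) {
    v <- as_direction3(rnorm(3) * 10)
    expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-12)
  }
  expect_error(as_direction3(c(0, 0)), class = "rollgaze_bad_vector")
  expect_error(as_direction3(c(1e-12, 0, 0)), class = "rollgaze_bad_vector")
  expect_error(point3(1, 2, Inf), class = "rollgaze_bad_vector")
})
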