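test_that("IK recovers known coordinates from noise-free markers", {
  w <- make_fixture("planar_walker")
  set.seed(21)
  q_true <- c(0.3, 1.0, 0.1, runif(6, -0.5, 0.5))
  fk <- forward_kinematics(w, q_true)
  fr <- observation_frame(0, markers = fk$markers)
  sol <- solve_frame(w, fr, q_init = c(0, 0.9, 0, numeric(6)))
  expect_lt(max(abs(sol$q - q_true)), 1e-6)
  expect_true(sol$converged)
  # objective at the solution never exceeds the starting objective
  r0 <- rtmsk:::ik_residual(w, fr, c(0, 0.9, 0, numeric(6)))
  expect_lte(sol$objective, 0.5 * sum(r0^2))
})

test_that("orientation-only tracking recovers the pendulum angle", {
  p <- make_fixture("pendulum")
  fk <- forward_kinematics(p, 0.7)
  fr <- observation_frame(0, orientations = fk$imus)
  sol <- solve_frame(p, fr, q_init = 0)
  expect_lt(abs(sol$q - 0.7), 1e-6)
})

test_that("zero-weight markers do not influence the solution", {
  w <- make_fixture("planar_walker")
  q_true <- c(0.1, 0.98, 0.05, 0.2, -0.3, 0.1, -0.2, -0.1, 0.15)
  fk <- forward_kinematics(w, q_true)
  mk <- fk$markers
  # corrupt one marker, then de-weight it to zero
  mk$pelvis_m1 <- mk$pelvis_m1 + c(0.5, 0.5, 0.5)
  fr_w0 <- observation_frame(0, markers = mk,
                             marker_weights = c(pelvis_m1 = 0))
  mk2 <- mk; mk2$pelvis_m1 <- NULL
  fr_drop <- observation_frame(0, markers = mk2)
  q_init <- c(0, 0.9, 0, numeric(6))
  s1 <- solve_frame(w, fr_w0, q_init)
  s2 <- solve_frame(w, fr_drop, q_init)
  expect_lt(max(abs(s1$q - s2$q)), 1e-10)
})

test_that("marker recovery error grows with marker noise", {
  p <- make_fixture("pendulum")
  q_true <- 0.5
  fk <- forward_kinematics(p, q_true)
  sigmas <- c(0, 0.001, 0.003, 0.005)
  set.seed(99)
  rmse <- vapply(sigmas, function(sg) {
    errs <- vapply(1:50, function(i) {
      mk <- lapply(fk$markers, function(m) m + rnorm(3, 0, sg))
      sol <- solve_frame(p, observation_frame(0, markers = mk),
                         q_init = 0.4)
      (sol$q - q_true)^2
    }, numeric(1))
    sqrt(mean(errs))
  }, numeric(1))
  expect_true(all(diff(rmse) > 0))
  expect_equal(rmse[1], 0, tolerance = 1e-8)
})

test_that("warm-started solves track a smooth trajectory tightly", {
  p <- make_fixture("double_pendulum")
  ts <- seq(0, 1, by = 0.01)
  q1 <- 0.5 * sin(2 * pi * ts); q2 <- -0.4 + 0.3 * cos(2 * pi * ts)
  q_prev <- c(q1[1], q2[1])
  for (i in 2:length(ts)) {
    fk <- forward_kinematics(p, c(q1[i], q2[i]))
    sol <- solve_frame(p, observation_frame(ts[i], markers = fk$markers),
                       q_init = q_prev)
    step <- sqrt(sum((sol$q - q_prev)^2))
    true_step <- sqrt((q1[i] - q1[i - 1])^2 + (q2[i] - q2[i - 1])^2)
    expect_lte(step, true_step + 1e-3)
    q_prev <- sol$q
  }
})

test_that("IMU calibration undoes a constant yaw offset", {
  w <- make_fixture("planar_walker")
  fk0 <- forward_kinematics(w, numeric(9))
  yaw <- rotation_about_axis(c(0, 1, 0), pi / 6)
  obs <- lapply(fk0$imus, function(q)
    matrix_to_quat(yaw %*% quat_to_matrix(q)))
  frames <- lapply(seq(0, 0.5, by = 0.01), function(t)
    observation_frame(t, orientations = obs))
  cal <- calibrate_imu_placement(w, frames, "pelvis_imu")
  calibrated <- apply_imu_calibration(frames[[1]], cal)
  errs <- vapply(names(calibrated$orientations), function(nm)
    quat_geodesic(calibrated$orientations[[nm]], fk0$imus[[nm]]),
    numeric(1))
  expect_lt(max(errs), 1e-9)
  # zero offset: identity calibration
  frames0 <- lapply(frames, function(f) {
    f$orientations <- fk0$imus; f
  })
  cal0 <- calibrate_imu_placement(w, frames0, "pelvis_imu")
  expect_lt(max(abs(cal0$offset - diag(3))), 1e-9)
})

test_that("heading uses the horizontal projection of the anterior axis", {
  w <- make_fixture("planar_walker")
  fk0 <- forward_kinematics(w, numeric(9))
  # yaw 40 deg composed with pitch 20 deg out of horizontal
  yaw_ang <- 40 * pi / 180
  R_off <- rotation_about_axis(c(0, 1, 0), yaw_ang) %*%
    rotation_about_axis(c(0, 0, 1), 20 * pi / 180)
  obs <- lapply(fk0$imus, function(q)
    matrix_to_quat(R_off %*% quat_to_matrix(q)))
  frames <- list(observation_frame(0, orientations = obs))
  cal <- calibrate_imu_placement(w, frames, "pelvis_imu")
  # oracle: yaw of the horizontal projection of the offset anterior axis
  v <- as.numeric(R_off %*% c(1, 0, 0))
  psi <- atan2(v[3], v[1])
  expect_equal(cal$heading_angle, psi, tolerance = 1e-12)
  # near-vertical anterior axis is rejected
  R_vert <- rotation_about_axis(c(0, 0, 1), pi / 2)
  obs_v <- lapply(fk0$imus, function(q)
    matrix_to_quat(R_vert %*% quat_to_matrix(q)))
  expect_error(
    calibrate_imu_placement(w, list(observation_frame(0,
                                                      orientations = obs_v)),
                            "pelvis_imu"),
    "vertical")
})

test_that("marker completion reconstructs occlusions by Procrustes", {
  b <- four_marker_body()
  q <- c(0.2, -0.1, 0.3, 0.4, -0.2, 0.5)
  fk <- forward_kinematics(b, q)
  full <- fk$markers
  occluded <- full
  occluded["d"] <- list(NULL)
  cm <- complete_markers(observation_frame(0, markers = occluded), b)
  expect_equal(cm$report$method, "procrustes")
  expect_lt(max(abs(cm$frame$markers$d - full$d)), 1e-9)
  # no missing markers: unchanged
  cm2 <- complete_markers(observation_frame(0, markers = full), b)
  expect_equal(nrow(cm2$report), 0)
  expect_equal(cm2$frame$markers, full)
  # whole segment occluded: held from history, flagged
  all_gone <- lapply(full, function(m) NULL)
  all_gone$a <- full$a  # frame needs >= 1 target somewhere
  cm3 <- complete_markers(observation_frame(1, markers = all_gone), b,
                          history = cm$history)
  expect_true(all(cm3$report$method == "held"))
  expect_equal(cm3$frame$markers$b, full$b, tolerance = 1e-12)
})

test_that("stream resampling is exact for linear and slerp cases", {
  # single source already uniform: output equals input
  mk <- function(t) observation_frame(t, markers = list(p = c(t, 2 * t, 0)))
  src <- lapply(seq(0, 1, by = 0.01), mk)
  out <- resample_streams(list(src), fs = 100)
  expect_equal(length(out), length(src))
  expect_equal(out[[51]]$markers$p, src[[51]]$markers$p,
               tolerance = 1e-12)
  # two offset sources with linear signals interpolate exactly
  src2 <- lapply(seq(0.005, 1.005, by = 0.01), function(t)
    observation_frame(t, markers = list(v = c(3 * t, -t, 0.5 * t))))
  out2 <- resample_streams(list(src, src2), fs = 100)
  tg <- out2[[40]]$t
  expect_equal(out2[[40]]$markers$v, c(3 * tg, -tg, 0.5 * tg),
               tolerance = 1e-12)
  # constant-rate rotation: slerp error small at 100 Hz
  rate <- 3 # rad/s
  src3 <- lapply(seq(0, 1, by = 0.01), function(t)
    observation_frame(t, orientations = list(
      s = quat_from_axis_angle(c(0, 0, 1), rate * t))))
  out3 <- resample_streams(list(src, src3), fs = 100)
  errs <- vapply(out3, function(f)
    quat_geodesic(f$orientations$s,
                  quat_from_axis_angle(c(0, 0, 1), rate * f$t)),
    numeric(1))
  expect_lt(max(errs), 1e-4)
  # non-monotone timestamps rejected
  bad <- list(mk(0), mk(0.2), mk(0.1))
  expect_error(resample_streams(list(bad), 100), "increasing")
})
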