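test_that("total wrench matches statics, free fall and summation", {
  w <- make_fixture("planar_walker")
  BW <- total_mass(w) * 9.80665
  st <- gen_state(0, c(0, 0.97, 0, numeric(6)), numeric(9), numeric(9))
  sp <- com_kinematics(w, st)
  tw <- total_wrench(w, sp)
  expect_equal(tw$force[2], BW, tolerance = 1e-10)
  expect_lt(max(abs(tw$force[c(1, 3)])), 1e-10)
  # free fall: a_com = g everywhere -> zero wrench
  st_ff <- gen_state(0, c(0, 0.97, 0, numeric(6)), numeric(9),
                     c(0, -9.80665, 0, numeric(6)))
  tw_ff <- total_wrench(w, com_kinematics(w, st_ff))
  expect_lt(max(abs(c(tw_ff$force, tw_ff$moment))), 1e-9)
  # mid-gait frame vs direct per-segment summation oracle
  params <- gait_params()
  traj <- generate_gait_trajectory(w, params, fs = 100, duration = 0.5)
  st_mid <- traj$states[[25]]
  spm <- com_kinematics(w, st_mid)
  twm <- total_wrench(w, spm)
  f_o <- Reduce(`+`, lapply(names(w$segments), function(sn)
    w$segments[[sn]]$mass * (spm$segments[[sn]]$a_com - c(0, -9.80665, 0))))
  m_o <- Reduce(`+`, lapply(names(w$segments), function(sn) {
    k <- spm$segments[[sn]]; s <- w$segments[[sn]]
    Iw <- k$R %*% s$inertia %*% t(k$R)
    as.numeric(Iw %*% k$alpha) +
      rtmsk:::cross3(k$omega, as.numeric(Iw %*% k$omega)) +
      rtmsk:::cross3(k$com, s$mass * (k$a_com - c(0, -9.80665, 0)))
  }))
  expect_lt(max(abs(twm$force - f_o)), 1e-10)
  expect_lt(max(abs(twm$moment - m_o)), 1e-10)
})

test_that("gait state machine debounces and time-stamps events", {
  # always above threshold: stance throughout, no events after initial
  det <- gait_detector("r", v_th = 0.5, k = 3, initial_phase = "stance")
  for (i in 0:20) {
    st <- detect_gait_phase(det, i * 0.01, c(r = 1))
    det <- st$detector
    expect_equal(nrow(st$events), 0)
  }
  expect_equal(unname(gait_phases(det)), "stance")
  # sustained step change: heel-strike stamped at the run's first frame
  det <- gait_detector("r", v_th = 0.5, k = 3)
  u_seq <- c(rep(0, 10), rep(1, 10))
  events <- NULL
  for (i in seq_along(u_seq)) {
    st <- detect_gait_phase(det, (i - 1) * 0.01, c(r = u_seq[i]))
    det <- st$detector
    events <- rbind(events, st$events)
  }
  expect_equal(nrow(events), 1)
  expect_equal(events$type, "heel_strike")
  expect_equal(events$time, 10 * 0.01)  # first sample of the run
  # a blip of k - 1 frames does not flip the phase
  det <- gait_detector("r", v_th = 0.5, k = 3, initial_phase = "swing")
  u_seq <- c(rep(0, 5), rep(1, 2), rep(0, 10))
  n_ev <- 0
  for (i in seq_along(u_seq)) {
    st <- detect_gait_phase(det, (i - 1) * 0.01, c(r = u_seq[i]))
    det <- st$detector
    n_ev <- n_ev + nrow(st$events)
  }
  expect_equal(n_ev, 0)
  expect_equal(unname(gait_phases(det)), "swing")
})

test_that("events on synthetic crossing profiles land within one frame", {
  # insole-like square profiles with known crossing times
  fs <- 100
  t <- seq(0, 4, by = 1 / fs)
  hs_true <- c(0.5, 1.7, 2.9); to_true <- c(1.2, 2.4, 3.6)
  u <- numeric(length(t))
  for (i in seq_along(hs_true))
    u[t >= hs_true[i] & t < to_true[i]] <- 1
  det <- gait_detector("r", v_th = 0.5, k = 3)
  ev <- NULL
  for (i in seq_along(t)) {
    st <- detect_gait_phase(det, t[i], c(r = u[i]))
    det <- st$detector
    ev <- rbind(ev, st$events)
  }
  hs_det <- ev$time[ev$type == "heel_strike"]
  to_det <- ev$time[ev$type == "toe_off"]
  expect_equal(length(hs_det), 3)
  expect_lt(max(abs(hs_det - hs_true)), 1 / fs + 1e-12)
  expect_lt(max(abs(to_det - to_true)), 1 / fs + 1e-12)
})

test_that("support durations estimated from two-leg timing", {
  fs <- 100
  params <- gait_params()
  sched <- rtmsk:::gait_schedule(params)
  ev <- sched$events_in(0, 4.8)
  det <- gait_detector(c("r", "l"), v_th = 0.5, k = 1)
  # replay the scheduled events as clean square insole signals
  t <- seq(0, 4.8, by = 1 / fs)
  stance_of <- function(leg, tt) {
    tau <- (tt - sched$offsets[[leg]]) %% params$T_cycle
    as.numeric(tau < params$T_cycle / 2 + sched$T_ds)
  }
  for (i in seq_along(t)) {
    u <- c(r = stance_of("r", t[i]), l = stance_of("l", t[i]))
    det <- detect_gait_phase(det, t[i], u)$detector
  }
  expect_lt(abs(det$T_ds - sched$T_ds), 2 / fs + 1e-12)
  expect_lt(abs(det$T_ss - sched$T_ss), 2 / fs + 1e-12)
})

test_that("walking direction is the circular mean of pelvis yaw", {
  q_id <- list(c(1, 0, 0, 0))
  expect_equal(walking_direction(q_id)$angle, 0, tolerance = 1e-14)
  # constant 30 deg yaw: wrench transform preserves the force norm
  q30 <- list(quat_from_axis_angle(c(0, 1, 0), pi / 6))
  wd <- walking_direction(q30)
  expect_equal(wd$angle, pi / 6, tolerance = 1e-12)
  f <- c(120, 700, -30)
  fw <- as.numeric(t(wd$rotation) %*% f)
  expect_equal(sqrt(sum(fw^2)), sqrt(sum(f^2)), tolerance = 1e-12)
  # symmetric oscillation about a mean yaw
  psi <- 0.4
  qs <- lapply(seq(-10, 10) * pi / 180, function(d)
    quat_from_axis_angle(c(0, 1, 0), psi + d))
  expect_equal(walking_direction(qs)$angle, psi, tolerance = 1e-9)
})

test_that("wrench distribution honors the support-phase rules", {
  ft <- transition_function()
  total <- list(force = c(10, 700, -5), moment = c(1, 2, 3))
  # single support: stance leg takes everything
  out <- distribute_wrench(total, NULL, c(r = "stance", l = "swing"),
                           leading = "r", t = 1)
  expect_identical(out$r, total)
  expect_identical(out$l$force, c(0, 0, 0))
  # double support at t = t_hs: trailing gets the frozen total
  frozen <- list(force = c(8, 650, -2), moment = c(0.5, 1, 2))
  out2 <- distribute_wrench(total, frozen,
                            c(r = "stance", l = "stance"), leading = "r",
                            t = 2, t_hs = 2, T_ds = 0.18, ft = ft)
  expect_equal(out2$l$force, frozen$force, tolerance = 1e-14)
  expect_equal(out2$r$force, total$force - frozen$force,
               tolerance = 1e-14)
  # at t = t_hs + T_ds the trailing leg is fully unloaded
  out3 <- distribute_wrench(total, frozen,
                            c(r = "stance", l = "stance"), leading = "r",
                            t = 2.18, t_hs = 2, T_ds = 0.18, ft = ft)
  expect_equal(out3$l$force, c(0, 0, 0), tolerance = 1e-14)
  expect_equal(out3$r$force, total$force, tolerance = 1e-14)
  # before any heel-strike: fall back to the first stance leg
  out4 <- distribute_wrench(total, NULL,
                            c(r = "stance", l = "stance"),
                            leading = NA_character_, t = 0)
  expect_identical(out4$r, total)
})

test_that("transition functions are monotone with unit boundaries", {
  for (shape in c("smoothstep", "linear")) {
    ft <- transition_function(shape)
    s <- vapply(seq(0, 0.18, length.out = 200), function(t)
      eval_transition(ft, t, 0.18)[1], numeric(1))
    expect_equal(s[1], 1)
    expect_equal(s[length(s)], 0)
    expect_true(all(diff(s) <= 1e-12))
  }
})

test_that("CoP scaling matches its closed form and is monotone", {
  T_ss <- 0.38
  expect_equal(cop_scaling(0, T_ss), 0, tolerance = 1e-14)
  expect_equal(cop_scaling(T_ss, T_ss), 1, tolerance = 1e-12)
  expect_equal(cop_scaling(T_ss / 2, T_ss), 0.5, tolerance = 1e-12)
  s <- cop_scaling(seq(0, T_ss, length.out = 1000), T_ss)
  expect_true(all(diff(s) >= -1e-12))
  # zero slope at both endpoints
  h <- 1e-6
  expect_lt(abs(cop_scaling(h, T_ss) - cop_scaling(0, T_ss)) / h, 1e-4)
  expect_lt(abs(cop_scaling(T_ss, T_ss) -
                cop_scaling(T_ss - h, T_ss)) / h, 1e-4)
  expect_error(cop_scaling(0.1, 0), "T_ss")
})

test_that("CoP trajectory interpolates heel to metatarsophalangeal", {
  w <- make_fixture("planar_walker")
  q <- c(0, 0.97, 0, numeric(6))
  fk <- forward_kinematics(w, q)
  heel <- rtmsk:::segment_point_world(fk, "foot_r",
                                      w$segments$foot_r$endpoints$heel)
  mtp <- rtmsk:::segment_point_world(fk, "foot_r",
                                     w$segments$foot_r$endpoints$mtp)
  p0 <- cop_trajectory(w, q, "foot_r", 0)
  p1 <- cop_trajectory(w, q, "foot_r", 1)
  ph <- cop_trajectory(w, q, "foot_r", 0.5)
  expect_equal(p0, c(heel[1], 0, heel[3]), tolerance = 1e-12)
  expect_equal(p1, c(mtp[1], 0, mtp[3]), tolerance = 1e-12)
  # flat 0.2 m foot aligned with x: halfway point is 0.1 m anterior
  expect_equal(ph[1] - p0[1], 0.1, tolerance = 1e-12)
})

test_that("predicted per-leg wrenches conserve the total at all times", {
  w <- make_fixture("planar_walker")
  params <- gait_params()
  traj <- generate_gait_trajectory(w, params, fs = 100, duration = 2.4)
  gt <- ground_truth_grfm(w, traj$states, params)
  pred <- predict_grfm(w, traj$states,
                       list(events = gt$events, T_ds = gt$T_ds,
                            T_ss = gt$T_ss))
  W <- pred$wrenches
  for (cc in c("x", "y", "z")) {
    i <- match(paste0(c("r", "l"), "_force_", cc), names(W))
    expect_lt(max(abs(W[, i[1]] + W[, i[2]] -
                      pred$totals[, match(cc, c("x", "y", "z"))])),
              1e-9)
  }
  # moments about the origin also sum to the total moment
  m_origin <- function(l) {
    f <- as.matrix(W[paste0(l, c("_force_x", "_force_y", "_force_z"))])
    p <- as.matrix(W[paste0(l, c("_point_x", "_point_y", "_point_z"))])
    m <- as.matrix(W[paste0(l, c("_moment_x", "_moment_y", "_moment_z"))])
    m + t(vapply(seq_len(nrow(f)), function(i)
      rtmsk:::cross3(p[i, ], f[i, ]), numeric(3)))
  }
  expect_lt(max(abs(m_origin("r") + m_origin("l") -
                    pred$totals[, 4:6])), 1e-9)
  # swing-leg wrench is identically zero during single support
  sched <- rtmsk:::gait_schedule(params)
  for (i in seq_along(traj$time)) {
    ph <- sched$phase_at(traj$time[i])
    if (sum(ph$stance) == 1) {
      swing <- names(ph$stance)[!ph$stance]
      expect_lt(max(abs(as.numeric(
        W[i, paste0(swing, c("_force_x", "_force_y", "_force_z"))]))),
        1e-9)
    }
  }
})
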