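test_that("muscle path forces behave like an ideal string", {
  w <- make_fixture("planar_walker")
  f_m <- setNames(numeric(12), names(w$muscles))
  expect_length(muscle_path_forces(w, numeric(9), f_m), 0)
  # single muscle under 100 N: equal and opposite end forces on the line
  f_m["hip_flex_r"] <- 100
  loads <- muscle_path_forces(w, numeric(9), f_m)
  expect_length(loads, 2)
  expect_equal(loads[[1]]$force, -loads[[2]]$force, tolerance = 1e-12)
  expect_equal(sqrt(sum(loads[[1]]$force^2)), 100, tolerance = 1e-12)
  dir <- (loads[[2]]$point - loads[[1]]$point)
  dir <- dir / sqrt(sum(dir^2))
  expect_equal(loads[[1]]$force, 100 * dir, tolerance = 1e-12)
  expect_error(muscle_path_forces(w, numeric(9), f_m - 1), ">= 0")
})

test_that("path forces generate R(q) f_m as generalized force", {
  w <- make_fixture("planar_walker")
  set.seed(14)
  q <- runif(9, -0.5, 0.5)
  st <- gen_state(0, q, numeric(9), numeric(9))
  f_m <- setNames(runif(12, 0, 500), names(w$muscles))
  loads <- muscle_path_forces(w, q, f_m)
  # generalized force of the point loads via the inverse-dynamics path
  tau_with <- rtmsk:::inverse_dynamics(w, st, point_loads = loads)$tau
  tau_wo <- inverse_dynamics(w, st)$tau
  tau_muscle <- -(tau_with - tau_wo)   # applied loads enter with -J^T
  R <- moment_arm_matrix(w, q)
  expect_lt(max(abs(tau_muscle - as.numeric(R %*% f_m))), 1e-6)
})

test_that("static joint reactions match equilibrium closed forms", {
  p <- make_fixture("pendulum")
  jr <- joint_reaction_analysis(p, gen_state(0, 0, 0, 0))
  # pin supports the hanging weight: (0, m g, 0)
  expect_equal(c(jr$fx, jr$fy, jr$fz), c(0, 1 * 9.80665, 0),
               tolerance = 1e-12)
  expect_lt(max(abs(c(jr$mx, jr$my, jr$mz))), 1e-12)
  # massless distal segment: zero reaction
  m0 <- msk_model(
    name = "massless",
    segments = list(
      a = list(mass = 1, inertia = diag(0.01, 3), com = c(0, -0.2, 0)),
      b = list(mass = 0, inertia = diag(0, 3), com = c(0, -0.1, 0))),
    joints = list(
      j1 = list(type = "revolute", parent = "ground", child = "a",
                axis = c(0, 0, 1)),
      j2 = list(type = "revolute", parent = "a", child = "b",
                offset_parent = c(0, -0.4, 0), axis = c(0, 0, 1))))
  jr0 <- joint_reaction_analysis(m0, gen_state(0, c(0.3, -0.2), c(0, 0),
                                               c(0, 0)))
  expect_lt(max(abs(as.matrix(jr0[jr0$joint == "j2",
                                  c("fx", "fy", "fz",
                                    "mx", "my", "mz")]))), 1e-12)
})

test_that("co-contraction raises compression without changing tau", {
  w <- make_fixture("planar_walker")
  st <- gen_state(0, numeric(9), numeric(9), numeric(9))
  f0 <- setNames(numeric(12), names(w$muscles))
  f1 <- f0
  f1[c("knee_ext_r", "knee_flex_r")] <- 200  # antagonist pair
  R <- moment_arm_matrix(w, numeric(9))
  tau_pair <- as.numeric(R %*% f1)
  arms <- R[coord_names(w) == "knee_r", c("knee_ext_r", "knee_flex_r")]
  # equal tensions at (near-)equal opposite arms: net knee moment ~ 0
  expect_lt(abs(sum(arms * 200)), abs(arms[1]) * 200 * 0.2)
  jr0 <- joint_reaction_analysis(w, st, f0)
  jr1 <- joint_reaction_analysis(w, st, f1)
  knee0 <- jr0[jr0$joint == "knee_r", ]
  knee1 <- jr1[jr1$joint == "knee_r", ]
  # the shank subtree is pulled upward along the muscle lines:
  # compressive (axial, +y here) reaction grows by ~ the summed axial
  # components of the two tensions
  loads <- muscle_path_forces(w, numeric(9), f1)
  on_shank <- Reduce(`+`, lapply(loads, function(pl)
    if (pl$segment %in% c("shank_r", "foot_r")) pl$force else c(0, 0, 0)))
  expect_equal(knee1$fy - knee0$fy, -on_shank[2], tolerance = 1e-9)
  # the tibia is pulled up into the femur: larger axial load magnitude
  expect_gt(abs(knee1$fy), abs(knee0$fy))
})

test_that("action equals reaction across an internal joint", {
  dp <- make_fixture("double_pendulum")
  set.seed(33)
  st <- gen_state(0, runif(2, -1, 1), runif(2, -2, 2), runif(2, -3, 3))
  jr <- joint_reaction_analysis(dp, st)
  sp <- com_kinematics(dp, st)
  g <- c(0, -9.80665, 0)
  # parent-side balance of rod1: F_pin1 - F_pin2_on_rod1 = m1 (a1 - g)
  # with F_pin2_on_rod1 = -reaction_on_child(pin2)
  F1 <- as.numeric(jr[jr$joint == "pin1", c("fx", "fy", "fz")])
  F2 <- as.numeric(jr[jr$joint == "pin2", c("fx", "fy", "fz")])
  m1a <- 1 * (sp$segments$rod1$a_com - g)
  expect_lt(max(abs(F1 - F2 - m1a)), 1e-9)
})

test_that("base reaction equals the residual wrench from RNE", {
  w <- make_fixture("planar_walker")
  params <- gait_params()
  traj <- generate_gait_trajectory(w, params, fs = 100, duration = 0.3)
  st <- traj$states[[12]]
  ew <- external_wrench("foot_r", c(0.1, 0, 0.09), c(20, 400, -5),
                        c(0, 2, 1))
  gf <- inverse_dynamics(w, st, list(ew))
  jr <- joint_reaction_analysis(w, st, NULL, list(ew))
  base <- jr[jr$joint == "base", ]
  # translational base residuals are the base reaction force components
  expect_equal(unname(gf$tau["base_tx"]), base$fx, tolerance = 1e-8)
  expect_equal(unname(gf$tau["base_ty"]), base$fy, tolerance = 1e-8)
  expect_equal(unname(gf$tau["base_rz"]), base$mz, tolerance = 1e-8)
})

test_that("raising one muscle force shifts the joint reaction along its
           line of action only", {
  w <- make_fixture("planar_walker")
  st <- gen_state(0, numeric(9), numeric(9), numeric(9))
  f0 <- setNames(numeric(12), names(w$muscles))
  f1 <- f0; f1["knee_ext_r"] <- 300
  jr0 <- joint_reaction_analysis(w, st, f0)
  jr1 <- joint_reaction_analysis(w, st, f1)
  dF <- as.numeric(jr1[jr1$joint == "knee_r", c("fx", "fy", "fz")] -
                   jr0[jr0$joint == "knee_r", c("fx", "fy", "fz")])
  # direction of the knee extensor line at this pose
  pts <- vapply(w$muscles$knee_ext_r$path, function(p)
    rtmsk:::segment_point_world(forward_kinematics(w, numeric(9)),
                                p$segment, p$point), numeric(3))
  u <- (pts[, 2] - pts[, 1]) / sqrt(sum((pts[, 2] - pts[, 1])^2))
  # the change is parallel to the muscle line
  expect_lt(sqrt(sum((dF - sum(dF * u) * u)^2)), 1e-9)
  # joints the muscle does not span are untouched
  expect_lt(max(abs(as.matrix(
    jr1[jr1$joint == "ankle_l", c("fx", "fy", "fz", "mx", "my", "mz")] -
    jr0[jr0$joint == "ankle_l", c("fx", "fy", "fz", "mx", "my", "mz")]))),
    1e-10)
})
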