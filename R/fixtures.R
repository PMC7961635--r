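# Bundled rigid-body fixtures. These toy models stand in for full
# musculoskeletal models (e.g. lower-limb gait models) so that every
# pipeline stage can be exercised and verified against closed-form
# mechanics without any external data.

#' Construct a bundled fixture model
#'
#' Available fixtures:
#' \describe{
#'   \item{`pendulum`}{single thin rod on a ground pin (1 DoF); its
#'     statics and circular-motion kinematics have textbook closed forms.}
#'   \item{`double_pendulum`}{two thin rods (2 DoF); its equations of
#'     motion have a closed Lagrangian form used as an independent
#'     dynamics oracle.}
#'   \item{`spatial_pendulum`}{a 6-DoF floating carrier plus a pin rod
#'     (7 DoF); exercises the free spatial base and the residual-force
#'     bookkeeping.}
#'   \item{`planar_walker`}{7 segments, 9 DoF (3-DoF planar pelvis base,
#'     bilateral hip/knee/ankle pins), anthropometric mass fractions,
#'     markers and an IMU on every segment, heel and metatarsophalangeal
#'     endpoints on each foot, and 12 straight-line muscles (an
#'     antagonist pair per joint).}
#' }
#'
#' @param name fixture name.
#' @param subject_mass total walker mass (kg); walker only.
#' @param mass,length pendulum rod parameters (also used for the rods of
#'   the other pendulum fixtures).
#' @return An `msk_model`.
#' @export
make_fixture <- function(name = c("pendulum", "double_pendulum",
                                  "spatial_pendulum", "planar_walker"),
                         subject_mass = 75, mass = 1, length = 1) {
  name <- match.arg(name)
  switch(name,
    pendulum = fixture_pendulum(mass, length),
    double_pendulum = fixture_double_pendulum(mass, length),
    spatial_pendulum = fixture_spatial_pendulum(mass, length),
    planar_walker = fixture_walker(subject_mass))
}

rod_inertia <- function(m, L) {
  I <- m * L^2 / 12
  diag(c(I, 1e-4 * I + 1e-6, I))
}

fixture_pendulum <- function(m = 1, L = 1) {
  msk_model(
    name = "pendulum",
    segments = list(
      rod = list(mass = m, inertia = rod_inertia(m, L),
                 com = c(0, -L / 2, 0),
                 endpoints = list(tip = c(0, -L, 0)))),
    joints = list(
      pin = list(type = "revolute", parent = "ground", child = "rod",
                 offset_parent = c(0, 0, 0), offset_child = c(0, 0, 0),
                 axis = c(0, 0, 1), range = list(c(-pi, pi)))),
    markers = list(
      tip = list(segment = "rod", position = c(0, -L, 0)),
      mid = list(segment = "rod", position = c(0, -L / 2, 0)),
      side = list(segment = "rod", position = c(0.1, -L / 2, 0))),
    imus = list(
      rod_imu = list(segment = "rod", orientation = c(1, 0, 0, 0))))
}

fixture_double_pendulum <- function(m = 1, L = 1) {
  m2 <- 0.8 * m; L2 <- 0.8 * L
  msk_model(
    name = "double_pendulum",
    segments = list(
      rod1 = list(mass = m, inertia = rod_inertia(m, L),
                  com = c(0, -L / 2, 0),
                  endpoints = list(distal = c(0, -L, 0))),
      rod2 = list(mass = m2, inertia = rod_inertia(m2, L2),
                  com = c(0, -L2 / 2, 0),
                  endpoints = list(tip = c(0, -L2, 0)))),
    joints = list(
      pin1 = list(type = "revolute", parent = "ground", child = "rod1",
                  axis = c(0, 0, 1), range = list(c(-pi, pi))),
      pin2 = list(type = "revolute", parent = "rod1", child = "rod2",
                  offset_parent = c(0, -L, 0), axis = c(0, 0, 1),
                  range = list(c(-pi, pi)))),
    markers = list(
      elbow = list(segment = "rod1", position = c(0, -L, 0)),
      tip = list(segment = "rod2", position = c(0, -L2, 0))))
}

fixture_spatial_pendulum <- function(m = 1, L = 1) {
  msk_model(
    name = "spatial_pendulum",
    segments = list(
      carrier = list(mass = m, inertia = diag(0.01, 3), com = c(0, 0, 0),
                     endpoints = list()),
      rod = list(mass = m, inertia = rod_inertia(m, L),
                 com = c(0, -L / 2, 0),
                 endpoints = list(tip = c(0, -L, 0)))),
    joints = list(
      base = list(type = "free_spatial", parent = "ground",
                  child = "carrier"),
      pin = list(type = "revolute", parent = "carrier", child = "rod",
                 axis = c(0, 0, 1), range = list(c(-pi, pi)))))
}

# Winter-style anthropometric mass fractions with the head-arms-trunk
# mass lumped into the pelvis segment of a 7-segment planar walker.
fixture_walker <- function(subject_mass = 75) {
  m_hat <- 0.678 * subject_mass
  m_thigh <- 0.100 * subject_mass
  m_shank <- 0.0465 * subject_mass
  m_foot <- 0.0145 * subject_mass
  L_thigh <- 0.45; L_shank <- 0.43
  hip_w <- 0.09   # lateral hip offset from pelvis mid-line

  thigh_I <- function() {
    I <- m_thigh * (0.323 * L_thigh)^2
    diag(c(I, 0.05 * I, I))
  }
  shank_I <- function() {
    I <- m_shank * (0.302 * L_shank)^2
    diag(c(I, 0.05 * I, I))
  }
  foot_I <- diag(c(0.002, 0.005, 0.005)) * (m_foot / 1.0875)
  hat_I <- diag(c(1.5, 0.8, 1.3)) * (m_hat / 50)

  leg_segments <- function(side, sgn) {
    stats::setNames(list(
      list(mass = m_thigh, inertia = thigh_I(),
           com = c(0, -0.433 * L_thigh, 0),
           endpoints = list(knee = c(0, -L_thigh, 0))),
      list(mass = m_shank, inertia = shank_I(),
           com = c(0, -0.433 * L_shank, 0),
           endpoints = list(ankle = c(0, -L_shank, 0))),
      list(mass = m_foot, inertia = foot_I,
           com = c(0.05, -0.05, 0),
           endpoints = list(heel = c(-0.05, -0.07, 0),
                            mtp = c(0.15, -0.07, 0)))),
      paste0(c("thigh_", "shank_", "foot_"), side))
  }

  leg_joints <- function(side, sgn) {
    rng <- list(c(-1.2, 1.2))
    stats::setNames(list(
      list(type = "revolute", parent = "pelvis",
           child = paste0("thigh_", side),
           offset_parent = c(0, 0, sgn * hip_w),
           axis = c(0, 0, 1), range = rng),
      list(type = "revolute", parent = paste0("thigh_", side),
           child = paste0("shank_", side),
           offset_parent = c(0, -L_thigh, 0),
           axis = c(0, 0, 1), range = rng),
      list(type = "revolute", parent = paste0("shank_", side),
           child = paste0("foot_", side),
           offset_parent = c(0, -L_shank, 0),
           axis = c(0, 0, 1), range = rng)),
      paste0(c("hip_", "knee_", "ankle_"), side))
  }

  seg_markers <- function(seg, base_pts) {
    nms <- paste0(seg, "_m", seq_along(base_pts))
    stats::setNames(lapply(base_pts, function(p)
      list(segment = seg, position = p)), nms)
  }
  leg_markers <- function(side) {
    c(seg_markers(paste0("thigh_", side),
                  list(c(0.06, -0.1, 0), c(-0.05, -0.2, 0.03),
                       c(0.04, -0.35, -0.03))),
      seg_markers(paste0("shank_", side),
                  list(c(0.05, -0.1, 0), c(-0.04, -0.25, 0.02),
                       c(0.03, -0.38, -0.02))),
      seg_markers(paste0("foot_", side),
                  list(c(-0.05, -0.07, 0), c(0.15, -0.07, 0),
                       c(0.05, 0.02, 0.03))))
  }

  # straight-line antagonist pair per pin joint; anterior (+x) and
  # posterior (-x) lines give opposite-sign moment arms
  leg_muscles <- function(side, sgn) {
    th <- paste0("thigh_", side); sh <- paste0("shank_", side)
    ft <- paste0("foot_", side)
    stats::setNames(list(
      list(fmax = 2000, path = list(
        list(segment = "pelvis", point = c(0.06, 0.06, sgn * hip_w)),
        list(segment = th, point = c(0.05, -0.16, 0)))),
      list(fmax = 2000, path = list(
        list(segment = "pelvis", point = c(-0.06, 0.06, sgn * hip_w)),
        list(segment = th, point = c(-0.05, -0.16, 0)))),
      list(fmax = 3000, path = list(
        list(segment = th, point = c(0.05, -0.3, 0)),
        list(segment = sh, point = c(0.05, -0.12, 0)))),
      list(fmax = 3000, path = list(
        list(segment = th, point = c(-0.05, -0.3, 0)),
        list(segment = sh, point = c(-0.04, -0.12, 0)))),
      list(fmax = 1500, path = list(
        list(segment = sh, point = c(0.04, -0.3, 0)),
        list(segment = ft, point = c(0.09, -0.05, 0)))),
      list(fmax = 3000, path = list(
        list(segment = sh, point = c(-0.04, -0.3, 0)),
        list(segment = ft, point = c(-0.05, -0.06, 0))))),
      paste0(c("hip_flex_", "hip_ext_", "knee_ext_", "knee_flex_",
               "ankle_dflex_", "ankle_pflex_"), side))
  }

  msk_model(
    name = "planar_walker",
    segments = c(
      list(pelvis = list(mass = m_hat, inertia = hat_I,
                         com = c(0, 0.25, 0),
                         endpoints = list(hip_r = c(0, 0, hip_w),
                                          hip_l = c(0, 0, -hip_w)))),
      leg_segments("r", +1), leg_segments("l", -1)),
    joints = c(
      list(base = list(type = "free_planar", parent = "ground",
                       child = "pelvis",
                       range = list(c(-10, 10), c(0.5, 1.5), c(-pi, pi)))),
      leg_joints("r", +1), leg_joints("l", -1)),
    markers = c(
      seg_markers("pelvis", list(c(0.08, 0.05, 0.1), c(0.08, 0.05, -0.1),
                                 c(-0.1, 0.08, 0))),
      leg_markers("r"), leg_markers("l")),
    imus = stats::setNames(lapply(
      c("pelvis", "thigh_r", "shank_r", "foot_r",
        "thigh_l", "shank_l", "foot_l"),
      function(s) list(segment = s, orientation = c(1, 0, 0, 0))),
      paste0(c("pelvis", "thigh_r", "shank_r", "foot_r",
               "thigh_l", "shank_l", "foot_l"), "_imu")),
    muscles = c(leg_muscles("r", +1), leg_muscles("l", -1)))
}

#' Write a model description file
#'
#' Serializes an `msk_model` to the YAML schema read by [load_model()].
#'
#' @param model an `msk_model`.
#' @param path output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  inertia6 <- function(I)
    c(I[1, 1], I[2, 2], I[3, 3], I[1, 2], I[1, 3], I[2, 3])
  out <- list(
    name = model$name,
    segments = lapply(names(model$segments), function(nm) {
      s <- model$segments[[nm]]
      list(name = nm, mass = s$mass, inertia = inertia6(s$inertia),
           com = s$com,
           endpoints = lapply(names(s$endpoints), function(en)
             list(name = en, point = s$endpoints[[en]])))
    }),
    joints = lapply(names(model$joints), function(nm) {
      j <- model$joints[[nm]]
      out <- list(name = nm, type = j$type, parent = j$parent,
                  child = j$child, offset_parent = j$offset_parent,
                  offset_child = j$offset_child)
      if (!is.null(j$axis)) out$axis <- j$axis
      if (!is.null(j$range)) out$range <- j$range
      out
    }),
    markers = lapply(names(model$markers), function(nm)
      c(list(name = nm), model$markers[[nm]])),
    imus = lapply(names(model$imus), function(nm)
      c(list(name = nm), model$imus[[nm]])),
    muscles = lapply(names(model$muscles), function(nm) {
      mu <- model$muscles[[nm]]
      list(name = nm, fmax = mu$fmax, path = mu$path)
    }))
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}
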