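# Synthetic gait generator: band-limited periodic joint trajectories
# with analytic derivatives, noisy marker/IMU observation streams, and
# dynamically consistent ground-truth per-leg ground reaction wrenches
# built from a closed-form gait schedule and the same smooth-transition
# rules the predictor implements. Everything is seeded and reproducible.

#' Gait generation parameters
#'
#' Defaults describe a slow, straight walk of the bundled planar walker:
#' a 1.2 s gait cycle, 15% double-support fraction per transfer, 1.2 m/s
#' forward progression, and joint-angle waveforms that are band-limited
#' sums of one or two harmonics of the cycle. The waveforms are motion
#' surrogates chosen for testability (smooth, periodic, analytic
#' derivatives), not validated gait curves.
#'
#' @param T_cycle gait cycle duration (s).
#' @param ds_fraction double-support duration as a fraction of the
#'   cycle, in (0, 0.5); each cycle contains two double supports.
#' @param speed forward progression speed (m/s).
#' @param table named list per coordinate: `offset`, `amp` (one entry
#'   per harmonic) and `phase` (rad, same length); missing coordinates
#'   stay at zero.
#' @param marker_sigma marker noise standard deviation (m).
#' @param orient_sigma orientation noise standard deviation (rad).
#' @param occlusion marker occlusion probability in `[0, 1)`.
#' @param drift linear IMU yaw drift rate (rad/s).
#' @param seed integer seed for all stochastic synthesis.
#' @return object of class `gait_params`.
#' @export
gait_params <- function(T_cycle = 1.2, ds_fraction = 0.15, speed = 1.2,
                        table = NULL, marker_sigma = 0, orient_sigma = 0,
                        occlusion = 0, drift = 0, seed = 1L) {
  if (!(ds_fraction > 0 && ds_fraction < 0.5))
    stop("ds_fraction must be in (0, 0.5)")
  if (marker_sigma < 0 || orient_sigma < 0)
    stop("noise sigmas must be >= 0")
  if (occlusion < 0 || occlusion >= 1) stop("occlusion must be in [0, 1)")
  structure(list(T_cycle = T_cycle, ds_fraction = ds_fraction,
                 speed = speed, table = table %||% default_gait_table(),
                 marker_sigma = marker_sigma, orient_sigma = orient_sigma,
                 occlusion = occlusion, drift = drift,
                 seed = as.integer(seed)),
            class = "gait_params")
}

# hip flexion positive forward, knee flexion negative, ankle small;
# left leg in antiphase; gentle double-bounce of the pelvis
default_gait_table <- function() {
  list(
    base_ty = list(offset = 0.97, amp = c(0, 0.015), phase = c(0, 0)),
    hip_r = list(offset = 0.05, amp = 0.35, phase = pi / 2),
    hip_l = list(offset = 0.05, amp = 0.35, phase = -pi / 2),
    knee_r = list(offset = -0.25, amp = c(0.12, 0.10),
                  phase = c(pi, pi / 3)),
    knee_l = list(offset = -0.25, amp = c(0.12, 0.10),
                  phase = c(0, pi / 3 + pi)),
    ankle_r = list(offset = 0, amp = 0.1, phase = 0),
    ankle_l = list(offset = 0, amp = 0.1, phase = pi))
}

#' Generate an analytic gait kinematics stream
#'
#' Each coordinate follows
#' `q(t) = offset + sum_k amp_k sin(2 pi k t / T + phase_k)`, with the
#' base forward translation additionally progressing at the configured
#' speed; `u = dq/dt` and `a = d2q/dt2` are returned analytically, so the
#' stream is exact ground truth for filter and dynamics tests.
#'
#' @param model an `msk_model` (coordinate names select table entries).
#' @param params a [gait_params()].
#' @param fs sampling frequency (Hz), `>= 50`.
#' @param duration trial length (s).
#' @return list with `time`, `states` (list of [gen_state()]) and
#'   matrices `q`, `u`, `a` (samples x coordinates).
#' @export
generate_gait_trajectory <- function(model, params, fs = 100,
                                     duration = 2 * params$T_cycle) {
  if (fs < 50) stop("fs must be >= 50 Hz")
  time <- seq(0, duration, by = 1 / fs)
  cn <- coord_names(model)
  N <- length(cn)
  Tc <- params$T_cycle
  q <- matrix(0, length(time), N, dimnames = list(NULL, cn))
  u <- q; a <- q
  for (ci in seq_len(N)) {
    entry <- params$table[[cn[ci]]]
    if (!is.null(entry)) {
      q[, ci] <- entry$offset %||% 0
      for (k in seq_along(entry$amp)) {
        wk <- 2 * pi * k / Tc
        ph <- wk * time + entry$phase[k]
        q[, ci] <- q[, ci] + entry$amp[k] * sin(ph)
        u[, ci] <- u[, ci] + entry$amp[k] * wk * cos(ph)
        a[, ci] <- a[, ci] - entry$amp[k] * wk^2 * sin(ph)
      }
    }
    if (grepl("_tx$", cn[ci])) {
      q[, ci] <- q[, ci] + params$speed * time
      u[, ci] <- u[, ci] + params$speed
    }
  }
  states <- lapply(seq_along(time), function(i)
    gen_state(time[i], q[i, ], u[i, ], a[i, ]))
  list(time = time, states = states, q = q, u = u, a = a)
}

#' Synthesize a noisy marker observation stream
#'
#' Markers are forward-kinematics positions plus iid Gaussian noise per
#' axis; occlusions are iid Bernoulli draws replacing a marker by a
#' missing value.
#'
#' @param model an `msk_model`.
#' @param states list of [gen_state()].
#' @param sigma noise standard deviation (m).
#' @param occlusion occlusion probability per marker per frame.
#' @param seed integer seed.
#' @return list of [observation_frame()]s.
#' @export
synthesize_markers <- function(model, states, sigma = 0, occlusion = 0,
                               seed = 1L) {
  set.seed(seed)
  lapply(states, function(st) {
    fk <- forward_kinematics(model, st$q)
    mk <- lapply(fk$markers, function(p) {
      if (occlusion > 0 && stats::runif(1) < occlusion) return(NULL)
      p + stats::rnorm(3, 0, sigma)
    })
    # built directly: under occlusion a frame may lose every marker,
    # which downstream completion handles by holding last positions
    structure(list(t = st$t, markers = mk, orientations = list(),
                   marker_weights = NULL, orientation_weights = NULL),
              class = "observation_frame")
  })
}

#' Synthesize a noisy IMU orientation stream
#'
#' Sensor orientations are forward-kinematics orientations composed with
#' small-angle Gaussian noise and a linear-in-time yaw drift — the error
#' accumulation mode typical of magnetometer-aided IMUs.
#'
#' @param model an `msk_model`.
#' @param states list of [gen_state()].
#' @param sigma rotational noise standard deviation (rad).
#' @param drift yaw drift rate (rad/s), applied in the world frame.
#' @param seed integer seed.
#' @return list of [observation_frame()]s.
#' @export
synthesize_imu <- function(model, states, sigma = 0, drift = 0,
                           seed = 1L) {
  set.seed(seed)
  t0 <- states[[1]]$t
  lapply(states, function(st) {
    fk <- forward_kinematics(model, st$q)
    ors <- lapply(fk$imus, function(qq) {
      qd <- quat_from_axis_angle(c(0, 1, 0), drift * (st$t - t0))
      qn <- if (sigma > 0) {
        v <- stats::rnorm(3, 0, sigma)
        ang <- sqrt(sum(v^2))
        if (ang > 0) quat_from_axis_angle(v, ang) else c(1, 0, 0, 0)
      } else c(1, 0, 0, 0)
      quat_multiply(qd, quat_multiply(qq, qn))
    })
    observation_frame(st$t, orientations = ors)
  })
}

# closed-form gait schedule: leg r strikes at t = 0 mod T, leg l at
# T/2 mod T; each stance lasts T/2 + T_ds; double support occupies the
# first T_ds of the leading leg's stance
gait_schedule <- function(params, legs = c("r", "l")) {
  Tc <- params$T_cycle
  T_ds <- params$ds_fraction * Tc
  T_ss <- Tc / 2 - T_ds
  offsets <- stats::setNames(c(0, Tc / 2), legs)
  phase_at <- function(t) {
    tau <- stats::setNames(((t - offsets) %% Tc), legs)
    stance <- tau < Tc / 2 + T_ds
    leading <- legs[which.min(tau)]
    list(tau = tau, stance = stance, leading = leading,
         in_ds = tau[leading] < T_ds,
         t_hs_leading = t - tau[leading],
         ss_elapsed = tau[leading] - T_ds)
  }
  events_in <- function(t0, t1) {
    ev <- list()
    keep <- function(tt) tt[tt >= t0 - 1e-12 & tt <= t1 + 1e-12]
    for (l in legs) {
      hs <- seq(offsets[[l]] - 2 * Tc, t1 + Tc, by = Tc)
      to <- hs + Tc / 2 + T_ds
      for (tt in keep(hs))
        ev[[length(ev) + 1]] <- data.frame(time = tt, leg = l,
                                           type = "heel_strike")
      for (tt in keep(to))
        ev[[length(ev) + 1]] <- data.frame(time = tt, leg = l,
                                           type = "toe_off")
    }
    ev <- do.call(rbind, ev)
    ev[order(ev$time), ]
  }
  list(T_ds = T_ds, T_ss = T_ss, offsets = offsets,
       phase_at = phase_at, events_in = events_in)
}

#' Ground-truth per-leg ground reaction wrenches
#'
#' Builds dynamically consistent per-leg GRF&M for a synthetic gait
#' stream: the total wrench follows from the Newton-Euler equations of
#' motion, gait events follow from the constructed cycle timing, the
#' per-leg split applies the same smooth-transition rules as the
#' predictor (trailing wrench frozen at the leading heel-strike and
#' faded by the transition function), and the CoP progresses from heel
#' to metatarsophalangeal per the scaling model. Feeding these wrenches
#' to inverse dynamics yields near-zero base residuals by construction.
#'
#' @param model an `msk_model` with `foot_r`/`foot_l` segments.
#' @param states list of [gen_state()] on a uniform grid aligned with
#'   the schedule (event times fall on samples).
#' @param params the [gait_params()] that generated the states.
#' @param transition a [transition_function()].
#' @return list with `wrenches` (same column layout as
#'   [predict_grfm()]), `events`, `T_ds`, `T_ss` and per-frame `totals`.
#' @export
ground_truth_grfm <- function(model, states, params,
                              transition = transition_function()) {
  legs <- c("r", "l")
  feet <- stats::setNames(paste0("foot_", legs), legs)
  sched <- gait_schedule(params, legs)
  n <- length(states)
  time <- vapply(states, function(s) s$t, numeric(1))
  tw_all <- vector("list", n)
  fks <- vector("list", n)
  for (i in seq_len(n)) {
    spatial <- com_kinematics(model, states[[i]])
    tw_all[[i]] <- total_wrench(model, spatial)
    fks[[i]] <- forward_kinematics(model, states[[i]]$q)
  }
  # frozen total at a heel-strike time = total at that grid sample
  total_at <- function(t_hs) {
    i <- which.min(abs(time - t_hs))
    if (abs(time[i] - t_hs) > 1e-6)
      stop("heel-strike time not aligned with the sample grid")
    tw_all[[i]]
  }
  cols <- c("time", unlist(lapply(legs, function(l)
    paste0(l, c("_force_x", "_force_y", "_force_z",
                "_point_x", "_point_y", "_point_z",
                "_moment_x", "_moment_y", "_moment_z")))))
  W <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  yaw_window <- list()
  for (i in seq_len(n)) {
    t <- time[i]
    ph <- sched$phase_at(t)
    tw <- tw_all[[i]]
    yaw_window[[length(yaw_window) + 1]] <- fks[[i]]$segments$pelvis$quat
    if (length(yaw_window) > 200) yaw_window <- yaw_window[-1]
    Rw <- walking_direction(yaw_window)$rotation
    tw_w <- to_walking(tw, Rw)
    phase <- stats::setNames(ifelse(ph$stance, "stance", "swing"), legs)
    split <- distribute_wrench(
      tw_w, total_at_hs = to_walking(total_at(ph$t_hs_leading), Rw),
      phase = phase, leading = ph$leading, t = t,
      t_hs = ph$t_hs_leading, T_ds = sched$T_ds, ft = transition)
    row <- t
    for (l in legs) {
      wr <- from_walking(split[[l]], Rw)
      if (phase[[l]] == "stance") {
        if (sum(ph$stance) == 2) {
          sg <- if (identical(ph$leading, l)) 0 else 1
        } else {
          sg <- cop_scaling(min(max(ph$ss_elapsed, 0), sched$T_ss),
                            sched$T_ss)
        }
        p_cop <- cop_trajectory(model, fks[[i]], feet[[l]], sg)
      } else p_cop <- c(0, 0, 0)
      m_cop <- wr$moment - cross3(p_cop, wr$force)
      row <- c(row, wr$force, p_cop, m_cop)
    }
    W[i, ] <- row
  }
  totals <- t(vapply(tw_all, function(w) c(w$force, w$moment), numeric(6)))
  list(wrenches = as.data.frame(W),
       events = sched$events_in(time[1], time[n]),
       T_ds = sched$T_ds, T_ss = sched$T_ss, totals = totals)
}
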