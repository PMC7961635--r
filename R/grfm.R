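# Ground reaction force & moment prediction from kinematics alone:
# total external wrench from the Newton-Euler equations, gait-phase
# state machine with debounced threshold detection, smooth-transition
# distribution between the legs during double support, and a
# heel-to-metatarsophalangeal center-of-pressure progression model.

#' Total external wrench from whole-body kinematics
#'
#' Under the assumption that the ground reactions are the only external
#' loads, the total reaction force is `sum_i m_i (a_i - g)` and the total
#' reaction moment about the ground origin is
#' `sum_i [I_i w_i' + w_i x (I_i w_i)] + sum_i c_i x m_i (a_i - g)`,
#' with `a_i`, `w_i`, `w_i'` the COM acceleration and angular
#' velocity/acceleration of segment `i` and `c_i` its COM position.
#'
#' @param model an `msk_model`.
#' @param spatial a [com_kinematics()] result.
#' @return list with `force` (N) and `moment` (N m, about the ground
#'   origin), ground frame.
#' @export
total_wrench <- function(model, spatial) {
  f <- c(0, 0, 0); m <- c(0, 0, 0)
  for (sn in names(model$segments)) {
    s <- model$segments[[sn]]
    if (is.null(s$inertia)) stop("segment '", sn, "' lacks inertia")
    k <- spatial$segments[[sn]]
    Iw <- k$R %*% s$inertia %*% t(k$R)
    fi <- s$mass * (k$a_com - GRAVITY)
    f <- f + fi
    m <- m + as.numeric(Iw %*% k$alpha) +
      cross3(k$omega, as.numeric(Iw %*% k$omega)) + cross3(k$com, fi)
  }
  list(force = f, moment = m)
}

#' Gait-phase detector state machine
#'
#' Raw per-sample detections (`u >= v_th` means stance) are debounced:
#' the committed phase flips only after `k` consecutive raw detections
#' of the opposite phase, and the emitted event is time-stamped at the
#' first sample of the committing run. The leading leg is reassigned at
#' each heel-strike. Running double- and single-support durations are
#' estimated from the event log.
#'
#' @param legs character vector of leg labels.
#' @param v_th detection threshold (same units as the measure `u`).
#' @param k debounce count (raw samples), `k >= 1`.
#' @param initial_phase committed phase at start, per leg.
#' @return object of class `gait_detector`.
#' @export
gait_detector <- function(legs = c("r", "l"), v_th = -0.02, k = 3,
                          initial_phase = "swing") {
  if (k < 1) stop("k must be >= 1")
  per_leg <- stats::setNames(lapply(legs, function(l)
    list(phase = initial_phase, pending = NA_character_, count = 0L,
         pending_t0 = NA_real_)), legs)
  structure(list(legs = legs, v_th = v_th, k = as.integer(k),
                 state = per_leg, leading = NA_character_,
                 events = data.frame(time = numeric(0),
                                     leg = character(0),
                                     type = character(0)),
                 T_ds = NA_real_, T_ss = NA_real_),
            class = "gait_detector")
}

#' Advance the gait-phase state machine by one sample
#'
#' @param det a [gait_detector()].
#' @param t sample time (s).
#' @param u named numeric vector: detection measure per leg (by default
#'   the negated heel clearance, so larger means closer to the ground).
#' @return list with the updated `detector` and `events` emitted at this
#'   sample (data.frame, possibly empty).
#' @export
detect_gait_phase <- function(det, t, u) {
  emitted <- det$events[0, ]
  for (leg in det$legs) {
    st <- det$state[[leg]]
    raw <- if (u[[leg]] >= det$v_th) "stance" else "swing"
    if (raw == st$phase) {
      st$pending <- NA_character_; st$count <- 0L
      st$pending_t0 <- NA_real_
    } else {
      if (is.na(st$pending) || st$pending != raw) {
        st$pending <- raw; st$count <- 1L; st$pending_t0 <- t
      } else {
        st$count <- st$count + 1L
      }
      if (st$count >= det$k) {
        ev_type <- if (raw == "stance") "heel_strike" else "toe_off"
        ev <- data.frame(time = st$pending_t0, leg = leg, type = ev_type)
        det$events <- rbind(det$events, ev)
        emitted <- rbind(emitted, ev)
        st$phase <- raw
        st$pending <- NA_character_; st$count <- 0L
        st$pending_t0 <- NA_real_
        if (ev_type == "heel_strike") det$leading <- leg
      }
    }
    det$state[[leg]] <- st
  }
  if (nrow(emitted) > 0) det <- update_periods(det)
  list(detector = det, events = emitted)
}

# T_ds: heel-strike -> next toe-off (the trailing/other leg unloads);
# T_ss: toe-off -> next heel-strike (the swinging leg lands again).
# Running estimates use the latest completed interval.
update_periods <- function(det) {
  ev <- det$events[order(det$events$time), ]
  n <- nrow(ev)
  for (i in seq_len(n - 1)) {
    a <- ev[i, ]; b <- ev[i + 1, ]
    dt <- b$time - a$time
    if (dt <= 0) next
    if (a$type == "heel_strike" && b$type == "toe_off") det$T_ds <- dt
    if (a$type == "toe_off" && b$type == "heel_strike") det$T_ss <- dt
  }
  det
}

#' Current committed phases of a detector
#' @param det a [gait_detector()].
#' @return named character vector, `"stance"` or `"swing"` per leg.
#' @export
gait_phases <- function(det) {
  vapply(det$state, function(s) s$phase, character(1))
}

#' Walking direction from pelvis orientations
#'
#' Circular mean of the yaw of the horizontal projection of the pelvis
#' anterior axis (+x of the pelvis frame). Returns the rotation about
#' the vertical mapping the ground +x onto the mean walking direction.
#'
#' @param orientations list of pelvis orientation quaternions (or a
#'   single quaternion).
#' @return list with `angle` (rad, yaw about +y) and `rotation` (3x3).
#' @export
walking_direction <- function(orientations) {
  if (!is.list(orientations)) orientations <- list(orientations)
  if (length(orientations) == 0) stop("need at least one orientation")
  yaws <- vapply(orientations, function(q) {
    v <- as.numeric(quat_to_matrix(q) %*% c(1, 0, 0))
    vh <- c(v[1], 0, v[3])
    if (sqrt(sum(vh^2)) < 1e-6)
      stop("pelvis anterior axis near vertical; walking direction undefined")
    atan2(-v[3], v[1])   # yaw about +y (right-handed, y-up)
  }, numeric(1))
  ang <- atan2(mean(sin(yaws)), mean(cos(yaws)))
  list(angle = ang, rotation = rotation_about_axis(c(0, 1, 0), ang))
}

#' Smooth transition function for double-support load transfer
#'
#' Monotone non-increasing maps from elapsed double-support time to the
#' trailing leg's share, per force and moment component:
#' `f_t(0) = 1`, `f_t(T_ds) = 0`. The default is the cubic smoothstep
#' `1 - (3 s^2 - 2 s^3)`; per-component tables may be supplied to mimic
#' published per-component transition shapes.
#'
#' @param shape `"smoothstep"`, `"linear"` or `"table"`.
#' @param table for `"table"`: a function of the normalized phase
#'   `s in [0, 1]` returning a length-6 vector (force xyz, moment xyz)
#'   of trailing shares in `[0, 1]`.
#' @return object of class `transition_function`; call it via
#'   [eval_transition()].
#' @export
transition_function <- function(shape = c("smoothstep", "linear", "table"),
                                table = NULL) {
  shape <- match.arg(shape)
  if (shape == "table" && !is.function(table))
    stop("shape 'table' requires a function of the normalized phase")
  structure(list(shape = shape, table = table),
            class = "transition_function")
}

#' Evaluate a transition function
#'
#' @param ft a [transition_function()].
#' @param t elapsed time since the leading leg's heel-strike (s).
#' @param T_ds double-support duration (s).
#' @return length-6 vector of trailing-leg shares in `[0, 1]`
#'   (force x, y, z, moment x, y, z).
#' @export
eval_transition <- function(ft, t, T_ds) {
  s <- min(1, max(0, t / T_ds))
  switch(ft$shape,
    smoothstep = rep(1 - (3 * s^2 - 2 * s^3), 6),
    linear = rep(1 - s, 6),
    table = pmin(1, pmax(0, ft$table(s))))
}

#' Distribute the total wrench between the legs
#'
#' Implements the smooth transition assumption: in single support the
#' stance leg carries the whole wrench; in double support the trailing
#' leg's wrench is the total wrench frozen at the leading leg's
#' heel-strike, scaled element-wise by the transition function, and the
#' leading leg takes the remainder. All quantities are in the walking
#' frame.
#'
#' @param total list with `force`, `moment`: total wrench at time `t`.
#' @param total_at_hs same, frozen at the leading heel-strike (required
#'   during double support).
#' @param phase named character vector of per-leg phases.
#' @param leading leading leg label (most recent heel-strike).
#' @param t current time (s); `t_hs` leading heel-strike time.
#' @param T_ds double-support duration (s).
#' @param ft a [transition_function()].
#' @return named list of per-leg `list(force, moment)`.
#' @export
distribute_wrench <- function(total, total_at_hs = NULL, phase, leading,
                              t, t_hs = NA, T_ds = NA,
                              ft = transition_function()) {
  legs <- names(phase)
  zero <- list(force = c(0, 0, 0), moment = c(0, 0, 0))
  out <- stats::setNames(rep(list(zero), length(legs)), legs)
  stance <- legs[phase == "stance"]
  if (length(stance) <= 1) {
    # single support (or flight): stance leg takes everything
    if (length(stance) == 1) out[[stance]] <- total
    return(out)
  }
  # double support
  if (is.na(leading) || is.null(total_at_hs) || !is.finite(T_ds)) {
    # before the first heel-strike: fall back to single support on the
    # first detected stance leg
    out[[stance[1]]] <- total
    return(out)
  }
  trailing <- setdiff(stance, leading)[1]
  share <- eval_transition(ft, t - t_hs, T_ds)
  out[[trailing]] <- list(
    force = total_at_hs$force * share[1:3],
    moment = total_at_hs$moment * share[4:6])
  out[[leading]] <- list(
    force = total$force - out[[trailing]]$force,
    moment = total$moment - out[[trailing]]$moment)
  out
}

#' Center-of-pressure scaling factor
#'
#' Fraction of the heel-to-metatarsophalangeal distance travelled by the
#' center of pressure after time `t` of single support, with stance
#' frequency `w = 2 pi / T_ss`:
#' `sigma(t) = -(2 / (3 pi)) * (sin(w t) - sin(2 w t) / 8 - (3/4) w t)`.
#' Monotone from 0 at single-support onset to 1 at its end, with zero
#' slope at both endpoints.
#'
#' @param t time since single-support onset (s), in `[0, T_ss]`.
#' @param T_ss single-support duration (s), `> 0`.
#' @return scaling factor in `[0, 1]`.
#' @export
cop_scaling <- function(t, T_ss) {
  if (any(T_ss <= 0)) stop("T_ss must be > 0")
  w <- 2 * pi / T_ss
  -(2 / (3 * pi)) * (sin(w * t) - sin(2 * w * t) / 8 - 3 / 4 * w * t)
}

#' Center-of-pressure point for a stance foot
#'
#' The heel-to-metatarsophalangeal vector `d` is scaled by `sigma` and
#' the point `heel + sigma d` is projected onto the ground plane (y = 0).
#'
#' @param model an `msk_model` whose foot segments carry `heel` and
#'   `mtp` endpoints.
#' @param q coordinate vector (or a precomputed [forward_kinematics()]
#'   result).
#' @param foot foot segment name.
#' @param sigma scaling factor in `[0, 1]`.
#' @return length-3 CoP point on the ground plane.
#' @export
cop_trajectory <- function(model, q, foot, sigma) {
  fk <- if (is.list(q) && !is.null(q$segments)) q
        else forward_kinematics(model, q)
  eps <- model$segments[[foot]]$endpoints
  if (is.null(eps$heel) || is.null(eps$mtp))
    stop("foot segment '", foot, "' lacks heel/mtp endpoints")
  heel <- segment_point_world(fk, foot, eps$heel)
  mtp <- segment_point_world(fk, foot, eps$mtp)
  p <- heel + sigma * (mtp - heel)
  c(p[1], 0, p[3])
}

# express a (force, moment-about-origin) pair in the walking frame
to_walking <- function(wr, Rw) {
  list(force = as.numeric(t(Rw) %*% wr$force),
       moment = as.numeric(t(Rw) %*% wr$moment))
}
from_walking <- function(wr, Rw) {
  list(force = as.numeric(Rw %*% wr$force),
       moment = as.numeric(Rw %*% wr$moment))
}

#' Predict per-leg ground reaction wrenches from kinematics
#'
#' Composes the prediction pipeline per frame: total wrench, transform
#' into the walking frame, gait-phase bookkeeping, smooth-transition
#' distribution, per-leg CoP assignment, and back-transform to the
#' ground frame with the per-leg moment re-expressed about the assigned
#' CoP.
#'
#' Gait events can either be detected online from the heel-clearance
#' measure (the default) or supplied precomputed (e.g. from instrumented
#' timing) through `config$events`; support durations can likewise be
#' supplied via `config$T_ds`/`config$T_ss` or estimated online.
#'
#' @param model an `msk_model` with `foot_<leg>` segments.
#' @param states list of [gen_state()] (a filtered kinematics stream).
#' @param config list: `legs` (default `c("r","l")`), `feet` (segment
#'   names), `pelvis` segment, `transition` (a [transition_function()]),
#'   `v_th`, `k`, optional `events` data.frame (time, leg, type) and
#'   optional known `T_ds`, `T_ss`.
#' @return object of class `grfm_prediction`: data.frame `wrenches` with
#'   per-leg force/point/moment columns, the `events` log, and the
#'   per-frame `total` wrench.
#' @export
predict_grfm <- function(model, states, config = list()) {
  legs <- config$legs %||% c("r", "l")
  feet <- config$feet %||% stats::setNames(paste0("foot_", legs), legs)
  pelvis <- config$pelvis %||% "pelvis"
  ft <- config$transition %||% transition_function()
  v_th <- config$v_th %||% -0.02
  k_deb <- config$k %||% 3L
  known_events <- config$events
  det <- gait_detector(legs, v_th = v_th, k = k_deb)
  if (!is.null(config$T_ds)) det$T_ds <- config$T_ds
  if (!is.null(config$T_ss)) det$T_ss <- config$T_ss

  n <- length(states)
  cols <- c("time", unlist(lapply(legs, function(l)
    paste0(l, c("_force_x", "_force_y", "_force_z",
                "_point_x", "_point_y", "_point_z",
                "_moment_x", "_moment_y", "_moment_z")))))
  W <- matrix(0, nrow = n, ncol = length(cols),
              dimnames = list(NULL, cols))
  totals <- matrix(0, nrow = n, ncol = 6)
  yaw_window <- list()
  t_hs_lead <- NA_real_
  total_at_hs <- NULL
  ss_start <- stats::setNames(rep(NA_real_, length(legs)), legs)
  phase_prev <- NULL

  for (i in seq_len(n)) {
    st <- states[[i]]
    spatial <- com_kinematics(model, st)
    tw <- total_wrench(model, spatial)
    totals[i, ] <- c(tw$force, tw$moment)
    fk <- forward_kinematics(model, st$q)

    # walking frame from the running pelvis orientation window
    yaw_window[[length(yaw_window) + 1]] <- fk$segments[[pelvis]]$quat
    if (length(yaw_window) > 200) yaw_window <- yaw_window[-1]
    wd <- walking_direction(yaw_window)
    Rw <- wd$rotation
    tw_w <- to_walking(tw, Rw)

    # phase bookkeeping: supplied events or online detection
    if (!is.null(known_events)) {
      ev_now <- known_events[abs(known_events$time - st$t) < 1e-9, ]
      for (j in seq_len(nrow(ev_now))) {
        ev <- ev_now[j, ]
        det$events <- rbind(det$events, ev)
        det$state[[ev$leg]]$phase <-
          if (ev$type == "heel_strike") "stance" else "swing"
        if (ev$type == "heel_strike") det$leading <- ev$leg
      }
      if (nrow(ev_now) > 0 && is.null(config$T_ds)) det <- update_periods(det)
      emitted <- ev_now
    } else {
      u <- stats::setNames(vapply(legs, function(l) {
        eps <- model$segments[[feet[[l]]]]$endpoints
        heel <- segment_point_world(fk, feet[[l]], eps$heel)
        -heel[2]
      }, numeric(1)), legs)
      step <- detect_gait_phase(det, st$t, u)
      det <- step$detector
      emitted <- step$events
    }
    phase <- gait_phases(det)

    # cache the total wrench at the leading heel-strike; start the CoP
    # clock of a leg when its single support begins (other leg toes off)
    if (nrow(emitted) > 0) {
      for (j in seq_len(nrow(emitted))) {
        ev <- emitted[j, ]
        if (ev$type == "heel_strike") {
          t_hs_lead <- ev$time
          total_at_hs <- tw_w
        } else {
          other <- setdiff(legs, ev$leg)
          ss_start[other] <- ev$time
        }
      }
    }

    split <- distribute_wrench(tw_w, total_at_hs, phase, det$leading,
                               t = st$t, t_hs = t_hs_lead,
                               T_ds = det$T_ds, ft = ft)

    row <- st$t
    both_stance <- sum(phase == "stance") >= 2
    for (l in legs) {
      wr_w <- split[[l]]
      wr <- from_walking(wr_w, Rw)
      if (phase[[l]] == "stance") {
        if (both_stance) {
          # double support: trailing pinned at its mtp, leading at heel
          sg <- if (identical(det$leading, l)) 0 else 1
        } else {
          tss <- if (is.finite(det$T_ss)) det$T_ss else NA_real_
          sg <- if (is.finite(tss) && is.finite(ss_start[[l]]))
            cop_scaling(min(max(st$t - ss_start[[l]], 0), tss), tss) else 0
        }
        p_cop <- cop_trajectory(model, fk, feet[[l]], sg)
      } else {
        p_cop <- c(0, 0, 0)
      }
      m_cop <- wr$moment - cross3(p_cop, wr$force)
      row <- c(row, wr$force, p_cop, m_cop)
    }
    W[i, ] <- row
    phase_prev <- phase
  }
  structure(list(wrenches = as.data.frame(W), events = det$events,
                 totals = totals, legs = legs),
            class = "grfm_prediction")
}

#' Convert one row of a GRF&M prediction to external wrenches
#'
#' @param pred a `grfm_prediction`.
#' @param i frame index.
#' @param feet named mapping leg -> foot segment.
#' @return list of [external_wrench()] (one per leg in stance; legs with
#'   zero force are kept with zero wrenches).
#' @export
grfm_wrenches <- function(pred, i,
                          feet = stats::setNames(
                            paste0("foot_", pred$legs), pred$legs)) {
  row <- pred$wrenches[i, ]
  lapply(pred$legs, function(l) {
    g <- function(suffix) as.numeric(row[paste0(l, suffix)])
    external_wrench(feet[[l]],
                    point = g(c("_point_x", "_point_y", "_point_z")),
                    force = g(c("_force_x", "_force_y", "_force_z")),
                    moment = g(c("_moment_x", "_moment_y", "_moment_z")))
  })
}
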