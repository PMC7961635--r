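# Marker- and IMU-based inverse kinematics: per-frame weighted
# least-squares tracking of marker positions and segment orientations,
# IMU placement/heading calibration, marker completion for occlusions,
# and multi-source stream resampling.

#' Create an observation frame
#'
#' One time-stamped set of IK targets: marker positions (ground frame)
#' and/or segment orientations (quaternions). A missing target is `NULL`.
#'
#' @param t time (s).
#' @param markers named list of length-3 positions (or `NULL` entries for
#'   occluded markers).
#' @param orientations named list of quaternions (IMU names).
#' @param marker_weights,orientation_weights named numeric vectors of
#'   nonnegative weights; unnamed targets default to weight 1.
#' @return object of class `observation_frame`.
#' @export
observation_frame <- function(t, markers = list(), orientations = list(),
                              marker_weights = NULL,
                              orientation_weights = NULL) {
  n_obs <- sum(!vapply(markers, is.null, logical(1))) +
    sum(!vapply(orientations, is.null, logical(1)))
  if (n_obs == 0) stop("observation frame needs at least one target")
  if (any(c(marker_weights, orientation_weights) < 0))
    stop("weights must be >= 0")
  structure(list(t = t, markers = markers, orientations = orientations,
                 marker_weights = marker_weights,
                 orientation_weights = orientation_weights),
            class = "observation_frame")
}

target_weight <- function(weights, name) {
  if (is.null(weights) || is.na(weights[name] %||% NA)) 1 else
    unname(weights[name])
}

#' Calibrate IMU placement and heading
#'
#' Averages the sensor orientations over a static trial in which the
#' subject holds the model's default pose, then computes a constant
#' offset rotation composed of (i) the given Earth-to-model frame change
#' and (ii) a heading rotation about the vertical that aligns the
#' horizontal projection of the base sensor's anterior axis with the
#' model's anterior axis (+x). The composed offset is pre-multiplied to
#' every sensor stream for the rest of the session; using only the
#' horizontal projection keeps vertical tilt of the base sensor from
#' corrupting the yaw alignment.
#'
#' @param model an `msk_model` (default pose `q = 0` defines the target
#'   orientations).
#' @param static_frames list of [observation_frame()]s spanning the
#'   static pose.
#' @param base_imu name of the base (pelvis/torso) sensor.
#' @param earth_to_model rotation matrix taking Earth-frame vectors to
#'   the model ground frame (identity when the acquisition frame is
#'   already y-up/x-forward).
#' @return object of class `imu_calibration` with fields
#'   `earth_to_model`, `heading` (matrix), `heading_angle` (rad) and the
#'   composed `offset` matrix.
#' @export
calibrate_imu_placement <- function(model, static_frames, base_imu,
                                    earth_to_model = diag(3)) {
  qs <- lapply(static_frames, function(f) f$orientations[[base_imu]])
  qs <- Filter(Negate(is.null), qs)
  if (length(qs) == 0)
    stop("base IMU '", base_imu, "' absent from static frames")
  mean_quat <- function(qlist) {
    A <- matrix(0, 4, 4)
    for (q in qlist) A <- A + tcrossprod(q)
    quat_normalize(eigen(A, symmetric = TRUE)$vectors[, 1])
  }
  R_meas <- earth_to_model %*% quat_to_matrix(mean_quat(qs))
  # expected orientation of that sensor at the default pose
  fk0 <- forward_kinematics(model, numeric(n_coords(model)))
  R_exp <- quat_to_matrix(fk0$imus[[base_imu]])
  # sensor-frame direction that should point along the model's +x
  a_sensor <- as.numeric(t(R_exp) %*% c(1, 0, 0))
  v <- as.numeric(R_meas %*% a_sensor)
  v_h <- c(v[1], 0, v[3])
  if (sqrt(sum(v_h^2)) < 1e-6)
    stop("base sensor anterior axis is vertical; heading undefined")
  v_h <- v_h / sqrt(sum(v_h^2))
  # rotation about +y taking v_h to +x
  ang <- atan2(v_h[3], v_h[1])   # yaw of v_h measured toward +z
  heading <- rotation_about_axis(c(0, 1, 0), ang)
  structure(list(earth_to_model = earth_to_model, heading = heading,
                 heading_angle = ang,
                 offset = heading %*% earth_to_model),
            class = "imu_calibration")
}

#' Apply an IMU calibration to an observation frame or stream
#'
#' Pre-multiplies every orientation target by the constant calibration
#' offset, expressing sensor orientations in the model ground frame.
#'
#' @param frames an [observation_frame()] or a list of them.
#' @param calibration an `imu_calibration`.
#' @return the calibrated frame(s).
#' @export
apply_imu_calibration <- function(frames, calibration) {
  q_off <- matrix_to_quat(calibration$offset)
  one <- function(f) {
    f$orientations <- lapply(f$orientations, function(q)
      if (is.null(q)) NULL else quat_multiply(q_off, q))
    f
  }
  if (inherits(frames, "observation_frame")) one(frames)
  else lapply(frames, one)
}

#' Reconstruct occluded markers
#'
#' Markers missing from `frame` are reconstructed per segment: if at
#' least three of the segment's markers are visible, the rigid transform
#' (orthogonal Procrustes/Kabsch fit of the visible markers' model-frame
#' positions to their world positions) is applied to the missing markers'
#' model-frame positions; otherwise the last known position is held and
#' the marker flagged. Never hard-fails.
#'
#' @param frame an [observation_frame()].
#' @param model an `msk_model`.
#' @param history state carried between calls; pass the `history` element
#'   of the previous result (or `NULL` on the first frame).
#' @return list with the completed `frame`, a `report` data.frame
#'   (marker, method) and the updated `history`.
#' @export
complete_markers <- function(frame, model, history = NULL) {
  if (is.null(history)) history <- list(last = list())
  mk <- frame$markers
  model_marks <- model$markers[names(model$markers) %in% names(mk)]
  missing <- names(mk)[vapply(mk, is.null, logical(1))]
  report <- data.frame(marker = character(0), method = character(0))
  if (length(missing) > 0) {
    seg_of <- vapply(model$markers, function(m) m$segment, character(1))
    for (sn in unique(seg_of[missing])) {
      seg_markers <- names(seg_of)[seg_of == sn]
      vis <- setdiff(intersect(seg_markers, names(mk)), missing)
      miss_here <- intersect(missing, seg_markers)
      if (length(vis) >= 3) {
        X <- vapply(vis, function(nm) model$markers[[nm]]$position,
                    numeric(3))
        Y <- vapply(vis, function(nm) mk[[nm]], numeric(3))
        tr <- kabsch(X, Y)
        for (nm in miss_here) {
          mk[[nm]] <- as.numeric(
            tr$R %*% model$markers[[nm]]$position + tr$t)
          report <- rbind(report,
                          data.frame(marker = nm, method = "procrustes"))
        }
      } else {
        for (nm in miss_here) {
          if (!is.null(history$last[[nm]])) {
            mk[[nm]] <- history$last[[nm]]
            report <- rbind(report,
                            data.frame(marker = nm, method = "held"))
          } else {
            report <- rbind(report,
                            data.frame(marker = nm, method = "unresolved"))
          }
        }
      }
    }
  }
  for (nm in names(mk)) if (!is.null(mk[[nm]])) history$last[[nm]] <- mk[[nm]]
  frame$markers <- mk
  list(frame = frame, report = report, history = history)
}

# rigid fit Y ~ R X + t (columns are points)
kabsch <- function(X, Y) {
  cx <- rowMeans(X); cy <- rowMeans(Y)
  H <- (X - cx) %*% t(Y - cy)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = cy - as.numeric(R %*% cx))
}

ik_residual <- function(model, frame, q) {
  fk <- forward_kinematics(model, q)
  res <- numeric(0)
  for (nm in names(frame$markers)) {
    obs <- frame$markers[[nm]]
    if (is.null(obs) || is.null(fk$markers[[nm]])) next
    w <- target_weight(frame$marker_weights, nm)
    res <- c(res, sqrt(w) * (fk$markers[[nm]] - obs))
  }
  for (nm in names(frame$orientations)) {
    obs <- frame$orientations[[nm]]
    if (is.null(obs) || is.null(fk$imus[[nm]])) next
    w <- target_weight(frame$orientation_weights, nm)
    R_rel <- t(quat_to_matrix(fk$imus[[nm]])) %*% quat_to_matrix(obs)
    res <- c(res, sqrt(w) * rotation_log(R_rel))
  }
  res
}

#' Solve one inverse-kinematics frame
#'
#' Minimizes the weighted sum of squared marker position errors and
#' squared geodesic orientation errors over the generalized coordinates,
#' by damped Gauss-Newton (Levenberg-Marquardt) on the stacked residuals
#' with a numeric Jacobian. For tree models there are no holonomic
#' constraints, so the constraint-penalty term is identically zero; the
#' argument is kept for models with loop-closure penalties.
#'
#' @param model an `msk_model`.
#' @param frame an [observation_frame()].
#' @param q_init starting coordinates (warm start with the previous
#'   frame's solution for streaming use).
#' @param constraint_penalty_weight weight of the (empty) constraint
#'   penalty; unused for tree models.
#' @param max_iter,tol iteration cap and step-norm stopping tolerance.
#' @return list with `q`, `objective`, per-target `errors` (data.frame),
#'   `iterations` and `converged`.
#' @export
solve_frame <- function(model, frame, q_init = NULL,
                        constraint_penalty_weight = 1,
                        max_iter = 100, tol = 1e-10) {
  N <- n_coords(model)
  q <- if (is.null(q_init)) numeric(N) else as.numeric(q_init)
  if (length(q) != N) stop("q_init has wrong length")
  if (!all(is.finite(q))) stop("q_init must be finite")
  cost <- function(q) { r <- ik_residual(model, frame, q); 0.5 * sum(r^2) }
  r <- ik_residual(model, frame, q)
  if (length(r) == 0) stop("frame has no targets known to the model")
  lambda <- 1e-3
  converged <- FALSE
  iter <- 0
  h <- 1e-6
  while (iter < max_iter) {
    iter <- iter + 1
    J <- matrix(0, length(r), N)
    for (k in seq_len(N)) {
      qp <- q; qp[k] <- qp[k] + h
      qm <- q; qm[k] <- qm[k] - h
      J[, k] <- (ik_residual(model, frame, qp) -
                 ik_residual(model, frame, qm)) / (2 * h)
    }
    g <- crossprod(J, r)
    if (max(abs(g)) < 1e-12) { converged <- TRUE; break }
    A <- crossprod(J)
    improved <- FALSE
    for (tries in 1:12) {
      dq <- tryCatch(
        as.numeric(solve(A + lambda * diag(N), -g)),
        error = function(e) NULL)
      if (!is.null(dq)) {
        r_new <- ik_residual(model, frame, q + dq)
        if (0.5 * sum(r_new^2) <= 0.5 * sum(r^2)) {
          q <- q + dq; r <- r_new
          lambda <- max(lambda / 3, 1e-12)
          improved <- TRUE
          if (sqrt(sum(dq^2)) < tol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!improved || converged) { if (improved) converged <- TRUE; break }
  }
  fk <- forward_kinematics(model, q)
  errs <- data.frame(target = character(0), type = character(0),
                     error = numeric(0))
  for (nm in names(frame$markers)) {
    obs <- frame$markers[[nm]]
    if (is.null(obs) || is.null(fk$markers[[nm]])) next
    errs <- rbind(errs, data.frame(
      target = nm, type = "marker",
      error = sqrt(sum((fk$markers[[nm]] - obs)^2))))
  }
  for (nm in names(frame$orientations)) {
    obs <- frame$orientations[[nm]]
    if (is.null(obs) || is.null(fk$imus[[nm]])) next
    errs <- rbind(errs, data.frame(
      target = nm, type = "orientation",
      error = quat_geodesic(fk$imus[[nm]], obs)))
  }
  list(q = q, objective = 0.5 * sum(r^2), errors = errs,
       iterations = iter, converged = converged)
}

#' Solve inverse kinematics over a stream of frames
#'
#' Sequentially solves each frame, warm-starting from the previous
#' solution, with optional marker completion.
#'
#' @param model an `msk_model`.
#' @param frames list of [observation_frame()]s.
#' @param q_init starting coordinates for the first frame.
#' @param complete run [complete_markers()] before each solve.
#' @return data.frame with `time` and one column per coordinate.
#' @export
solve_ik <- function(model, frames, q_init = NULL, complete = TRUE) {
  N <- n_coords(model)
  q <- if (is.null(q_init)) numeric(N) else q_init
  history <- NULL
  out <- matrix(NA_real_, nrow = length(frames), ncol = N + 1)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (complete && length(f$markers) > 0) {
      cm <- complete_markers(f, model, history)
      f <- cm$frame; history <- cm$history
    }
    sol <- solve_frame(model, f, q_init = q)
    q <- sol$q
    out[i, ] <- c(f$t, q)
  }
  out <- as.data.frame(out)
  names(out) <- c("time", coord_names(model))
  out
}

#' Resample multi-source observation streams to a shared uniform grid
#'
#' Each source is a list of [observation_frame()]s with monotone
#' timestamps. Channels are linearly interpolated (spherical-linear for
#' orientations) onto a uniform grid at `fs` spanning the overlap of all
#' sources, and merged into one frame per grid point.
#'
#' @param sources list of frame lists (one per device).
#' @param fs target sampling frequency (Hz).
#' @return list of merged, uniformly sampled [observation_frame()]s.
#' @export
resample_streams <- function(sources, fs) {
  if (length(sources) == 0) stop("no sources")
  times <- lapply(sources, function(src) {
    if (length(src) == 0) stop("empty source")
    tt <- vapply(src, function(f) f$t, numeric(1))
    if (any(diff(tt) <= 0)) stop("source timestamps must be increasing")
    tt
  })
  t0 <- max(vapply(times, min, numeric(1)))
  t1 <- min(vapply(times, max, numeric(1)))
  if (t1 < t0) stop("sources do not overlap in time")
  grid <- seq(t0, t1, by = 1 / fs)
  out <- lapply(grid, function(tg) {
    markers <- list(); orientations <- list()
    for (si in seq_along(sources)) {
      src <- sources[[si]]; tt <- times[[si]]
      i <- findInterval(tg, tt, rightmost.closed = TRUE)
      i <- max(1, min(i, length(tt) - 1))
      s <- if (tt[i + 1] > tt[i]) (tg - tt[i]) / (tt[i + 1] - tt[i]) else 0
      f0 <- src[[i]]; f1 <- src[[i + 1]]
      for (nm in union(names(f0$markers), names(f1$markers))) {
        a <- f0$markers[[nm]]; b <- f1$markers[[nm]]
        markers[[nm]] <- if (is.null(a) || is.null(b)) NULL
          else (1 - s) * a + s * b
      }
      for (nm in union(names(f0$orientations), names(f1$orientations))) {
        a <- f0$orientations[[nm]]; b <- f1$orientations[[nm]]
        orientations[[nm]] <- if (is.null(a) || is.null(b)) NULL
          else quat_slerp(a, b, s)
      }
    }
    observation_frame(tg, markers, orientations)
  })
  out
}
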