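# Pipeline plumbing: a bounded FIFO frame buffer decoupling acquisition
# (IK per arriving frame) from processing (filter -> inverse dynamics ->
# GRF&M -> muscle optimization -> joint reactions), an end-to-end driver
# with an interleaved event loop emulating the two-thread architecture,
# a value-identical single-pass replay mode, and per-module latency
# accounting.

#' Bounded FIFO frame buffer
#'
#' Payloads are delivered in producer order. On overflow the
#' `drop_oldest` policy discards the oldest payload (counting drops);
#' `block` refuses the push (the sequential driver drains the consumer
#' first, so a blocking buffer never overflows in replay mode).
#'
#' @param capacity maximum queued payloads, `> 0`.
#' @param policy `"drop_oldest"` or `"block"`.
#' @return object of class `frame_buffer` (environment).
#' @export
frame_buffer <- function(capacity = 64, policy = c("drop_oldest",
                                                   "block")) {
  if (capacity <= 0) stop("capacity must be > 0")
  policy <- match.arg(policy)
  env <- new.env(parent = emptyenv())
  env$items <- vector("list", capacity)
  env$head <- 1L; env$count <- 0L
  env$capacity <- as.integer(capacity)
  env$policy <- policy
  env$dropped <- 0L
  class(env) <- "frame_buffer"
  env
}

#' @rdname frame_buffer
#' @param buf a `frame_buffer`.
#' @param x payload.
#' @return `TRUE` if stored, `FALSE` if refused (policy `block`, full).
#' @export
buffer_push <- function(buf, x) {
  if (buf$count == buf$capacity) {
    if (buf$policy == "block") return(FALSE)
    buf$head <- buf$head %% buf$capacity + 1L
    buf$count <- buf$count - 1L
    buf$dropped <- buf$dropped + 1L
  }
  slot <- (buf$head - 1L + buf$count) %% buf$capacity + 1L
  buf$items[[slot]] <- x
  buf$count <- buf$count + 1L
  TRUE
}

#' @rdname frame_buffer
#' @return the oldest payload, or `NULL` when empty.
#' @export
buffer_pop <- function(buf) {
  if (buf$count == 0L) return(NULL)
  x <- buf$items[[buf$head]]
  buf$items[buf$head] <- list(NULL)
  buf$head <- buf$head %% buf$capacity + 1L
  buf$count <- buf$count - 1L
  x
}

#' @rdname frame_buffer
#' @export
buffer_size <- function(buf) buf$count

new_latency_log <- function() {
  env <- new.env(parent = emptyenv())
  env$records <- list()
  env
}

log_latency <- function(log, module, seconds) {
  log$records[[length(log$records) + 1]] <-
    list(module = module, seconds = seconds)
  invisible(log)
}

#' Summarize a pipeline latency log
#'
#' @param log the `latency` element of a [run_pipeline()] result.
#' @return data.frame with per-module frame counts, mean and 50/90/99th
#'   percentile durations (ms).
#' @export
latency_summary <- function(log) {
  if (length(log$records) == 0)
    return(data.frame(module = character(0)))
  mods <- vapply(log$records, function(r) r$module, character(1))
  secs <- vapply(log$records, function(r) r$seconds, numeric(1))
  out <- lapply(unique(mods), function(m) {
    s <- secs[mods == m] * 1e3
    data.frame(module = m, frames = length(s), mean_ms = mean(s),
               p50_ms = stats::quantile(s, 0.5),
               p90_ms = stats::quantile(s, 0.9),
               p99_ms = stats::quantile(s, 0.99))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Run the full real-time analysis pipeline
#'
#' The acquisition stage solves IK per observation frame (with marker
#' completion) and pushes coordinates into the frame buffer; the
#' processing stage consumes them through the real-time filter and runs
#' inverse dynamics, GRF&M prediction (or measured wrenches), muscle
#' optimization and joint reaction analysis. The two stages are
#' interleaved through the buffer; `replay = TRUE` runs the identical
#' computation in a single pass with a blocking buffer and must produce
#' value-identical outputs.
#'
#' @param config list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{model}{path to a model file, or an `msk_model`.}
#'     \item{simulate}{optional list (`duration`, `fs`, `marker_sigma`,
#'       `orient_sigma`, `occlusion`, `seed`, gait parameter overrides) —
#'       generates the input streams internally.}
#'     \item{trc, quat_csv}{input file paths (when not simulating).}
#'     \item{filter}{list with `M`, `fc`, `Ns`, `D` (and `fs`).}
#'     \item{grfm}{`"predict"`, `"none"`, or a path/data.frame of
#'       measured wrenches in the predictor's column layout.}
#'     \item{muscles}{`TRUE`/`FALSE` or list(`p`, `degree`).}
#'     \item{reactions}{`TRUE`/`FALSE`.}
#'     \item{output_dir}{optional directory for STO outputs.}
#'     \item{buffer}{list(`capacity`, `policy`).}
#'   }
#' @param replay single-pass deterministic mode (default `TRUE`; the
#'   interleaved mode exercises the buffer).
#' @return list with `coordinates` (IK), `filtered` (value/d1/d2),
#'   `tau`, `grfm`, `muscle_forces`, `reactions` data.frames, the
#'   `latency` log and `buffer_dropped` count.
#' @export
run_pipeline <- function(config, replay = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$model)) stop("config lacks 'model'")
  model <- if (inherits(config$model, "msk_model")) config$model
           else load_model(config$model)

  fs <- config$filter$fs %||% 100
  lat <- new_latency_log()

  # ---- input streams -------------------------------------------------
  events <- NULL; known_periods <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    params <- gait_params(
      T_cycle = sim$T_cycle %||% 1.2,
      ds_fraction = sim$ds_fraction %||% 0.15,
      speed = sim$speed %||% 1.2,
      marker_sigma = sim$marker_sigma %||% 0,
      occlusion = sim$occlusion %||% 0,
      seed = sim$seed %||% 1L)
    traj <- generate_gait_trajectory(model, params, fs = fs,
                                     duration = sim$duration %||% 2.4)
    frames <- synthesize_markers(model, traj$states,
                                 sigma = params$marker_sigma,
                                 occlusion = params$occlusion,
                                 seed = params$seed)
    sched <- gait_schedule(params)
    events <- sched$events_in(traj$time[1], traj$time[length(traj$time)])
    known_periods <- list(T_ds = sched$T_ds, T_ss = sched$T_ss)
  } else {
    if (is.null(config$trc) && is.null(config$quat_csv))
      stop("config needs 'simulate' or input files ('trc'/'quat_csv')")
    sources <- list()
    if (!is.null(config$trc)) {
      if (!file.exists(config$trc)) stop("missing TRC: ", config$trc)
      sources <- c(sources, list(read_trc(config$trc)))
    }
    if (!is.null(config$quat_csv)) {
      if (!file.exists(config$quat_csv))
        stop("missing quaternion CSV: ", config$quat_csv)
      sources <- c(sources, list(read_quat_csv(config$quat_csv)))
    }
    frames <- if (length(sources) > 1 ||
                  !is.null(config$resample %||% NULL))
      resample_streams(sources, fs) else sources[[1]]
  }

  # ---- acquisition: IK per frame -> buffer ---------------------------
  bufcfg <- config$buffer %||% list()
  buf <- frame_buffer(bufcfg$capacity %||% 256,
                      if (replay) "block"
                      else bufcfg$policy %||% "drop_oldest")
  fcfg <- filter_config(M = config$filter$M %||% 35,
                        fc = config$filter$fc %||% 6,
                        Ns = config$filter$Ns %||% 3,
                        D = config$filter$D %||% 14, fs = fs)
  filt <- rt_filter(fcfg, n_coords(model), coord_names(model))

  q_warm <- numeric(n_coords(model))
  history <- NULL
  coords_rows <- list()
  filtered_states <- list()

  acquire_one <- function(f) {
    t0 <- proc.time()[3]
    if (length(f$markers) > 0) {
      cm <- complete_markers(f, model, history)
      f <- cm$frame; history <<- cm$history
    }
    sol <- solve_frame(model, f, q_init = q_warm)
    q_warm <<- sol$q
    log_latency(lat, "ik", proc.time()[3] - t0)
    list(t = f$t, q = sol$q)
  }
  process_one <- function(item) {
    t0 <- proc.time()[3]
    st <- push_and_evaluate(filt, item$t, item$q)
    filt <<- st$filter
    log_latency(lat, "filter", proc.time()[3] - t0)
    if (!is.null(st$output)) {
      o <- st$output
      filtered_states[[length(filtered_states) + 1]] <<-
        gen_state(o$t_d, o$value, o$d1, o$d2)
    }
  }

  for (f in frames) {
    item <- acquire_one(f)
    coords_rows[[length(coords_rows) + 1]] <- c(item$t, item$q)
    ok <- buffer_push(buf, item)
    if (!ok) stop("frame buffer full under blocking policy")
    if (replay) {
      process_one(buffer_pop(buf))
    } else {
      # interleaved event loop: drain opportunistically
      while (buf$count > 0) process_one(buffer_pop(buf))
    }
  }
  while (buf$count > 0) process_one(buffer_pop(buf))

  coordinates <- as.data.frame(do.call(rbind, coords_rows))
  names(coordinates) <- c("time", coord_names(model))
  filtered <- data.frame(
    time = vapply(filtered_states, function(s) s$t, numeric(1)))
  filtered[coord_names(model)] <-
    t(vapply(filtered_states, function(s) s$q,
             numeric(n_coords(model))))

  # ---- GRF&M ---------------------------------------------------------
  grfm_mode <- config$grfm %||% "predict"
  grfm <- NULL; wrench_lists <- NULL
  if (identical(grfm_mode, "predict")) {
    t0 <- proc.time()[3]
    gcfg <- list(events = events, T_ds = known_periods$T_ds,
                 T_ss = known_periods$T_ss)
    grfm <- predict_grfm(model, filtered_states, gcfg)
    log_latency(lat, "grfm", proc.time()[3] - t0)
    wrench_lists <- lapply(seq_along(filtered_states), function(i)
      grfm_wrenches(grfm, i))
  } else if (is.character(grfm_mode) && grfm_mode != "none") {
    meas <- read_sto(grfm_mode)
    wrench_lists <- lapply(filtered_states, function(s) {
      i <- which.min(abs(meas$time - s$t))
      lapply(c("r", "l"), function(l) {
        g <- function(sfx) as.numeric(meas[i, paste0(l, sfx)])
        external_wrench(paste0("foot_", l),
                        g(c("_point_x", "_point_y", "_point_z")),
                        g(c("_force_x", "_force_y", "_force_z")),
                        g(c("_moment_x", "_moment_y", "_moment_z")))
      })
    })
  }

  # ---- inverse dynamics ---------------------------------------------
  gfs <- vector("list", length(filtered_states))
  for (i in seq_along(filtered_states)) {
    t0 <- proc.time()[3]
    ext <- if (is.null(wrench_lists)) list() else wrench_lists[[i]]
    gfs[[i]] <- inverse_dynamics(model, filtered_states[[i]], ext)
    log_latency(lat, "id", proc.time()[3] - t0)
  }
  tau <- data.frame(time = filtered$time)
  tau[coord_names(model)] <-
    t(vapply(gfs, function(g) g$tau, numeric(n_coords(model))))

  # ---- muscles + reactions ------------------------------------------
  muscles_cfg <- config$muscles %||% FALSE
  msol <- NULL; reactions <- NULL
  if (!identical(muscles_cfg, FALSE) && length(model$muscles) > 0) {
    if (isTRUE(muscles_cfg)) muscles_cfg <- list()
    t0 <- proc.time()[3]
    mam <- build_moment_arm_model(model,
                                  degree = muscles_cfg$degree %||% 4)
    msol <- solve_muscles_stream(model, filtered_states, gfs, mam,
                                 p = muscles_cfg$p %||% 2)
    log_latency(lat, "muscles", proc.time()[3] - t0)
    if (isTRUE(config$reactions %||% FALSE)) {
      rx <- lapply(seq_along(filtered_states), function(i) {
        t0 <- proc.time()[3]
        ext <- if (is.null(wrench_lists)) list() else wrench_lists[[i]]
        jr <- joint_reaction_analysis(model, filtered_states[[i]],
                                      unlist(msol$forces[i, -1]), ext)
        log_latency(lat, "reactions", proc.time()[3] - t0)
        cbind(data.frame(time = filtered_states[[i]]$t), jr)
      })
      reactions <- do.call(rbind, rx)
    }
  }

  out <- list(coordinates = coordinates, filtered = filtered,
              filtered_states = filtered_states, tau = tau,
              grfm = grfm,
              muscle_forces = if (!is.null(msol)) msol$forces else NULL,
              reactions = reactions, latency = lat,
              buffer_dropped = buf$dropped)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, nm) if (!is.null(df))
      write_sto(df, file.path(config$output_dir, nm))
    w(coordinates, "coordinates.sto")
    w(filtered, "filtered.sto")
    w(tau, "generalized_forces.sto")
    if (!is.null(grfm)) w(grfm$wrenches, "grfm.sto")
    w(out$muscle_forces, "muscle_forces.sto")
    if (!is.null(reactions)) {
      wide <- stats::reshape(
        reactions[, c("time", "joint", "fx", "fy", "fz",
                      "mx", "my", "mz")],
        idvar = "time", timevar = "joint", direction = "wide", sep = "_")
      w(wide, "joint_reactions.sto")
    }
  }
  out
}
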