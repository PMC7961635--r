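# Inverse dynamics by the recursive Newton-Euler method, generalized to
# the elementary-joint chain. Generalized forces are obtained by
# projecting subtree inertial-minus-applied wrenches onto each
# coordinate's joint axis (d'Alembert); the floating-base block doubles
# as the residual-force diagnostic.

GRAVITY <- c(0, -9.80665, 0)

#' Create an external wrench
#'
#' The 9-vector currency of ground reactions: an application point, a
#' force and a free moment, expressed in the ground frame (or tagged as
#' walking-frame during GRF&M distribution).
#'
#' @param segment name of the segment the wrench acts on.
#' @param point application point (ground frame, m).
#' @param force force vector (N).
#' @param moment free moment (N m).
#' @param frame `"ground"` or `"walking"`.
#' @return object of class `external_wrench`.
#' @export
external_wrench <- function(segment, point, force, moment = c(0, 0, 0),
                            frame = "ground") {
  w <- list(segment = segment, point = as.numeric(point),
            force = as.numeric(force), moment = as.numeric(moment),
            frame = frame)
  if (!all(is.finite(c(w$point, w$force, w$moment))))
    stop("external wrench entries must be finite")
  structure(w, class = "external_wrench")
}

# Per-subtree net wrench: F = sum m (a - g) - sum f_ext,
# N(p0) = sum[(c - p0) x m(a - g) + I alpha + w x I w]
#         - sum[(p_ext - p0) x f_ext + m_ext],
# over the given segments, with point loads (muscle path forces) and
# external wrenches restricted to those segments.
subtree_wrench <- function(model, spatial, segments, about,
                           external = list(), point_loads = list()) {
  F <- c(0, 0, 0); N <- c(0, 0, 0)
  for (sn in segments) {
    s <- model$segments[[sn]]
    k <- spatial$segments[[sn]]
    Iw <- k$R %*% s$inertia %*% t(k$R)
    fg <- s$mass * (k$a_com - GRAVITY)
    F <- F + fg
    N <- N + cross3(k$com - about, fg) +
      as.numeric(Iw %*% k$alpha) + cross3(k$omega, as.numeric(Iw %*% k$omega))
  }
  for (w in external) {
    if (!(w$segment %in% names(model$segments)))
      stop("external wrench on unknown segment '", w$segment, "'")
    if (!(w$segment %in% segments)) next
    F <- F - w$force
    N <- N - cross3(w$point - about, w$force) - w$moment
  }
  for (pl in point_loads) {
    if (!(pl$segment %in% segments)) next
    F <- F - pl$force
    N <- N - cross3(pl$point - about, pl$force)
  }
  list(force = F, moment = N)
}

#' Recursive Newton-Euler inverse dynamics
#'
#' Computes the generalized forces `tau` that balance the equations of
#' motion for a full generalized state and a set of external wrenches.
#' The first block of `tau` (the floating-base coordinates, if any) holds
#' the residual forces: non-physical loads that absorb any inconsistency
#' between the kinematics and the applied external loads.
#'
#' @param model an `msk_model`.
#' @param state a [gen_state()] with `q`, `u`, `a`.
#' @param external list of [external_wrench()] objects (ground frame).
#' @param point_loads optional list of `list(segment, point, force)` point
#'   forces (ground frame), e.g. muscle path forces.
#' @return object of class `generalized_forces`: `tau` (named, coordinate
#'   order), `base` (residual block indices), `actuated` (the rest).
#' @export
inverse_dynamics <- function(model, state, external = list(),
                             point_loads = list()) {
  spatial <- com_kinematics(model, state)
  ch <- model$chain
  N <- n_coords(model)
  # world axis and origin of each coordinate's elementary joint element
  fkq <- forward_kinematics(model, state$q)
  # recompute element frames (cheap, tiny models): reuse chain walk
  tau <- numeric(N)
  el_R <- vector("list", length(ch$elements))
  el_p <- vector("list", length(ch$elements))
  for (e in seq_along(ch$elements)) {
    el <- ch$elements[[e]]
    if (el$parent == 0) { Rp <- diag(3); pp <- c(0, 0, 0) }
    else { Rp <- el_R[[el$parent]]; pp <- el_p[[el$parent]] }
    p <- pp + as.numeric(Rp %*% el$r)
    R <- Rp
    if (el$type == "P") p <- p + as.numeric(Rp %*% el$axis) * state$q[el$coord]
    if (el$type == "R") R <- Rp %*% rotation_about_axis(el$axis, state$q[el$coord])
    el_R[[e]] <- R; el_p[[e]] <- p
    if (!is.na(el$coord)) {
      z <- as.numeric(Rp %*% el$axis)
      segs <- ch$descendants[[e]]
      sw <- subtree_wrench(model, spatial, segs, about = p,
                           external = external, point_loads = point_loads)
      tau[el$coord] <- if (el$type == "P") sum(z * sw$force)
                       else sum(z * sw$moment)
    }
  }
  names(tau) <- ch$coord_names
  structure(list(tau = tau, base = base_coords(model),
                 actuated = actuated_coords(model), t = state$t),
            class = "generalized_forces")
}

#' @export
print.generalized_forces <- function(x, ...) {
  cat("generalized_forces @ t =", x$t, "\n")
  print(round(x$tau, 6))
  invisible(x)
}

#' Residual-force report
#'
#' Extracts the floating-base block of one or more generalized-force
#' results and summarizes it. The base residuals are the pipeline's
#' consistency diagnostic: with dynamically consistent kinematics and
#' external loads they vanish.
#'
#' @param gf a `generalized_forces` object or a list of them (a stream).
#' @return list with `residuals` (matrix, frames x base coordinates) and
#'   `rms` (per-coordinate root-mean-square).
#' @export
residual_report <- function(gf) {
  if (inherits(gf, "generalized_forces")) gf <- list(gf)
  if (length(gf) == 0) return(list(residuals = NULL, rms = NULL))
  base <- gf[[1]]$base
  if (length(base) == 0) {
    res <- matrix(numeric(0), nrow = length(gf), ncol = 0)
  } else {
    res <- t(vapply(gf, function(g) g$tau[base], numeric(length(base))))
    if (length(base) == 1) res <- matrix(res, ncol = 1)
  }
  rms <- if (ncol(res) > 0) sqrt(colMeans(res^2)) else numeric(0)
  list(residuals = res, rms = rms)
}

# --- test-support forward integrator (not a product feature) ----------

# Mass matrix and bias via inverse dynamics: M[,j] = tau(a = e_j) - tau(0),
# bias = tau(a = 0). Used only to integrate small fixtures in tests.
mass_matrix_bias <- function(model, t, q, u, external = list()) {
  N <- n_coords(model)
  bias <- inverse_dynamics(model, gen_state(t, q, u, numeric(N)),
                           external)$tau
  M <- matrix(0, N, N)
  for (j in seq_len(N)) {
    ej <- numeric(N); ej[j] <- 1
    M[, j] <- inverse_dynamics(model, gen_state(t, q, u, ej),
                               external)$tau - bias
  }
  list(M = M, bias = bias)
}

#' Forward integration of the model dynamics (test support)
#'
#' Integrates `M(q) qdd = tau - bias(q, u)` with a fixed-step RK4 scheme.
#' Exists to close round-trip tests (torques -> motion -> torques); it is
#' not a simulation feature.
#'
#' @param model an `msk_model`.
#' @param q0,u0 initial coordinates and speeds.
#' @param tau_fun function of `(t, q, u)` returning generalized forces.
#' @param t_end,dt integration horizon and step (s).
#' @return data.frame with time, coordinates, speeds and accelerations.
#' @export
integrate_dynamics <- function(model, q0, u0, tau_fun, t_end, dt = 1e-3) {
  N <- n_coords(model)
  deriv <- function(t, q, u) {
    mb <- mass_matrix_bias(model, t, q, u)
    a <- solve(mb$M, tau_fun(t, q, u) - mb$bias)
    list(u = u, a = as.numeric(a))
  }
  steps <- ceiling(t_end / dt)
  out <- matrix(NA_real_, nrow = steps + 1, ncol = 1 + 3 * N)
  q <- q0; u <- u0; t <- 0
  acc0 <- deriv(t, q, u)$a
  out[1, ] <- c(t, q, u, acc0)
  for (i in seq_len(steps)) {
    k1 <- deriv(t, q, u)
    k2 <- deriv(t + dt / 2, q + dt / 2 * k1$u, u + dt / 2 * k1$a)
    k3 <- deriv(t + dt / 2, q + dt / 2 * k2$u, u + dt / 2 * k2$a)
    k4 <- deriv(t + dt, q + dt * k3$u, u + dt * k3$a)
    q <- q + dt / 6 * (k1$u + 2 * k2$u + 2 * k3$u + k4$u)
    u <- u + dt / 6 * (k1$a + 2 * k2$a + 2 * k3$a + k4$a)
    t <- t + dt
    out[i + 1, ] <- c(t, q, u, deriv(t, q, u)$a)
  }
  colnames(out) <- c("time", paste0("q_", coord_names(model)),
                     paste0("u_", coord_names(model)),
                     paste0("a_", coord_names(model)))
  as.data.frame(out)
}
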