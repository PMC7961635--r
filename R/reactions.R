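# Joint reaction load analysis: muscle tensions applied as point forces
# along their straight-line paths, then a distal-to-proximal balance —
# each joint's reaction is the inertial wrench of the distal subtree
# minus the gravity, muscle and external loads applied to it, resolved
# at the joint center, expressed in the ground frame, acting on the
# child segment.

#' Muscle path point-forces
#'
#' Each muscle under tension `f_i` pulls its attachment/via points along
#' the local path direction: the point at the proximal end of every path
#' segment is pulled toward the distal end and vice versa (equal and
#' opposite on adjoining segments, as for an ideal string).
#'
#' @param model an `msk_model`.
#' @param q coordinate vector (or [forward_kinematics()] result).
#' @param f_m named or ordered vector of muscle tensions (N), `>= 0`.
#' @return list of point loads `list(segment, point, force)` in the
#'   ground frame.
#' @export
muscle_path_forces <- function(model, q, f_m) {
  fk <- if (is.list(q) && !is.null(q$segments)) q
        else forward_kinematics(model, q)
  loads <- list()
  mn <- names(model$muscles)
  for (mi in seq_along(mn)) {
    tension <- if (!is.null(names(f_m))) f_m[[mn[mi]]] else f_m[mi]
    if (tension < 0) stop("muscle tensions must be >= 0")
    if (tension == 0) next
    path <- model$muscles[[mn[mi]]]$path
    pts <- vapply(path, function(p)
      segment_point_world(fk, p$segment, p$point), numeric(3))
    for (k in seq_len(length(path) - 1)) {
      d <- pts[, k + 1] - pts[, k]
      nd <- sqrt(sum(d^2))
      if (nd < 1e-12)
        stop("muscle '", mn[mi], "': zero-length path segment")
      u <- d / nd
      loads[[length(loads) + 1]] <- list(segment = path[[k]]$segment,
                                         point = pts[, k],
                                         force = tension * u)
      loads[[length(loads) + 1]] <- list(segment = path[[k + 1]]$segment,
                                         point = pts[, k + 1],
                                         force = -tension * u)
    }
  }
  loads
}

# ground-frame position of each joint center (first elementary element)
joint_centers <- function(model, q) {
  ch <- model$chain
  el_R <- vector("list", length(ch$elements))
  el_p <- vector("list", length(ch$elements))
  for (e in seq_along(ch$elements)) {
    el <- ch$elements[[e]]
    if (el$parent == 0) { Rp <- diag(3); pp <- c(0, 0, 0) }
    else { Rp <- el_R[[el$parent]]; pp <- el_p[[el$parent]] }
    p <- pp + as.numeric(Rp %*% el$r)
    R <- Rp
    if (el$type == "P") p <- p + as.numeric(Rp %*% el$axis) * q[el$coord]
    if (el$type == "R") R <- Rp %*% rotation_about_axis(el$axis, q[el$coord])
    el_R[[e]] <- R; el_p[[e]] <- p
  }
  centers <- list()
  for (jn in ch$joint_order) {
    # last elementary element: for a floating base this sits after the
    # translational coordinates, i.e. at the moving joint center
    els <- which(vapply(ch$elements, function(el)
      el$joint == jn && !is.na(el$coord), logical(1)))
    centers[[jn]] <- el_p[[els[length(els)]]]
  }
  centers
}

#' Joint reaction analysis
#'
#' Computes the reaction force and moment transmitted through every
#' joint, given a dynamically consistent state, solved muscle tensions
#' and external wrenches. Reactions are expressed in the ground frame at
#' the joint center, acting on the child segment. Any dynamic
#' inconsistency is not redistributed: it surfaces in the base joint's
#' reaction, mirroring the residual-force diagnostic.
#'
#' @param model an `msk_model`.
#' @param state a [gen_state()].
#' @param f_m muscle tensions (N); may be `NULL` for a muscle-less model.
#' @param external list of [external_wrench()].
#' @return data.frame of class `joint_reactions`: one row per joint with
#'   `fx, fy, fz, mx, my, mz` and the joint center coordinates.
#' @export
joint_reaction_analysis <- function(model, state, f_m = NULL,
                                    external = list()) {
  spatial <- com_kinematics(model, state)
  loads <- if (!is.null(f_m) && length(model$muscles) > 0)
    muscle_path_forces(model, state$q, f_m) else list()
  centers <- joint_centers(model, state$q)
  ch <- model$chain
  rows <- lapply(ch$joint_order, function(jn) {
    child <- model$joints[[jn]]$child
    child_el <- ch$seg_elem[[child]]
    segs <- ch$descendants[[child_el]]
    sw <- subtree_wrench(model, spatial, segs, about = centers[[jn]],
                         external = external, point_loads = loads)
    data.frame(joint = jn,
               fx = sw$force[1], fy = sw$force[2], fz = sw$force[3],
               mx = sw$moment[1], my = sw$moment[2], mz = sw$moment[3],
               px = centers[[jn]][1], py = centers[[jn]][2],
               pz = centers[[jn]][3])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("joint_reactions", class(out))
  out
}
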