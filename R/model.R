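# Rigid-body tree model: definition, validation, forward kinematics and
# center-of-mass kinematics. Internally every joint is expanded into a
# chain of elementary 1-DoF prismatic/revolute elements plus a fixed
# element carrying the child-segment frame, so the velocity/acceleration
# recursion only ever deals with two joint primitives.

JOINT_TYPES <- c(revolute = 1L, free_planar = 3L, free_spatial = 6L)

#' Construct a musculoskeletal model
#'
#' Builds and validates a rigid-body tree model from its parts. Most users
#' will call [load_model()] or [make_fixture()] instead.
#'
#' @param name model name.
#' @param segments named list; each segment has `mass` (kg), `inertia`
#'   (3x3 tensor about the COM, segment frame, kg m^2), `com` (COM offset
#'   in the segment frame, m) and optionally `endpoints`, a named list of
#'   attachment points (segment frame, m).
#' @param joints named list; each joint has `type` (one of `"revolute"`,
#'   `"free_planar"`, `"free_spatial"`), `parent`/`child` segment names
#'   (`"ground"` allowed as parent), `offset_parent`/`offset_child`
#'   (joint-center offsets in parent/child frames, m), `axis` (revolute
#'   only) and optionally `range`, a list of `c(min, max)` per coordinate.
#' @param markers named list of `list(segment, position)` entries.
#' @param imus named list of `list(segment, orientation)` entries;
#'   `orientation` is the sensor-to-segment rotation as a quaternion.
#' @param muscles named list of `list(fmax, path)` entries; `path` is an
#'   ordered list of `list(segment, point)` stops from origin to insertion.
#' @return An object of class `msk_model`.
#' @export
msk_model <- function(name, segments, joints, markers = list(),
                      imus = list(), muscles = list()) {
  model <- structure(
    list(name = name, segments = segments, joints = joints,
         markers = markers, imus = imus, muscles = muscles),
    class = "msk_model")
  model <- validate_model(model)
  model <- build_chain(model)
  model
}

validate_model <- function(model) {
  segs <- model$segments
  if (is.null(names(segs)) || any(names(segs) == ""))
    stop("segments must be a named list")
  for (nm in names(segs)) {
    s <- segs[[nm]]
    s$mass <- as.numeric(s$mass)
    if (s$mass < 0) stop("segment '", nm, "': mass must be >= 0")
    s$inertia <- as_inertia(s$inertia, nm)
    s$com <- as.numeric(s$com)
    if (length(s$com) != 3) stop("segment '", nm, "': com must be length 3")
    s$endpoints <- lapply(s$endpoints %||% list(), as.numeric)
    segs[[nm]] <- s
  }
  model$segments <- segs

  jts <- model$joints
  seg_names <- names(segs)
  children <- character(0)
  for (nm in names(jts)) {
    j <- jts[[nm]]
    if (!(j$type %in% names(JOINT_TYPES)))
      stop("joint '", nm, "': unknown type '", j$type, "'")
    if (!(j$parent %in% c("ground", seg_names)))
      stop("joint '", nm, "': unknown parent segment '", j$parent, "'")
    if (!(j$child %in% seg_names))
      stop("joint '", nm, "': unknown child segment '", j$child, "'")
    j$offset_parent <- as.numeric(j$offset_parent %||% c(0, 0, 0))
    j$offset_child <- as.numeric(j$offset_child %||% c(0, 0, 0))
    if (j$type == "revolute") {
      j$axis <- as.numeric(j$axis %||% c(0, 0, 1))
      j$axis <- j$axis / sqrt(sum(j$axis^2))
    }
    children <- c(children, j$child)
    jts[[nm]] <- j
  }
  if (anyDuplicated(children))
    stop("a segment has more than one parent joint (not a tree)")
  orphan <- setdiff(seg_names, children)
  if (length(orphan) > 0)
    stop("segments not connected to the tree: ",
         paste(orphan, collapse = ", "))
  model$joints <- jts

  for (nm in names(model$markers)) {
    m <- model$markers[[nm]]
    if (!(m$segment %in% seg_names))
      stop("marker '", nm, "': unknown segment '", m$segment, "'")
    model$markers[[nm]]$position <- as.numeric(m$position)
  }
  for (nm in names(model$imus)) {
    im <- model$imus[[nm]]
    if (!(im$segment %in% seg_names))
      stop("imu '", nm, "': unknown segment '", im$segment, "'")
    model$imus[[nm]]$orientation <-
      quat_normalize(as.numeric(im$orientation %||% c(1, 0, 0, 0)))
  }
  for (nm in names(model$muscles)) {
    mu <- model$muscles[[nm]]
    if (as.numeric(mu$fmax) <= 0) stop("muscle '", nm, "': fmax must be > 0")
    if (length(mu$path) < 2)
      stop("muscle '", nm, "': path needs >= 2 points")
    psegs <- vapply(mu$path, function(p) p$segment, character(1))
    if (!all(psegs %in% seg_names))
      stop("muscle '", nm, "': path references unknown segment")
    if (length(unique(psegs)) < 2)
      stop("muscle '", nm, "': path must touch >= 2 distinct segments")
    model$muscles[[nm]]$fmax <- as.numeric(mu$fmax)
    model$muscles[[nm]]$path <- lapply(mu$path, function(p)
      list(segment = p$segment, point = as.numeric(p$point)))
  }
  model
}

as_inertia <- function(I, nm) {
  I <- unlist(I)
  if (length(I) == 6) {
    # xx, yy, zz, xy, xz, yz
    I <- matrix(c(I[1], I[4], I[5],
                  I[4], I[2], I[6],
                  I[5], I[6], I[3]), nrow = 3)
  } else if (length(I) == 9) {
    I <- matrix(as.numeric(I), nrow = 3)
  } else stop("segment '", nm, "': inertia must have 6 or 9 entries")
  if (max(abs(I - t(I))) > 1e-9)
    stop("segment '", nm, "': inertia must be symmetric")
  ev <- eigen(I, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9)
    stop("segment '", nm, "': inertia must be positive semidefinite")
  # principal moments of a physical body satisfy the triangle inequality
  ev <- sort(pmax(ev, 0))
  if (ev[3] > ev[1] + ev[2] + 1e-9)
    stop("segment '", nm, "': principal moments violate triangle inequality")
  I
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# depth-first traversal from ground; deterministic: children visited in
# the order their joints are declared
joint_order <- function(model) {
  jts <- model$joints
  parent_of <- vapply(jts, function(j) j$parent, character(1))
  child_of <- vapply(jts, function(j) j$child, character(1))
  ordered <- character(0)
  visit <- function(seg) {
    idx <- which(parent_of == seg)
    for (i in idx) {
      jn <- names(jts)[i]
      ordered <<- c(ordered, jn)
      visit(child_of[i])
    }
  }
  visit("ground")
  if (length(ordered) != length(jts))
    stop("joint graph contains a cycle or unreachable joints")
  ordered
}

coordinate_names <- function(joint_name, type) {
  switch(type,
    revolute = joint_name,
    free_planar = paste0(joint_name, c("_tx", "_ty", "_rz")),
    free_spatial = paste0(joint_name, c("_tx", "_ty", "_tz",
                                        "_rx", "_ry", "_rz")))
}

default_range <- function(type_elem) {
  if (type_elem == "P") c(-2, 2) else c(-pi, pi)
}

build_chain <- function(model) {
  jorder <- joint_order(model)
  elements <- list()
  seg_elem <- integer(0)        # segment name -> its frame element index
  coord_names <- character(0)
  coord_elem <- integer(0)      # coordinate index -> element index
  coord_joint <- character(0)
  ranges <- list()

  elem_of_parent <- function(p) if (p == "ground") 0L else seg_elem[[p]]

  for (jn in jorder) {
    j <- model$joints[[jn]]
    pe <- elem_of_parent(j$parent)
    cn <- coordinate_names(jn, j$type)
    prim <- switch(j$type,
      revolute = list(list(type = "R", axis = j$axis)),
      free_planar = list(
        list(type = "P", axis = c(1, 0, 0)),
        list(type = "P", axis = c(0, 1, 0)),
        list(type = "R", axis = c(0, 0, 1))),
      free_spatial = list(
        list(type = "P", axis = c(1, 0, 0)),
        list(type = "P", axis = c(0, 1, 0)),
        list(type = "P", axis = c(0, 0, 1)),
        list(type = "R", axis = c(1, 0, 0)),
        list(type = "R", axis = c(0, 1, 0)),
        list(type = "R", axis = c(0, 0, 1))))
    for (k in seq_along(prim)) {
      ci <- length(coord_names) + 1L
      coord_names <- c(coord_names, cn[k])
      coord_joint <- c(coord_joint, jn)
      rng <- if (!is.null(j$range) && length(j$range) >= k)
        as.numeric(j$range[[k]]) else default_range(prim[[k]]$type)
      ranges[[cn[k]]] <- rng
      elements[[length(elements) + 1L]] <- list(
        parent = pe, r = if (k == 1) j$offset_parent else c(0, 0, 0),
        type = prim[[k]]$type, axis = prim[[k]]$axis,
        coord = ci, seg = NA_character_, joint = jn)
      coord_elem <- c(coord_elem, length(elements))
      pe <- length(elements)
    }
    # fixed element carrying the child segment frame
    elements[[length(elements) + 1L]] <- list(
      parent = pe, r = -j$offset_child, type = "F",
      axis = c(0, 0, 0), coord = NA_integer_, seg = j$child, joint = jn)
    seg_elem[[j$child]] <- length(elements)
  }

  # descendant segments of each element (segments whose root path uses it)
  n_el <- length(elements)
  desc <- vector("list", n_el)
  for (s in names(seg_elem)) {
    e <- seg_elem[[s]]
    while (e > 0) {
      desc[[e]] <- c(desc[[e]], s)
      e <- elements[[e]]$parent
    }
  }

  model$chain <- list(elements = elements, seg_elem = seg_elem,
                      coord_names = coord_names, coord_elem = coord_elem,
                      coord_joint = coord_joint, descendants = desc,
                      joint_order = jorder, ranges = ranges)
  model
}

#' Model coordinate bookkeeping
#'
#' `n_coords()` returns the number of generalized coordinates N;
#' `coord_names()` their depth-first ordering (base joint first);
#' `base_coords()`/`actuated_coords()` the indices of the floating-base
#' block and of the remaining (actuated) coordinates. The base block is
#' where residual forces surface; it is excluded from the muscle-force
#' moment balance.
#'
#' @param model an `msk_model`.
#' @return integer count, character vector, or integer index vectors.
#' @export
n_coords <- function(model) length(model$chain$coord_names)

#' @rdname n_coords
#' @export
coord_names <- function(model) model$chain$coord_names

#' @rdname n_coords
#' @export
base_coords <- function(model) {
  jn <- model$chain$joint_order[1]
  j <- model$joints[[jn]]
  if (j$parent == "ground" && j$type %in% c("free_planar", "free_spatial"))
    which(model$chain$coord_joint == jn)
  else integer(0)
}

#' @rdname n_coords
#' @export
actuated_coords <- function(model) {
  setdiff(seq_len(n_coords(model)), base_coords(model))
}

#' Total model mass
#' @param model an `msk_model`.
#' @return mass in kg.
#' @export
total_mass <- function(model) {
  sum(vapply(model$segments, function(s) s$mass, numeric(1)))
}

#' @export
print.msk_model <- function(x, ...) {
  cat("msk_model '", x$name, "': ", length(x$segments), " segments, ",
      n_coords(x), " DoF, ", length(x$markers), " markers, ",
      length(x$imus), " IMUs, ", length(x$muscles), " muscles\n", sep = "")
  invisible(x)
}

#' Load a model description file
#'
#' Reads the declarative YAML/JSON model schema: top-level keys
#' `segments`, `joints`, `markers`, `imus`, `muscles`. Lengths in m,
#' masses in kg, inertias in kg m^2 given as `[xx, yy, zz, xy, xz, yz]`.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` model file.
#' @return A validated `msk_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  if (is.null(raw$segments) || is.null(raw$joints))
    stop("model file must define 'segments' and 'joints'")
  to_named <- function(x, what) {
    if (is.null(x)) return(list())
    nms <- vapply(x, function(e) e$name %||% stop(what, " entry lacks a name"),
                  character(1))
    stats::setNames(lapply(x, function(e) e[setdiff(names(e), "name")]), nms)
  }
  segments <- to_named(raw$segments, "segment")
  segments <- lapply(segments, function(s) {
    eps <- s$endpoints
    if (!is.null(eps) && is.null(names(eps))) {
      nms <- vapply(eps, function(e) e$name %||% "endpoint", character(1))
      eps <- stats::setNames(lapply(eps, function(e) as.numeric(e$point %||% e$position)), nms)
    }
    s$endpoints <- eps
    s
  })
  joints <- to_named(raw$joints, "joint")
  markers <- to_named(raw$markers, "marker")
  imus <- to_named(raw$imus, "imu")
  muscles <- to_named(raw$muscles, "muscle")
  muscles <- lapply(muscles, function(mu) {
    mu$path <- lapply(mu$path, function(p)
      list(segment = p$segment %||% p[[1]],
           point = as.numeric(p$point %||% p[[2]])))
    mu
  })
  msk_model(name = raw$name %||% basename(path), segments = segments,
            joints = joints, markers = markers, imus = imus,
            muscles = muscles)
}

#' Forward kinematics
#'
#' Composes the joint transforms along the tree for a coordinate vector
#' `q` and maps markers and IMU frames into the ground frame.
#'
#' @param model an `msk_model`.
#' @param q numeric vector of length `n_coords(model)`; angles in rad,
#'   translations in m.
#' @return list with `segments` (per segment: rotation `R`, origin `p`,
#'   orientation quaternion `quat`), `markers` (named list of world
#'   positions) and `imus` (named list of world orientation quaternions).
#' @export
forward_kinematics <- function(model, q) {
  N <- n_coords(model)
  if (length(q) != N)
    stop("q has length ", length(q), ", expected ", N)
  ch <- model$chain
  n_el <- length(ch$elements)
  Rs <- vector("list", n_el)
  ps <- vector("list", n_el)
  for (e in seq_len(n_el)) {
    el <- ch$elements[[e]]
    if (el$parent == 0) { Rp <- diag(3); pp <- c(0, 0, 0) }
    else { Rp <- Rs[[el$parent]]; pp <- ps[[el$parent]] }
    p <- pp + as.numeric(Rp %*% el$r)
    R <- Rp
    if (el$type == "P") {
      p <- p + as.numeric(Rp %*% el$axis) * q[el$coord]
    } else if (el$type == "R") {
      R <- Rp %*% rotation_about_axis(el$axis, q[el$coord])
    }
    Rs[[e]] <- R; ps[[e]] <- p
  }
  segs <- lapply(ch$seg_elem, function(e)
    list(R = Rs[[e]], p = ps[[e]], quat = matrix_to_quat(Rs[[e]])))
  markers <- lapply(model$markers, function(m) {
    s <- segs[[m$segment]]
    as.numeric(s$p + s$R %*% m$position)
  })
  imus <- lapply(model$imus, function(im) {
    s <- segs[[im$segment]]
    matrix_to_quat(s$R %*% quat_to_matrix(im$orientation))
  })
  list(segments = segs, markers = markers, imus = imus)
}

#' Generalized state of the model
#'
#' Bundles time, coordinates and their first/second derivatives — the
#' quantity every pipeline stage consumes and produces.
#'
#' @param t time (s).
#' @param q,u,a coordinates, speeds and accelerations (length N each).
#' @param model optional `msk_model` used to check dimensions.
#' @return object of class `gen_state`.
#' @export
gen_state <- function(t, q, u = NULL, a = NULL, model = NULL) {
  q <- as.numeric(q)
  u <- if (is.null(u)) numeric(length(q)) else as.numeric(u)
  a <- if (is.null(a)) numeric(length(q)) else as.numeric(a)
  if (length(u) != length(q) || length(a) != length(q))
    stop("q, u, a must have equal lengths")
  if (!all(is.finite(c(t, q, u, a)))) stop("gen_state entries must be finite")
  if (!is.null(model) && length(q) != n_coords(model))
    stop("state dimension does not match model")
  structure(list(t = t, q = q, u = u, a = a), class = "gen_state")
}

#' Center-of-mass kinematics of every segment
#'
#' Propagates angular velocity/acceleration and COM linear
#' velocity/acceleration through the tree for a full generalized state.
#' These are the per-segment quantities entering the Newton-Euler
#' equations of motion.
#'
#' @param model an `msk_model`.
#' @param state a [gen_state()] with `q`, `u` and `a` set.
#' @return object of class `spatial_kinematics`: per segment, rotation
#'   `R`, frame origin `p`, world COM position `com`, COM velocity
#'   `v_com` and acceleration `a_com`, angular velocity `omega` and
#'   angular acceleration `alpha` (ground frame).
#' @export
com_kinematics <- function(model, state) {
  N <- n_coords(model)
  if (length(state$q) != N) stop("state dimension does not match model")
  ch <- model$chain
  n_el <- length(ch$elements)
  Rs <- vector("list", n_el); ps <- vector("list", n_el)
  vs <- vector("list", n_el); as_ <- vector("list", n_el)
  ws <- vector("list", n_el); als <- vector("list", n_el)
  q <- state$q; u <- state$u; acc <- state$a
  for (e in seq_len(n_el)) {
    el <- ch$elements[[e]]
    if (el$parent == 0) {
      Rp <- diag(3); pp <- c(0, 0, 0)
      vp <- c(0, 0, 0); ap <- c(0, 0, 0)
      wp <- c(0, 0, 0); alp <- c(0, 0, 0)
    } else {
      Rp <- Rs[[el$parent]]; pp <- ps[[el$parent]]
      vp <- vs[[el$parent]]; ap <- as_[[el$parent]]
      wp <- ws[[el$parent]]; alp <- als[[el$parent]]
    }
    p <- pp + as.numeric(Rp %*% el$r)
    R <- Rp; w <- wp; al <- alp
    if (el$type == "P") {
      z <- as.numeric(Rp %*% el$axis)
      p <- p + z * q[el$coord]
      rel <- p - pp
      v <- vp + cross3(wp, rel) + z * u[el$coord]
      a <- ap + cross3(alp, rel) + cross3(wp, cross3(wp, rel)) +
        2 * cross3(wp, z) * u[el$coord] + z * acc[el$coord]
    } else if (el$type == "R") {
      z <- as.numeric(Rp %*% el$axis)
      R <- Rp %*% rotation_about_axis(el$axis, q[el$coord])
      rel <- p - pp
      v <- vp + cross3(wp, rel)
      a <- ap + cross3(alp, rel) + cross3(wp, cross3(wp, rel))
      w <- wp + z * u[el$coord]
      al <- alp + z * acc[el$coord] + cross3(wp, z) * u[el$coord]
    } else {
      rel <- p - pp
      v <- vp + cross3(wp, rel)
      a <- ap + cross3(alp, rel) + cross3(wp, cross3(wp, rel))
    }
    Rs[[e]] <- R; ps[[e]] <- p; vs[[e]] <- v; as_[[e]] <- a
    ws[[e]] <- w; als[[e]] <- al
  }
  out <- lapply(names(ch$seg_elem), function(sn) {
    e <- ch$seg_elem[[sn]]
    s <- model$segments[[sn]]
    R <- Rs[[e]]; p <- ps[[e]]
    w <- ws[[e]]; al <- als[[e]]
    rc <- as.numeric(R %*% s$com)
    com <- p + rc
    v_com <- vs[[e]] + cross3(w, rc)
    a_com <- as_[[e]] + cross3(al, rc) + cross3(w, cross3(w, rc))
    list(R = R, p = p, com = com, v_com = v_com, a_com = a_com,
         omega = w, alpha = al)
  })
  names(out) <- names(ch$seg_elem)
  structure(list(t = state$t, segments = out), class = "spatial_kinematics")
}

# world position of a point fixed in a segment frame, given FK output
segment_point_world <- function(fk_or_spatial, segment, point) {
  s <- fk_or_spatial$segments[[segment]]
  as.numeric(s$p + s$R %*% point)
}
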