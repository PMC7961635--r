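# Muscle redundancy resolution: straight-line path geometry, moment
# arms as minus the path-length gradient, multivariate polynomial
# moment-arm approximation over each muscle's spanned coordinates, and
# per-frame static optimization of the normalized-force p-norm subject
# to the actuated moment balance and nonnegative tensions.

#' Muscle path length
#'
#' Sum of the Euclidean distances between consecutive path points mapped
#' to the ground frame.
#'
#' @param model an `msk_model`.
#' @param q coordinate vector (or a [forward_kinematics()] result).
#' @param muscle muscle name.
#' @return length (m).
#' @export
muscle_path_length <- function(model, q, muscle) {
  fk <- if (is.list(q) && !is.null(q$segments)) q
        else forward_kinematics(model, q)
  path <- model$muscles[[muscle]]$path
  pts <- vapply(path, function(p)
    segment_point_world(fk, p$segment, p$point), numeric(3))
  L <- 0
  for (k in seq_len(ncol(pts) - 1)) {
    d <- sqrt(sum((pts[, k + 1] - pts[, k])^2))
    if (d < 1e-12) stop("muscle '", muscle, "': zero-length path segment")
    L <- L + d
  }
  L
}

#' Moment-arm matrix at a configuration
#'
#' Moment arm of muscle `i` about coordinate `j` is `-d l_i / d q_j`
#' (tension convention: a positive moment arm means a pulling muscle
#' produces a positive generalized force), computed by central
#' differences of the straight-line path length.
#'
#' @param model an `msk_model`.
#' @param q coordinate vector.
#' @param h central-difference step.
#' @return matrix, coordinates x muscles (N x M).
#' @export
moment_arm_matrix <- function(model, q, h = 1e-6) {
  N <- n_coords(model)
  Mn <- names(model$muscles)
  R <- matrix(0, N, length(Mn), dimnames = list(coord_names(model), Mn))
  for (j in seq_len(N)) {
    qp <- q; qp[j] <- qp[j] + h
    qm <- q; qm[j] <- qm[j] - h
    fkp <- forward_kinematics(model, qp)
    fkm <- forward_kinematics(model, qm)
    for (mi in seq_along(Mn)) {
      R[j, mi] <- -(muscle_path_length(model, fkp, Mn[mi]) -
                    muscle_path_length(model, fkm, Mn[mi])) / (2 * h)
    }
  }
  R
}

#' Sample moment arms over a configuration grid
#'
#' @param model an `msk_model`.
#' @param q_grid matrix of configurations (rows) x coordinates.
#' @return object of class `moment_arm_samples`: array
#'   `[coordinate, muscle, sample]` plus the grid.
#' @export
sample_moment_arms <- function(model, q_grid) {
  q_grid <- as.matrix(q_grid)
  if (ncol(q_grid) != n_coords(model)) stop("grid has wrong width")
  arr <- vapply(seq_len(nrow(q_grid)), function(i)
    moment_arm_matrix(model, q_grid[i, ]),
    matrix(0, n_coords(model), length(model$muscles)))
  structure(list(samples = arr, grid = q_grid,
                 coord_names = coord_names(model),
                 muscle_names = names(model$muscles)),
            class = "moment_arm_samples")
}

#' Identify the coordinates spanned by each muscle
#'
#' Coordinate `j` is spanned by muscle `i` iff the largest sampled
#' moment-arm magnitude exceeds `eps`.
#'
#' @param samples a [sample_moment_arms()] result.
#' @param eps spanning threshold (m).
#' @return named list: per muscle, integer vector of spanned coordinate
#'   indices (possibly empty, in which case the muscle is flagged via an
#'   attribute `degenerate`).
#' @export
identify_spanned_dofs <- function(samples, eps = 1e-6) {
  arr <- samples$samples
  out <- stats::setNames(vector("list", length(samples$muscle_names)),
                         samples$muscle_names)
  degenerate <- character(0)
  for (mi in seq_along(samples$muscle_names)) {
    mx <- apply(abs(arr[, mi, , drop = FALSE]), 1, max)
    out[[mi]] <- which(mx > eps)
    if (length(out[[mi]]) == 0)
      degenerate <- c(degenerate, samples$muscle_names[mi])
  }
  attr(out, "degenerate") <- degenerate
  out
}

monomial_exponents <- function(n_var, degree) {
  grid <- do.call(expand.grid, rep(list(0:degree), n_var))
  grid <- grid[rowSums(grid) <= degree, , drop = FALSE]
  as.matrix(grid)
}

monomial_design <- function(Q, expo) {
  X <- matrix(1, nrow(Q), nrow(expo))
  for (r in seq_len(nrow(expo)))
    for (v in seq_len(ncol(expo)))
      if (expo[r, v] > 0) X[, r] <- X[, r] * Q[, v]^expo[r, v]
  X
}

#' Fit polynomial moment-arm approximations
#'
#' Per (muscle, spanned coordinate), fits a multivariate polynomial of
#' bounded total degree in that muscle's spanned coordinates by least
#' squares over the sampled grid. Entries for non-spanned coordinates
#' are structurally zero.
#'
#' @param samples a [sample_moment_arms()] result.
#' @param degree total polynomial degree (default 4).
#' @param spanned optional [identify_spanned_dofs()] result (recomputed
#'   if missing).
#' @return object of class `moment_arm_model` with per-entry
#'   coefficients and the maximum absolute fit residual.
#' @export
fit_moment_arm_polynomials <- function(samples, degree = 4,
                                       spanned = NULL) {
  if (is.null(spanned)) spanned <- identify_spanned_dofs(samples)
  fits <- list()
  max_resid <- 0
  for (mi in seq_along(samples$muscle_names)) {
    mn <- samples$muscle_names[mi]
    sp <- spanned[[mn]]
    if (length(sp) == 0) next
    expo <- monomial_exponents(length(sp), degree)
    Q <- samples$grid[, sp, drop = FALSE]
    X <- monomial_design(Q, expo)
    if (nrow(X) < ncol(X))
      stop("muscle '", mn, "': fewer samples than basis functions")
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
      stop("muscle '", mn, "': rank-deficient polynomial design matrix")
    for (j in sp) {
      y <- samples$samples[j, mi, ]
      co <- qr.coef(qrX, y)
      res <- max(abs(X %*% co - y))
      max_resid <- max(max_resid, res)
      fits[[mn]][[as.character(j)]] <-
        list(coord = j, coef = as.numeric(co), residual = res)
    }
  }
  structure(list(fits = fits, spanned = spanned, degree = degree,
                 coord_names = samples$coord_names,
                 muscle_names = samples$muscle_names,
                 max_residual = max_resid),
            class = "moment_arm_model")
}

#' Evaluate a polynomial moment-arm model
#'
#' @param mam a [fit_moment_arm_polynomials()] result.
#' @param q coordinate vector.
#' @return matrix, coordinates x muscles.
#' @export
eval_moment_arms <- function(mam, q) {
  N <- length(mam$coord_names)
  R <- matrix(0, N, length(mam$muscle_names),
              dimnames = list(mam$coord_names, mam$muscle_names))
  for (mn in names(mam$fits)) {
    sp <- mam$spanned[[mn]]
    expo <- monomial_exponents(length(sp), mam$degree)
    X <- monomial_design(matrix(q[sp], nrow = 1), expo)
    for (entry in mam$fits[[mn]])
      R[entry$coord, mn] <- sum(X * entry$coef)
  }
  R
}

#' Build a polynomial moment-arm model for a whole model
#'
#' Convenience wrapper: identifies spanned coordinates from
#' one-at-a-time coordinate sweeps, samples each muscle's moment arms on
#' a full tensor grid over its spanned coordinates (others held at the
#' default pose), and fits the polynomials.
#'
#' @param model an `msk_model`.
#' @param degree polynomial total degree.
#' @param n_grid grid points per spanned coordinate.
#' @param n_sweep sweep points per coordinate for spanning detection.
#' @return a `moment_arm_model`.
#' @export
build_moment_arm_model <- function(model, degree = 4, n_grid = 9,
                                   n_sweep = 5) {
  N <- n_coords(model)
  ranges <- model$chain$ranges
  # stage 1: one-at-a-time sweeps to find spanned coordinates
  qs <- matrix(0, 0, N)
  for (j in seq_len(N)) {
    rng <- ranges[[coord_names(model)[j]]]
    vals <- seq(rng[1], rng[2], length.out = n_sweep)
    block <- matrix(0, n_sweep, N)
    block[, j] <- vals
    qs <- rbind(qs, block)
  }
  sweep_samples <- sample_moment_arms(model, qs)
  spanned <- identify_spanned_dofs(sweep_samples)
  # stage 2: tensor grid per muscle over its spanned coordinates
  all_grid <- matrix(0, 0, N)
  for (mn in names(model$muscles)) {
    sp <- spanned[[mn]]
    if (length(sp) == 0) next
    axes <- lapply(sp, function(j) {
      rng <- ranges[[coord_names(model)[j]]]
      seq(rng[1], rng[2], length.out = n_grid)
    })
    tg <- as.matrix(do.call(expand.grid, axes))
    block <- matrix(0, nrow(tg), N)
    block[, sp] <- tg
    all_grid <- rbind(all_grid, block)
  }
  all_grid <- unique(rbind(qs, all_grid))
  samples <- sample_moment_arms(model, all_grid)
  fit_moment_arm_polynomials(samples, degree = degree, spanned = spanned)
}

# equality-constrained nonnegative QP by a primal active-set method:
# minimize 1/2 f' W f  s.t.  A f = b, f >= 0, with diagonal W > 0
qp_nonneg <- function(A, b, w, active = NULL, max_iter = 200) {
  M <- ncol(A)
  act <- if (is.null(active)) rep(FALSE, M) else active
  lam <- NULL
  for (iter in seq_len(max_iter)) {
    free <- which(!act)
    if (length(free) == 0) {
      f <- numeric(M)
      return(list(f = f, lambda = rep(0, nrow(A)), iterations = iter,
                  singular = sqrt(sum((A %*% f - b)^2)) > 1e-8 * (1 + sqrt(sum(b^2)))))
    }
    Af <- A[, free, drop = FALSE]
    dinv <- 1 / w[free]
    K <- Af %*% (dinv * t(Af))
    lam <- tryCatch(solve(K, b), error = function(e) NULL)
    if (is.null(lam)) {
      # rank-deficient balance: minimum-norm multiplier via pseudoinverse
      sv <- svd(K)
      pos <- sv$d > 1e-12 * max(sv$d, 1e-300)
      lam <- sv$v[, pos, drop = FALSE] %*%
        ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos])
    }
    f_free <- dinv * as.numeric(t(Af) %*% lam)
    if (min(f_free) < -1e-10) {
      worst <- free[which.min(f_free)]
      act[worst] <- TRUE
      next
    }
    f <- numeric(M)
    f[free] <- pmax(f_free, 0)
    if (any(act)) {
      mu <- -as.numeric(t(A[, act, drop = FALSE]) %*% lam)
      if (min(mu) < -1e-10) {
        act[which(act)[which.min(mu)]] <- FALSE
        next
      }
    }
    return(list(f = f, lambda = as.numeric(lam), iterations = iter,
                singular = FALSE))
  }
  f <- numeric(M); f[!act] <- pmax(dinv * as.numeric(t(A[, !act, drop = FALSE]) %*% lam), 0)
  list(f = f, lambda = as.numeric(lam), iterations = max_iter,
       singular = TRUE)
}

#' Resolve the muscle redundancy for one frame
#'
#' Minimizes `(1/p) sum_i (f_i / fmax_i)^p` subject to the actuated
#' moment balance `tau = R f` and `f >= 0`. The floating-base residual
#' rows must be excluded before calling (pass only actuated rows of the
#' moment-arm matrix and of the generalized forces). `p = 2` is solved
#' exactly by an active-set quadratic program; `p = 3` (or any `p > 2`)
#' by an augmented-Lagrangian bounded quasi-Newton scheme warm-started
#' from the `p = 2` solution.
#'
#' @param R moment-arm matrix, actuated coordinates x muscles.
#' @param tau actuated generalized forces (N m).
#' @param fmax maximum isometric forces (N), `> 0`.
#' @param p objective exponent (2 or 3).
#' @param warm_start optional previous solution (muscle forces).
#' @param tol moment-balance residual tolerance (relative).
#' @return object of class `muscle_forces`: `f` (N), `objective`,
#'   `residual` (balance residual norm), `iterations`, `status`
#'   (`"ok"` or `"infeasible"`).
#' @export
solve_muscle_redundancy <- function(R, tau, fmax, p = 2,
                                    warm_start = NULL, tol = 1e-6) {
  R <- as.matrix(R)
  Mn <- ncol(R)
  if (any(fmax <= 0)) stop("fmax must be > 0")
  if (length(tau) != nrow(R)) stop("tau length must match rows of R")
  if (!all(is.finite(R))) stop("moment-arm matrix must be finite")
  if (!(p %in% c(2, 3))) stop("p must be 2 or 3")
  w <- 1 / fmax^2
  active0 <- if (!is.null(warm_start)) warm_start < 1e-9 else NULL
  qp <- qp_nonneg(R, tau, w, active = active0)
  f <- qp$f
  iters <- qp$iterations
  if (p > 2) {
    # augmented Lagrangian over the p-norm objective, bounds via L-BFGS-B
    obj <- function(f) sum((f / fmax)^p) / p
    gr <- function(f) (f / fmax)^(p - 1) / fmax
    lam <- rep(0, nrow(R))
    rho <- 10 / max(1, max(abs(tau)))
    f0 <- pmax(f, 0)
    r_prev <- Inf
    for (outer in 1:40) {
      al <- function(f) obj(f) + sum(lam * (R %*% f - tau)) +
        rho / 2 * sum((R %*% f - tau)^2)
      gal <- function(f) gr(f) + as.numeric(t(R) %*%
        (lam + rho * (R %*% f - tau)))
      op <- stats::optim(f0, al, gal, method = "L-BFGS-B",
                         lower = rep(0, Mn),
                         control = list(maxit = 500, factr = 1e1,
                                        pgtol = 1e-14))
      f0 <- op$par
      r <- as.numeric(R %*% f0 - tau)
      rn <- sqrt(sum(r^2))
      iters <- iters + op$counts[1]
      if (rn <= 1e-10 * (1 + sqrt(sum(tau^2)))) break
      lam <- lam + rho * r
      if (rn > 0.25 * r_prev) rho <- rho * 10
      r_prev <- rn
    }
    f <- f0
  }
  resid <- sqrt(sum((R %*% f - tau)^2))
  status <- "ok"
  if (resid > tol * (1 + sqrt(sum(tau^2)))) {
    # infeasible balance: least-squares fallback with nonnegativity
    ls <- stats::optim(pmax(f, 0),
                       function(f) sum((R %*% f - tau)^2),
                       function(f) 2 * as.numeric(t(R) %*% (R %*% f - tau)),
                       method = "L-BFGS-B", lower = rep(0, Mn),
                       control = list(maxit = 1000, factr = 1e1))
    f <- ls$par
    resid <- sqrt(sum((R %*% f - tau)^2))
    status <- "infeasible"
  }
  structure(list(f = stats::setNames(f, colnames(R)),
                 objective = sum((f / fmax)^p) / p,
                 residual = resid, iterations = iters,
                 status = status, p = p),
            class = "muscle_forces")
}

#' Solve muscle forces over a kinematics + generalized-forces stream
#'
#' Per-frame static optimization with the polynomial moment-arm model
#' and warm starting from the previous frame's solution.
#'
#' @param model an `msk_model`.
#' @param states list of [gen_state()].
#' @param gen_forces list of `generalized_forces` (same length).
#' @param mam a `moment_arm_model` (built if `NULL`).
#' @param p objective exponent.
#' @return list with `forces` (data.frame time x muscles), `objective`,
#'   `residual` and `status` per frame.
#' @export
solve_muscles_stream <- function(model, states, gen_forces, mam = NULL,
                                 p = 2) {
  if (is.null(mam)) mam <- build_moment_arm_model(model)
  act <- actuated_coords(model)
  fmax <- vapply(model$muscles, function(m) m$fmax, numeric(1))
  warm <- NULL
  n <- length(states)
  Fm <- matrix(NA_real_, n, length(fmax),
               dimnames = list(NULL, names(model$muscles)))
  meta <- data.frame(time = numeric(n), objective = numeric(n),
                     residual = numeric(n), status = character(n))
  for (i in seq_len(n)) {
    R <- eval_moment_arms(mam, states[[i]]$q)[act, , drop = FALSE]
    sol <- solve_muscle_redundancy(R, gen_forces[[i]]$tau[act], fmax,
                                   p = p, warm_start = warm)
    warm <- sol$f
    Fm[i, ] <- sol$f
    meta$time[i] <- states[[i]]$t
    meta$objective[i] <- sol$objective
    meta$residual[i] <- sol$residual
    meta$status[i] <- sol$status
  }
  list(forces = cbind(data.frame(time = meta$time), as.data.frame(Fm)),
       meta = meta, moment_arm_model = mam)
}
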