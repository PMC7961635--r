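test_that("moment arms follow pin-joint geometry", {
  w <- make_fixture("planar_walker")
  R <- moment_arm_matrix(w, numeric(9))
  cn <- coord_names(w)
  # a muscle that does not cross a joint has zero moment arm there
  expect_lt(max(abs(R[cn == "knee_r", "hip_flex_r"])), 1e-9)
  expect_lt(max(abs(R[cn == "hip_l", "hip_flex_r"])), 1e-9)
  # antagonist pair per joint with opposite signs at the default pose
  for (j in c("hip_r", "knee_r", "ankle_r", "hip_l", "knee_l",
              "ankle_l")) {
    arms <- R[cn == j, ]
    arms <- arms[abs(arms) > 1e-6]
    expect_length(arms, 2)
    expect_lt(prod(sign(arms)), 0)
  }
})

test_that("a straight muscle over a pin has |r| equal to the
           perpendicular distance", {
  # two-point muscle crossing a single pin at perpendicular distance d:
  # both attachment points at x = d on either side of the joint
  d <- 0.04
  m <- msk_model(
    name = "pin",
    segments = list(
      up = list(mass = 1, inertia = diag(0.01, 3), com = c(0, 0.1, 0)),
      lo = list(mass = 1, inertia = diag(0.01, 3), com = c(0, -0.1, 0))),
    joints = list(
      root = list(type = "revolute", parent = "ground", child = "up",
                  axis = c(0, 0, 1)),
      pin = list(type = "revolute", parent = "up", child = "lo",
                 offset_parent = c(0, -0.2, 0), axis = c(0, 0, 1),
                 range = list(c(-1, 1)))),
    muscles = list(
      mm = list(fmax = 100, path = list(
        list(segment = "up", point = c(d, -0.1, 0)),
        list(segment = "lo", point = c(d, -0.1, 0))))))
  R <- moment_arm_matrix(m, c(0, 0))
  expect_equal(abs(R["pin", "mm"]), d, tolerance = 1e-7)
  expect_lt(abs(R["root", "mm"]), 1e-9)
})

test_that("finite-difference moment arms match the analytic path-length
           derivative on the walker hip flexor", {
  w <- make_fixture("planar_walker")
  # analytic oracle: 2-point muscle from pelvis to thigh_r across the
  # hip pin; path length as an explicit function of the hip angle
  mu <- w$muscles$hip_flex_r
  a_local <- mu$path[[1]]$point   # pelvis frame
  b_local <- mu$path[[2]]$point   # thigh frame
  hip <- w$joints$hip_r$offset_parent
  ell <- function(q) {
    # pelvis at identity; thigh rotated by q about z at the hip center
    b_world <- hip + as.numeric(rotation_about_axis(c(0, 0, 1), q) %*%
                                b_local)
    sqrt(sum((b_world - a_local)^2))
  }
  for (q_hip in c(-0.6, -0.2, 0.3, 0.8)) {
    q <- numeric(9); q[4] <- q_hip
    R <- moment_arm_matrix(w, q)
    dd <- 1e-7
    analytic <- -(ell(q_hip + dd) - ell(q_hip - dd)) / (2 * dd)
    # the analytic oracle itself uses a tighter step; agreement to 1e-6
    expect_lt(abs(R["hip_r", "hip_flex_r"] - analytic), 1e-6)
  }
})

test_that("spanned-coordinate identification isolates crossed joints", {
  w <- make_fixture("planar_walker")
  qs <- matrix(0, 11, 9)
  set.seed(3)
  for (i in 2:11) qs[i, ] <- runif(9, -0.8, 0.8)
  samples <- sample_moment_arms(w, qs)
  spanned <- identify_spanned_dofs(samples)
  cn <- coord_names(w)
  expect_identical(cn[spanned$hip_flex_r], "hip_r")
  expect_identical(cn[spanned$knee_flex_l], "knee_l")
  expect_length(attr(spanned, "degenerate"), 0)
})

test_that("polynomial fitting recovers exact polynomial moment arms", {
  # synthetic samples with known polynomial structure
  grid <- expand.grid(q1 = seq(-1, 1, length.out = 9),
                      q2 = seq(-1, 1, length.out = 9))
  r_true <- function(q1, q2) 0.05 - 0.01 * q1 + 0.02 * q1 * q2 - 0.015 * q2^2
  arr <- array(0, dim = c(2, 1, nrow(grid)))
  arr[1, 1, ] <- r_true(grid$q1, grid$q2)
  arr[2, 1, ] <- 0.03   # constant arm about the second coordinate
  samples <- structure(list(samples = arr, grid = as.matrix(grid),
                            coord_names = c("q1", "q2"),
                            muscle_names = "m"),
                       class = "moment_arm_samples")
  mam <- fit_moment_arm_polynomials(samples, degree = 2)
  expect_lt(mam$max_residual, 1e-10)
  R_hat <- eval_moment_arms(mam, c(0.37, -0.58))
  expect_equal(R_hat[1, 1], r_true(0.37, -0.58), tolerance = 1e-10)
  expect_equal(R_hat[2, 1], 0.03, tolerance = 1e-12)
  # degree-0 case: constant recovered exactly
  mam0 <- fit_moment_arm_polynomials(samples, degree = 0)
  expect_equal(eval_moment_arms(mam0, c(0, 0))[2, 1], 0.03,
               tolerance = 1e-12)
})

test_that("fitted walker model matches direct moment arms", {
  w <- make_fixture("planar_walker")
  mam <- build_moment_arm_model(w)
  set.seed(9)
  for (i in 1:5) {
    q <- runif(9, -0.8, 0.8)
    expect_lt(max(abs(eval_moment_arms(mam, q) -
                      moment_arm_matrix(w, q))), 5e-3)
  }
})

test_that("redundancy solver reproduces KKT closed forms", {
  # two identical agonists split the moment evenly
  R <- matrix(c(0.05, 0.05), nrow = 1)
  s <- solve_muscle_redundancy(R, 50, c(1000, 1000), p = 2)
  expect_equal(unname(s$f), c(500, 500), tolerance = 1e-6)
  expect_identical(s$status, "ok")
  expect_lt(s$residual, 1e-6 * 51)
  # agonist-antagonist: antagonist silent
  s2 <- solve_muscle_redundancy(matrix(c(0.05, -0.05), nrow = 1), 50,
                                c(1000, 1000), p = 2)
  expect_equal(unname(s2$f), c(1000, 0), tolerance = 1e-6)
  # unequal strengths: f_i = tau r_i F_i^2 / sum(r_k^2 F_k^2)
  r <- c(0.04, 0.06); F <- c(800, 1500); tau <- 30
  s3 <- solve_muscle_redundancy(matrix(r, nrow = 1), tau, F, p = 2)
  f_kkt <- tau * r * F^2 / sum(r^2 * F^2)
  expect_lt(max(abs(s3$f - f_kkt)), 1e-6)
  # zero moment: zero force
  s0 <- solve_muscle_redundancy(matrix(r, nrow = 1), 0, F, p = 2)
  expect_equal(unname(s0$f), c(0, 0))
  expect_equal(s0$objective, 0)
})

test_that("p = 3 solution beats a dense feasible grid", {
  R <- matrix(c(0.05, 0.03, 0.06), nrow = 1)
  F <- c(1000, 800, 1200); tau <- 40
  s <- solve_muscle_redundancy(R, tau, F, p = 3)
  expect_lt(s$residual, 1e-6 * 41)
  f1 <- seq(0, 800, length.out = 1000)
  f2 <- seq(0, 1334, length.out = 1000)
  g <- expand.grid(f1 = f1, f2 = f2)
  f3 <- (tau - R[1] * g$f1 - R[2] * g$f2) / R[3]
  ok <- f3 >= 0
  obj <- ((g$f1 / F[1])^3 + (g$f2 / F[2])^3 + (f3 / F[3])^3) / 3
  expect_lte(s$objective, min(obj[ok]) + 1e-8)
})

test_that("warm starting and fmax scaling leave the optimum unchanged", {
  set.seed(25)
  n_dof <- 3; n_mus <- 8
  for (trial in 1:20) {
    R <- matrix(runif(n_dof * n_mus, -0.06, 0.06), n_dof)
    F <- runif(n_mus, 500, 2000)
    f_feas <- runif(n_mus, 0, 400)
    tau <- as.numeric(R %*% f_feas)  # feasible by construction
    cold <- solve_muscle_redundancy(R, tau, F, p = 2)
    warm <- solve_muscle_redundancy(R, tau, F, p = 2,
                                    warm_start = cold$f +
                                      runif(n_mus, 0, 1))
    expect_lt(max(abs(cold$f - warm$f)) / max(1, max(abs(cold$f))), 1e-5)
    # doubling fmax: same balance, objective shrinks
    big <- solve_muscle_redundancy(R, tau, 2 * F, p = 2)
    expect_lt(big$residual, 1e-6 * (1 + sqrt(sum(tau^2))))
    expect_lte(big$objective, cold$objective + 1e-12)
  }
})

test_that("infeasible moment demands are flagged with a residual", {
  # one muscle pulling the wrong way cannot produce a negative moment
  s <- solve_muscle_redundancy(matrix(0.05, 1, 1), -10, 1000, p = 2)
  expect_identical(s$status, "infeasible")
  expect_gt(s$residual, 1)
  expect_gte(min(s$f), -1e-9)
})
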