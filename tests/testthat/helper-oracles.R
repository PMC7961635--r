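# Shared oracles and small fixtures used across test files.

# Closed-form equations of motion of the bundled double pendulum
# (two thin rods, y-up, angles measured from the downward vertical,
# positive toward +x), derived independently from the Lagrangian:
#   tau = M(q) qdd + c(q, qd) + g(q)
# Inertias about each rod's COM enter as I = m L^2 / 12 plus the small
# regularization used by the fixture's rod_inertia().
lagrangian_double_pendulum <- function(q, u, a, m1 = 1, L1 = 1,
                                       m2 = 0.8, L2 = 0.8,
                                       g = 9.80665) {
  l1 <- L1 / 2; l2 <- L2 / 2
  I1 <- m1 * L1^2 / 12
  I2 <- m2 * L2^2 / 12
  q1 <- q[1]; q2 <- q[2]
  M11 <- I1 + I2 + m1 * l1^2 +
    m2 * (L1^2 + l2^2 + 2 * L1 * l2 * cos(q2))
  M12 <- I2 + m2 * (l2^2 + L1 * l2 * cos(q2))
  M22 <- I2 + m2 * l2^2
  h <- -m2 * L1 * l2 * sin(q2)
  c1 <- h * (2 * u[1] * u[2] + u[2]^2)
  c2 <- -h * u[1]^2
  g1 <- (m1 * l1 + m2 * L1) * g * sin(q1) + m2 * l2 * g * sin(q1 + q2)
  g2 <- m2 * l2 * g * sin(q1 + q2)
  c(M11 * a[1] + M12 * a[2] + c1 + g1,
    M12 * a[1] + M22 * a[2] + c2 + g2)
}

# A one-segment free body with four non-coplanar markers: the smallest
# model on which Procrustes marker completion is exercised.
four_marker_body <- function() {
  msk_model(
    name = "block",
    segments = list(
      block = list(mass = 2, inertia = diag(0.02, 3), com = c(0, 0, 0))),
    joints = list(
      base = list(type = "free_spatial", parent = "ground",
                  child = "block")),
    markers = list(
      a = list(segment = "block", position = c(0.1, 0, 0)),
      b = list(segment = "block", position = c(0, 0.1, 0)),
      c = list(segment = "block", position = c(0, 0, 0.1)),
      d = list(segment = "block", position = c(0.1, 0.1, 0.1))))
}

rel_err <- function(x, ref) max(abs(x - ref)) / max(1e-12, max(abs(ref)))
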