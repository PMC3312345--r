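test_that("one-target control has the LQ form and is noise independent", {
  cfg <- one_target_cfg()
  p <- standard_params(alpha = 0)
  expect_equal(one_target_control(0.25, 1, p, cfg), -0.125)
  expect_equal(one_target_control(0, 1.7, p, cfg), 0)  # on target -> no control

  # exact nu-independence across the experimental amplitudes
  pts <- expand.grid(y = c(-0.4, 0.1, 0.45), t = c(0.6, 1.5, 2.7))
  p2 <- standard_params(alpha = 0.3)
  u_ref <- one_target_control(pts$y, pts$t, p2, one_target_cfg(nu = 0.009))
  for (nu in c(0.04, 0.08)) {
    expect_identical(one_target_control(pts$y, pts$t, p2, one_target_cfg(nu = nu)),
                     u_ref)
  }
  expect_error(one_target_control(0, 3, p2, cfg), "t < T")
})

test_that("cost-to-go gradient and curvature match independent oracles", {
  cfg <- one_target_cfg(nu = 0.04)
  p <- standard_params(alpha = 0.4)
  # finite-difference gradient: u = -(1/R) dJ/dy at 20 random states
  pts <- withr::with_seed(2, data.frame(y = runif(20, -0.8, 0.8),
                                        t = runif(20, 0, 2.9)))
  h <- 1e-6
  grad <- (one_target_cost_to_go(pts$y + h, pts$t, p, cfg) -
           one_target_cost_to_go(pts$y - h, pts$t, p, cfg)) / (2 * h)
  expect_equal(-grad / p$R, one_target_control(pts$y, pts$t, p, cfg),
               tolerance = 1e-6)
  # end condition: J(y, T) equals the end cost
  ys <- seq(-0.5, 0.5, by = 0.1)
  expect_equal(one_target_cost_to_go(ys, 3, p, cfg),
               p$R * ys^2 / (2 * p$alpha) +
                 0)  # constant term vanishes at t = T
  expect_equal(one_target_cost_to_go(0, 3, p, cfg), 0)

  # curvature R/(alpha + T - t) vs backward Riccati integration dP/dt = P^2/R
  skip_if_not_installed("deSolve")
  # backward time s = T - t: dP/ds = -P^2/R from P(s=0) = end_weight = R/alpha
  sol <- deSolve::ode(y = c(P = p$R / p$alpha), times = seq(0, 3, by = 0.01),
                      func = function(s, state, parms) list(-state[["P"]]^2 / p$R))
  curv <- p$R / (p$alpha + sol[, "time"])
  expect_equal(as.numeric(sol[, "P"]), as.numeric(curv), tolerance = 1e-6)
})

test_that("two-target control is symmetric, blends per-target controls, and matches quadrature", {
  cfg <- two_target_cfg(nu = 0.04)
  p <- standard_params(alpha = 0.3)
  expect_equal(two_target_control(0, 1, p, cfg), 0)  # midpoint: symmetry
  ys <- c(0.05, 0.15, 0.3, 0.45, 0.6)
  for (t in c(0.3, 1, 2.5)) {
    expect_equal(two_target_control(-ys, t, p, cfg),
                 -two_target_control(ys, t, p, cfg))
  }
  # vectorized over time as well as position (the fitting path relies on it)
  expect_equal(two_target_control(c(0.1, 0.1, -0.3), c(0.5, 2, 1.2), p, cfg),
               c(two_target_control(0.1, 0.5, p, cfg),
                 two_target_control(0.1, 2, p, cfg),
                 two_target_control(-0.3, 1.2, p, cfg)))
  w <- two_target_responsibilities(c(-0.4, 0, 0.2, 0.45), 1, p, cfg)
  expect_true(all(w >= 0 & w <= 1))
  expect_equal(rowSums(w), rep(1, 4))
  expect_gt(w[4, 2], 0.99)  # near the upper target the upper basin dominates

  # desirability against adaptive quadrature of the defining integral
  lam <- p$R * cfg$nu
  phi <- function(x) p$R * pmin((x - 0.5)^2, (x + 0.5)^2) / (2 * p$alpha)
  for (y0 in c(-0.3, 0, 0.2)) {
    for (t0 in c(0.5, 2)) {
      s2 <- cfg$nu * (3 - t0)
      q <- integrate(function(x) dnorm(x, y0, sqrt(s2)) * exp(-phi(x) / lam),
                     -Inf, Inf, rel.tol = 1e-10)$value
      expect_equal(two_target_log_psi(y0, t0, p, cfg), log(q), tolerance = 1e-7)
    }
  }
  # and the control is nu * d(log psi)/dy
  h <- 1e-5
  for (y0 in c(-0.2, 0.1, 0.35)) {
    num <- cfg$nu * (two_target_log_psi(y0 + h, 1, p, cfg) -
                     two_target_log_psi(y0 - h, 1, p, cfg)) / (2 * h)
    expect_equal(two_target_control(y0, 1, p, cfg), num, tolerance = 1e-6)
  }
  expect_error(two_target_control(0.1, 1, p, two_target_cfg(nu = 0)),
               "deterministic")
  expect_error(two_target_control(0.1, 1, p, one_target_cfg()), "two-target")
})

test_that("two-target control converges to the nearest-target rule as nu -> 0", {
  p <- standard_params(alpha = 0.3)
  y0 <- 0.2; t0 <- 1
  cfg0 <- two_target_cfg(nu = 0)
  u_det <- two_target_control_deterministic(y0, t0, p, cfg0)
  gaps <- vapply(c(0.04, 0.004, 4e-4), function(nu) {
    abs(two_target_control(y0, t0, p, two_target_cfg(nu = nu)) - u_det)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))   # monotone approach on the nu ladder
  expect_lt(gaps[3], 1e-6)
})

test_that("noiseless two-target strategy is a straight constant-control path", {
  cfg <- two_target_cfg(nu = 0)
  cfg$reaction_time <- 0; cfg$delay <- 0   # respond from the first frame
  p <- standard_params(alpha = 0)
  expect_gt(two_target_control_deterministic(0.1, 0, p, cfg), 0)  # aims up
  expect_gt(two_target_control_deterministic(0, 0, p, cfg), 0)    # tie -> upper
  expect_lt(two_target_control_deterministic(-0.1, 0, p, cfg), 0)
  pol <- function(y, t) two_target_control_deterministic(y, t, p, cfg)
  tr <- simulate_trial(pol, cfg, 0.1)
  u_active <- tr$u[-length(tr$u)]
  expect_lt(diff(range(u_active)), 1e-10)          # constant control
  expect_equal(u_active[1], (0.5 - 0.1) / 3, tolerance = 1e-12)
  expect_equal(tr$y[226], 0.5, tolerance = 1e-10)  # lands on the nearest target
})

test_that("early midpoint pull under the standard model is small (symmetry breaking)", {
  cfg <- two_target_cfg(nu = 0.08)
  p <- standard_params(alpha = 0.3)
  ys <- seq(0.01, 0.1, by = 0.01)
  early <- max(abs(vapply(c(0.1, 0.3, 0.49), function(t) {
    max(abs(two_target_control(ys, t, p, cfg)))
  }, numeric(1))))
  late <- max(abs(two_target_control(ys, 2.7, p, cfg)))
  expect_lt(early / late, 0.1)
  # and the early pull really is toward the midpoint (negative for y > 0)
  expect_lt(two_target_control(0.05, 0.1, p, cfg), 0)
})
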