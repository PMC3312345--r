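test_that("position cost rate is zero on target, saturating, locally quadratic", {
  cfg <- one_target_cfg()
  p <- extended_params(alpha = 0.3, pos_weight = 2, pos_steepness = 4)
  expect_equal(position_cost_rate(0, p, cfg), 0)
  expect_equal(position_cost_rate(50, p, cfg), p$pos_weight, tolerance = 1e-12)
  expect_lt(position_cost_rate(0.9, p, cfg), p$pos_weight)
  # small-deviation Taylor expansion: pos_weight * steepness^2 * (y - mu)^2
  for (d in c(1e-3, -1e-3, 5e-4)) {
    expect_equal(position_cost_rate(d, p, cfg),
                 p$pos_weight * p$pos_steepness^2 * d^2, tolerance = 1e-4)
  }
  # two-target form vanishes at both targets and is even
  cfg2 <- two_target_cfg()
  expect_equal(position_cost_rate(c(-0.5, 0.5), p, cfg2), c(0, 0))
  ys <- seq(-1, 1, by = 0.05)
  expect_equal(position_cost_rate(ys, p, cfg2), position_cost_rate(-ys, p, cfg2))
  expect_true(all(position_cost_rate(ys, p, cfg2) <= p$pos_weight))
})

test_that("backward recursion with zero position cost reproduces the LQ control", {
  cfg <- one_target_cfg(nu = 0.04)
  p0 <- extended_params(alpha = 0.3, pos_weight = 0, pos_steepness = 1)
  g <- solve_backward(p0, cfg, dy = 0.005)
  sp <- standard_params(alpha = 0.3)
  # interior: at least a diffusion length + kernel radius away from the screen
  # edge, where the bounded-domain solution tracks the unbounded closed form
  margin <- sqrt(cfg$nu * cfg$T_final) + 6 * sqrt(cfg$nu * cfg$dt)
  iy <- which(g$y_grid >= -1 + margin & g$y_grid <= 1 - margin)
  kt <- seq_len(length(g$t_grid) - 1)
  err <- max(vapply(kt, function(k) {
    max(abs(g$u[iy, k] - one_target_control(g$y_grid[iy], g$t_grid[k], sp, cfg)))
  }, numeric(1)))
  umax <- max(abs(g$u[iy, kt]))
  expect_lt(err, 1e-3 * umax)
})

test_that("recursion refuses an under-resolved kernel and suggests a step", {
  cfg <- one_target_cfg(nu = 0.009)
  p <- extended_params(alpha = 0.3, pos_weight = 1)
  expect_error(solve_backward(p, cfg, dy = 0.01), "under-resolved")
  expect_silent(g <- solve_backward(p, cfg, dy = 0.005))
})

test_that("flat end cost with zero position cost conserves desirability and control", {
  cfg <- one_target_cfg(nu = 0.04)
  p0 <- extended_params(alpha = 0.3, pos_weight = 0)
  g <- solve_backward(p0, cfg, dy = 0.005, end_cost = "flat")
  expect_lt(max(abs(g$log_psi)), 1e-12)   # psi == 1 everywhere (stochastic rows)
  expect_lt(max(abs(g$u)), 1e-10)         # nothing to optimize
})

test_that("policy extraction matches a higher-order stencil and respects symmetry", {
  cfg <- two_target_cfg(nu = 0.04)
  p <- extended_params(alpha = 0.3, pos_weight = 2, pos_steepness = 4)
  g <- solve_backward(p, cfg, dy = 0.005)
  ny <- length(g$y_grid)
  # two-target task: u(t, -y) = -u(t, y) on the grid
  expect_equal(g$u[ny:1, ], -g$u, tolerance = 1e-9)
  # 5-point stencil on log psi agrees with the central difference away from
  # the terminal end-cost kink at the midpoint
  i <- 3:(ny - 2)
  lp <- g$log_psi
  u5 <- cfg$nu * (-lp[i + 2, ] + 8 * lp[i + 1, ] - 8 * lp[i - 1, ] + lp[i - 2, ]) /
    (12 * g$dy)
  kt <- which(g$t_grid <= 2.9)
  expect_lt(max(abs(u5[, kt] - g$u[i, kt])) / max(abs(g$u[i, kt])), 1e-2)
  # on a quadratic log-desirability (one-target, zero position cost) the two
  # stencils are exact and must agree to rounding
  g1 <- solve_backward(extended_params(alpha = 0.3, pos_weight = 0),
                       one_target_cfg(nu = 0.04), dy = 0.005)
  lp1 <- g1$log_psi
  n1 <- length(g1$y_grid); j <- 3:(n1 - 2)
  u5a <- 0.04 * (-lp1[j + 2, ] + 8 * lp1[j + 1, ] - 8 * lp1[j - 1, ] + lp1[j - 2, ]) /
    (12 * g1$dy)
  # away from the screen-edge boundary layer the quadratic is represented
  # exactly and the stencils agree to rounding
  jb <- which(abs(g1$y_grid[j]) <= 0.6)
  expect_lt(max(abs(u5a[jb, ] - g1$u[j, ][jb, ])) / max(abs(g1$u[j, ])), 1e-6)
  # non-finite value entries are reported with their grid location
  g_bad <- g
  g_bad$log_psi[10, 5] <- NaN
  expect_error(extract_policy(g_bad, p, cfg), "non-finite value")
})

test_that("halving the grid step barely changes the extracted control", {
  cfg <- one_target_cfg(nu = 0.04)
  p <- extended_params(alpha = 0.3, pos_weight = 2, pos_steepness = 4)
  g1 <- solve_backward(p, cfg, dy = 0.005)
  g2 <- solve_backward(p, cfg, dy = 0.0025)
  pol1 <- policy_fun(g1); pol2 <- policy_fun(g2)
  probes <- withr::with_seed(4, data.frame(y = runif(100, -0.6, 0.6),
                                           t = runif(100, 0, 2.8)))
  d <- abs(pol1(probes$y, probes$t) - pol2(probes$y, probes$t))
  expect_lt(max(d), 1e-3)
})

test_that("noiseless Bellman induction reproduces the LQ policy at zero position cost", {
  cfg <- one_target_cfg(nu = 0)
  p0 <- extended_params(alpha = 0.3, pos_weight = 0, pos_steepness = 1)
  g <- solve_backward_deterministic(p0, cfg)
  sp <- standard_params(alpha = 0.3)
  iy <- which(abs(g$y_grid) <= 0.8)
  kt <- which(g$t_grid <= 2.5)
  err <- max(vapply(kt, function(k) {
    max(abs(g$u[iy, k] - one_target_control(g$y_grid[iy], g$t_grid[k], sp, cfg)))
  }, numeric(1)))
  expect_lt(err, 0.02)  # du/2 plus interpolation slope error
  # J >= 0 everywhere and the terminal slice is exactly the end cost
  expect_true(all(g$J >= 0))
  expect_equal(g$J[, ncol(g$J)], g$y_grid^2 / (2 * 0.3))
})

test_that("position cost forces early arrival, monotonically in its weight", {
  cfg <- one_target_cfg(nu = 0)
  cfg$start_range <- 0.4
  arrival <- function(pw) {
    p <- extended_params(alpha = 0.3, pos_weight = pw, pos_steepness = 4)
    g <- solve_backward_deterministic(p, cfg)
    pol <- policy_fun(g)
    tr <- simulate_trial(pol, cfg, 0.4)
    hit <- which(abs(tr$y) <= 0.02)
    if (length(hit) == 0) Inf else tr$t[hit[1]]
  }
  times <- vapply(c(0, 0.5, 1, 2, 4), arrival, numeric(1))
  expect_true(all(diff(times) <= 1e-9))          # non-increasing in pos_weight
  expect_true(all(times[-1] < 3))                # strictly before the deadline
  expect_gt(times[1], 2.8)                       # standard policy: only near T
  # large position cost: on target well before 2 s
  expect_lt(times[5], 2.0)
})

test_that("position cost removes the early midpoint pull in the two-target task", {
  cfg <- two_target_cfg(nu = 0.08)
  p <- extended_params(alpha = 0.3, pos_weight = 2, pos_steepness = 4)
  g <- solve_backward(p, cfg, dy = 0.005)
  iy <- which(g$y_grid > 0.01 & g$y_grid < 0.49)
  kt <- which(g$t_grid >= 0.5 & g$t_grid < 3)
  # between midpoint and upper target, control never points back to the midpoint
  expect_gt(min(g$u[iy, kt]), -1e-8)
})

test_that("deterministic solver warns when the control grid cannot hit the optimum", {
  cfg <- one_target_cfg(nu = 0)
  p <- extended_params(alpha = 0.001, pos_weight = 0, pos_steepness = 1)
  expect_warning(solve_backward_deterministic(p, cfg, du = 0.05),
                 "cannot represent")
})
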