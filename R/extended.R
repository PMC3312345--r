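#' Parameters of the extended cost model
#'
#' The extended model adds to the standard cost a *time-integrated position
#' cost*: a running penalty on the distance between ball and target that is
#' zero at the target, grows approximately quadratically for small deviations,
#' and saturates at `pos_weight` for large ones (outliers are discounted, in
#' line with the subquadratic error sensitivity reported for sensorimotor
#' learning). With `pos_weight = 0` the model reduces exactly to the standard
#' model; with `pos_weight > 0` it pays to reach the target well before the
#' final time and then hold position.
#'
#' @param alpha ratio `R/end_weight` in seconds (as in [standard_params()]).
#' @param pos_weight scale of the position cost rate (cost per second at
#'   saturation), `>= 0`.
#' @param pos_steepness inverse length scale of the saturating penalty; the
#'   cost is approximately `pos_weight * pos_steepness^2 * (y - mu)^2` near the
#'   target.
#' @param R control-cost weight (fixed at 1 by convention).
#' @return object of class `"extended_params"`.
#' @export
extended_params <- function(alpha = 0.3, pos_weight = 1, pos_steepness = 4, R = 1) {
  stopifnot(R > 0, alpha >= 0, pos_weight >= 0, pos_steepness > 0)
  structure(list(R = R, alpha = alpha, pos_weight = pos_weight,
                 pos_steepness = pos_steepness),
            class = "extended_params")
}

#' Position cost rate
#'
#' One-target: `pos_weight * tanh(pos_steepness*(y - mu))^2`. Two-target:
#' the product `pos_weight * tanh(k*(y - mu1))^2 * tanh(k*(y - mu2))^2`, which
#' vanishes at both targets, is bounded by `pos_weight`, locally quadratic near
#' each target, and even under the task's midline symmetry.
#'
#' @param y position (vectorized).
#' @param params an [extended_params()].
#' @param config a [task_config()].
#' @return cost rate (cost per second).
#' @export
position_cost_rate <- function(y, params, config) {
  k <- params$pos_steepness
  if (config$task_kind == "one_target") {
    params$pos_weight * tanh(k * (y - config$targets[1]))^2
  } else {
    params$pos_weight *
      tanh(k * (y - config$targets[1]))^2 *
      tanh(k * (y - config$targets[2]))^2
  }
}

# end cost phi(y) at the final time; alpha > 0 required (soft constraint)
end_cost_fun <- function(y, R, alpha, config) {
  if (config$task_kind == "one_target") {
    R * (y - config$targets[1])^2 / (2 * alpha)
  } else {
    d2 <- pmin((y - config$targets[1])^2, (y - config$targets[2])^2)
    R * d2 / (2 * alpha)
  }
}

make_y_grid <- function(config, dy) {
  lo <- config$y_bounds[1]; hi <- config$y_bounds[2]
  n <- max(2L, as.integer(round((hi - lo) / dy)))
  seq(lo, hi, length.out = n + 1L)
}

#' Solve the extended model by backward desirability recursion
#'
#' Exponentiating the cost-to-go, `psi = exp(-J/lambda)` with
#' `lambda = R * nu`, turns the Bellman equation for this control-affine,
#' quadratic-control problem into a *linear* backward recursion: each time
#' slice is the Gaussian propagation (one uncontrolled diffusion step) of the
#' next slice, multiplied by `exp(-position_cost * dt / lambda)`. The
#' recursion runs on a regular position grid at the experiment's own frame
#' interval `dt`, entirely in the log domain; the transition kernel is
#' truncated at ±6 standard deviations and renormalized per row, so it is
#' exactly stochastic. Controls are then extracted with [extract_policy()].
#'
#' @param params an [extended_params()] with `alpha > 0`.
#' @param config a [task_config()] with `nu > 0`.
#' @param dy position grid step. Refused if the one-step kernel would be
#'   under-resolved (`sqrt(nu*dt) < 2*dy`).
#' @param end_cost `"task"` (quadratic-to-nearest-target end cost, default) or
#'   `"flat"` (zero end cost; with zero position cost the recursion then
#'   preserves `psi == 1`, a mass-conservation diagnostic).
#' @param kernel_radius kernel truncation radius in one-step standard
#'   deviations (default 6).
#' @return a `"policy_grid"`: list with `t_grid`, `y_grid`, `log_psi`, `J`,
#'   `u`, and solver metadata. Boundary rows of `u` (one-sided differences)
#'   are flagged in `boundary`.
#' @export
solve_backward <- function(params, config, dy = 0.005,
                           end_cost = c("task", "flat"), kernel_radius = 6) {
  end_cost <- match.arg(end_cost)
  if (config$nu <= 0) stop("solve_backward requires nu > 0; use solve_backward_deterministic")
  if (params$alpha <= 0 && end_cost == "task") {
    stop("solve_backward requires alpha > 0 (soft end cost)")
  }
  sdv <- step_noise_sd(config)
  if (sdv < 2 * dy) {
    stop(sprintf(
      "kernel under-resolved: sqrt(nu*dt) = %.3g < 2*dy = %.3g; use dy <= %.3g",
      sdv, 2 * dy, sdv / 2))
  }
  y <- make_y_grid(config, dy)
  dy_actual <- y[2] - y[1]
  nt <- n_steps(config)
  lambda <- params$R * config$nu
  w <- as.integer(ceiling(kernel_radius * sdv / dy_actual))
  offsets <- (-w):w
  wts <- exp(-(offsets * dy_actual)^2 / (2 * sdv^2))
  wts <- wts / sum(wts)
  lpT <- if (end_cost == "flat") rep(0, length(y)) else {
    -end_cost_fun(y, params$R, params$alpha, config) / lambda
  }
  pos_term <- position_cost_rate(y, params, config) * config$dt / lambda
  log_psi <- cpp_psi_backward(lpT, pos_term, wts, nt)
  grid <- structure(list(
    t_grid = time_grid(config), y_grid = y, log_psi = log_psi,
    J = -lambda * log_psi, u = NULL,
    boundary = c(1L, length(y)),
    nu = config$nu, dy = dy_actual, kernel_halfwidth = w,
    params = params, task_kind = config$task_kind, kind = "psi"
  ), class = "policy_grid")
  extract_policy(grid, params, config)
}

#' Extract the control table from a solved value grid
#'
#' The optimal control is the (negative, scaled) position gradient of the
#' expected cost-to-go: `u = -(1/R) dJ/dy`, equivalently
#' `u = nu * d(log psi)/dy`. The gradient is taken by central differences on
#' the interior and one-sided differences at the two boundary rows (flagged in
#' `grid$boundary`).
#'
#' @param grid a `"policy_grid"` with its value table (`log_psi` or `J`)
#'   filled.
#' @param params the parameter object used to solve the grid.
#' @param config the [task_config()] used to solve the grid.
#' @return the grid with its `u` table filled.
#' @export
extract_policy <- function(grid, params, config) {
  val <- if (!is.null(grid$log_psi)) grid$log_psi else -grid$J / params$R
  bad_mask <- is.nan(val) | val == Inf   # -Inf (underflow far from target) is allowed
  if (isTRUE(any(bad_mask))) {
    bad <- which(bad_mask, arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value entry at t = %.4f, y = %.4f",
                 grid$t_grid[bad[2]], grid$y_grid[bad[1]]))
  }
  ny <- length(grid$y_grid)
  dy <- grid$dy
  # u = nu * d(log psi)/dy; note nu * log_psi = -J/R, so the same differencing
  # applied to -J/(R) gives u directly in the deterministic representation
  scale <- if (!is.null(grid$log_psi)) grid$nu else 1
  u <- val
  u[2:(ny - 1), ] <- (val[3:ny, ] - val[1:(ny - 2), ]) / (2 * dy)
  u[1, ] <- (val[2, ] - val[1, ]) / dy
  u[ny, ] <- (val[ny, ] - val[ny - 1, ]) / dy
  grid$u <- scale * u
  grid
}

#' Solve the extended model without noise (Bellman induction)
#'
#' For the noiseless block the desirability transform is unavailable
#' (`lambda = R*nu = 0`), so the model is solved by explicit backward dynamic
#' programming over a discretized control set: at each grid point the control
#' minimizing `R/2 u^2 dt + position_cost(y) dt + J(y + u dt, t + dt)` is
#' chosen, with linear interpolation of the next time slice in position.
#'
#' @inheritParams solve_backward
#' @param du control grid step in s^-1; the control set spans `±u_max`.
#' @return a `"policy_grid"` with `J` and the argmin control table `u`.
#' @export
solve_backward_deterministic <- function(params, config, dy = 0.005, du = 0.01) {
  if (config$nu != 0) stop("solve_backward_deterministic requires nu = 0")
  if (params$alpha <= 0) stop("requires alpha > 0 (soft end cost)")
  y <- make_y_grid(config, dy)
  nu_ctrl <- as.integer(round(2 * config$u_max / du))
  u_grid <- seq(-config$u_max, config$u_max, length.out = nu_ctrl + 1L)
  # resolution check: the analytic standard-model control one frame before the
  # end, from the edge of the start range, must be representable
  if (params$pos_weight == 0) {
    span <- max(abs(range(config$start_range) - config$targets[1]))
    u_need <- span / (params$alpha + config$dt)
    if (u_need > config$u_max) {
      warning(sprintf(
        "control grid (|u| <= %g) cannot represent the analytic optimum (%.3g) near the final time",
        config$u_max, u_need))
    }
  }
  nt <- n_steps(config)
  sol <- cpp_det_dp(y, u_grid, position_cost_rate(y, params, config),
                    end_cost_fun(y, params$R, params$alpha, config),
                    config$dt, params$R, nt)
  structure(list(
    t_grid = time_grid(config), y_grid = y, log_psi = NULL,
    J = sol$J, u = sol$u,
    boundary = c(1L, length(y)),
    nu = 0, dy = y[2] - y[1], du = u_grid[2] - u_grid[1],
    params = params, task_kind = config$task_kind, kind = "bellman"
  ), class = "policy_grid")
}

#' @export
print.policy_grid <- function(x, ...) {
  cat(sprintf("<policy_grid> %s solver, %s task: %d x %d (y x t), nu = %g\n",
              x$kind, x$task_kind, length(x$y_grid), length(x$t_grid), x$nu))
  invisible(x)
}

#' Turn a policy grid into a feedback policy function
#'
#' Bilinear interpolation of the control table in `(t, y)`; positions and
#' times outside the grid are clamped to its edges.
#'
#' @param grid a solved `"policy_grid"` (with `u` filled).
#' @return `function(y, t)` returning controls, vectorized.
#' @export
policy_fun <- function(grid) {
  tg <- grid$t_grid; yg <- grid$y_grid
  U <- grid$u
  nt <- length(tg); ny <- length(yg)
  dt <- tg[2] - tg[1]; dy <- yg[2] - yg[1]
  function(y, t) {
    gt <- pmin(pmax((t - tg[1]) / dt, 0), nt - 1)
    it <- pmin(floor(gt), nt - 2); ft <- gt - it
    gy <- pmin(pmax((y - yg[1]) / dy, 0), ny - 1)
    iy <- pmin(floor(gy), ny - 2); fy <- gy - iy
    i1 <- cbind(iy + 1, it + 1)
    u00 <- U[i1]
    u10 <- U[cbind(iy + 2, it + 1)]
    u01 <- U[cbind(iy + 1, it + 2)]
    u11 <- U[cbind(iy + 2, it + 2)]
    (1 - ft) * ((1 - fy) * u00 + fy * u10) + ft * ((1 - fy) * u01 + fy * u11)
  }
}
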