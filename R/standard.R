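#' Parameters of the standard (effort + end-accuracy) cost model
#'
#' The standard model penalizes the time-integrated squared control,
#' `R/2 * integral u(t)^2 dt`, plus a quadratic end cost,
#' `end_weight/2 * (y(T) - mu)^2`. Only the ratio `alpha = R / end_weight`
#' (units: seconds) is identifiable from trajectories, so `R` is fixed at 1 by
#' convention and `alpha` is the model's single free parameter. `alpha = 0`
#' encodes the hard-constraint limit `end_weight -> Inf` (the end position is
#' forced onto the target).
#'
#' @param alpha ratio `R/end_weight` in seconds, `>= 0`.
#' @param R control-cost weight (fixed at 1 by convention).
#' @return object of class `"standard_params"`.
#' @export
standard_params <- function(alpha = 0.3, R = 1) {
  stopifnot(R > 0, alpha >= 0)
  structure(list(R = R, alpha = alpha,
                 end_weight = if (alpha > 0) R / alpha else Inf),
            class = "standard_params")
}

#' One-target optimal control (closed form)
#'
#' For the single-target task the stochastic optimal control problem is
#' linear-quadratic and solves exactly: `u*(y, t) = (mu - y) / (alpha + T - t)`.
#' The gain grows as the deadline approaches and the control is exactly
#' independent of the noise amplitude `nu`.
#'
#' @param y position (vectorized).
#' @param t time in `[0, T_final)` (vectorized).
#' @param p a [standard_params()].
#' @param config a [task_config()] (uses `targets[1]` and `T_final`).
#' @return optimal control in s^-1.
#' @export
one_target_control <- function(y, t, p, config) {
  if (any(t < 0 | t >= config$T_final)) {
    stop("one_target_control requires 0 <= t < T_final")
  }
  (config$targets[1] - y) / (p$alpha + config$T_final - t)
}

#' One-target optimal expected cost-to-go (closed form)
#'
#' Quadratic in the distance to the target with curvature
#' `R / (alpha + T - t)`, plus a state-independent term accumulating the
#' unavoidable noise cost. At `t = T` it equals the end cost, and its negative
#' position gradient divided by `R` is the optimal control.
#'
#' @inheritParams one_target_control
#' @return expected cost-to-go.
#' @export
one_target_cost_to_go <- function(y, t, p, config) {
  if (any(t < 0 | t > config$T_final)) stop("t must lie in [0, T_final]")
  horizon <- p$alpha + config$T_final - t
  quad <- p$R * (y - config$targets[1])^2 / (2 * horizon)
  # noise floor: (R*nu/2) * log((alpha + T - t)/alpha); finite only for alpha>0
  const <- if (config$nu > 0 && p$alpha > 0) {
    (p$R * config$nu / 2) * log(horizon / p$alpha)
  } else 0
  quad + const
}

# log responsibilities of the two targets and per-target controls.
# End cost (1/(2*alpha)) * min_i (y_T - mu_i)^2 with lambda = R*nu gives a
# desirability that splits at the targets' midpoint into two truncated
# Gaussians; because the targets are equidistant from the midpoint, the
# truncation boundary terms cancel in d(log psi)/dy, and the optimal control
# is exactly the responsibility-weighted blend of the per-target LQ controls.
two_target_parts <- function(y, t, p, config) {
  mu <- config$targets
  m <- mean(mu)
  n <- max(length(y), length(t))
  y <- rep_len(y, n); t <- rep_len(t, n)
  sigma2 <- config$nu * (config$T_final - t)      # uncontrolled spread to T
  s2 <- config$nu * p$alpha                       # end-cost softness
  tot <- sigma2 + s2
  # log of the Gaussian mass factor per target (common factors dropped)
  log_z <- cbind(-(y - mu[1])^2 / (2 * tot), -(y - mu[2])^2 / (2 * tot))
  # truncation probabilities of each piece on its own side of the midpoint;
  # a collapsed piece (alpha = 0) keeps all its mass on its own side
  v <- sigma2 * s2 / tot
  sv <- sqrt(pmax(v, 0))
  m1 <- (y * s2 + mu[1] * sigma2) / tot
  m2 <- (y * s2 + mu[2] * sigma2) / tot
  log_p1 <- ifelse(sv > 0,
                   stats::pnorm((m - m1) / sv, log.p = TRUE), 0)
  log_p2 <- ifelse(sv > 0,
                   stats::pnorm((m - m2) / sv, lower.tail = FALSE, log.p = TRUE), 0)
  lw <- cbind(log_z[, 1] + log_p1, log_z[, 2] + log_p2)
  mx <- pmax(lw[, 1], lw[, 2])
  w <- exp(lw - mx)
  w <- w / rowSums(w)
  list(w = w,
       u = cbind((mu[1] - y) / (p$alpha + config$T_final - t),
                 (mu[2] - y) / (p$alpha + config$T_final - t)))
}

#' Two-target optimal control (path-integral closed form)
#'
#' With two targets the end cost is the squared distance to the *nearest*
#' target, and the problem is linearly solvable: the desirability
#' `psi(y, t) = E[exp(-end_cost(y_T)/lambda)]` under the uncontrolled
#' diffusion, with `lambda = R*nu`, obeys a linear backward equation, and the
#' optimal control is `u = nu * d(log psi)/dy`. For symmetric targets this
#' evaluates exactly to a responsibility-weighted blend of the two per-target
#' one-target controls; the soft weighting produces the "symmetry breaking"
#' pull toward the midpoint early in high-noise trials.
#'
#' @inheritParams one_target_control
#' @param config a two-target [task_config()] with `nu > 0`.
#' @return optimal control in s^-1.
#' @seealso [two_target_control_deterministic()] for the `nu = 0` limit,
#'   [two_target_responsibilities()] for the blend weights.
#' @export
two_target_control <- function(y, t, p, config) {
  if (config$task_kind != "two_target") stop("requires a two-target config")
  if (config$nu <= 0) {
    stop("nu = 0: use two_target_control_deterministic for the noiseless limit")
  }
  if (any(t < 0 | t >= config$T_final)) stop("requires 0 <= t < T_final")
  parts <- two_target_parts(y, t, p, config)
  rowSums(parts$w * parts$u)
}

#' Responsibility weights of the two targets
#'
#' The posterior probability, under the desirability measure, that the trial
#' ends in each target's basin. Weights lie in `[0, 1]` and sum to 1; the
#' optimal two-target control is their weighted blend of per-target controls.
#'
#' @inheritParams two_target_control
#' @return matrix with one row per evaluation point and columns
#'   `(lower, upper)`.
#' @export
two_target_responsibilities <- function(y, t, p, config) {
  if (config$task_kind != "two_target") stop("requires a two-target config")
  if (config$nu <= 0) stop("requires nu > 0")
  two_target_parts(y, t, p, config)$w
}

#' Two-target control in the noiseless limit
#'
#' As `nu -> 0` the soft blend collapses onto the nearest target: the optimal
#' strategy is the one-target control aimed at whichever target is closer
#' (ties go to the upper target). With `alpha = 0` the resulting noiseless
#' trajectory is a straight line traversed with constant control.
#'
#' @inheritParams one_target_control
#' @param config a two-target [task_config()].
#' @return control in s^-1.
#' @export
two_target_control_deterministic <- function(y, t, p, config) {
  if (config$task_kind != "two_target") stop("requires a two-target config")
  if (any(t < 0 | t >= config$T_final)) stop("requires 0 <= t < T_final")
  mu <- config$targets
  d1 <- abs(y - mu[1]); d2 <- abs(y - mu[2])
  nearest <- ifelse(d2 <= d1, mu[2], mu[1])  # tie -> upper
  (nearest - y) / (p$alpha + config$T_final - t)
}

#' Two-target desirability (log domain)
#'
#' Full log-desirability `log psi(y, t)` for the two-target end cost,
#' evaluated via the two truncated-Gaussian pieces. Requires `alpha > 0` and
#' `nu > 0`. Primarily a cross-check against quadrature and the grid solver.
#'
#' @inheritParams two_target_control
#' @return `log psi` values.
#' @export
two_target_log_psi <- function(y, t, p, config) {
  if (config$task_kind != "two_target") stop("requires a two-target config")
  if (config$nu <= 0 || p$alpha <= 0) stop("requires nu > 0 and alpha > 0")
  mu <- config$targets
  m <- mean(mu)
  n <- max(length(y), length(t))
  y <- rep_len(y, n); t <- rep_len(t, n)
  sigma2 <- config$nu * (config$T_final - t)
  s2 <- config$nu * p$alpha
  tot <- sigma2 + s2
  v <- sigma2 * s2 / tot
  sv <- sqrt(pmax(v, 0))
  log_pref <- 0.5 * log(s2 / tot)
  piece <- function(i, lower) {
    mi <- (y * s2 + mu[i] * sigma2) / tot
    lp <- ifelse(sv > 0,
                 stats::pnorm((m - mi) / sv, lower.tail = lower, log.p = TRUE),
                 0)
    log_pref - (y - mu[i])^2 / (2 * tot) + lp
  }
  l1 <- piece(1, TRUE); l2 <- piece(2, FALSE)
  mx <- pmax(l1, l2)
  mx + log(exp(l1 - mx) + exp(l2 - mx))
}
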