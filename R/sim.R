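#' One Euler step of the ball dynamics
#'
#' The ball's vertical position follows first-order stochastic dynamics: at
#' each frame the position advances by the commanded velocity times `dt` plus a
#' Gaussian increment of standard deviation `sqrt(nu*dt)`. The result is
#' clipped to the screen bounds; whether clipping occurred is reported in the
#' `"clipped"` attribute.
#'
#' @param y current position (vectorized).
#' @param u control in s^-1 (vectorized).
#' @param eps standard-normal draw(s).
#' @param config a [task_config()].
#' @return next position(s), with logical attribute `"clipped"`.
#' @export
#' @examples
#' step_position(0, 1, 0, task_config(nu = 0))  # pure drift: 1/75
step_position <- function(y, u, eps, config) {
  y_new <- y + u * config$dt + step_noise_sd(config) * eps
  clipped <- y_new < config$y_bounds[1] | y_new > config$y_bounds[2]
  y_new <- pmin(pmax(y_new, config$y_bounds[1]), config$y_bounds[2])
  attr(y_new, "clipped") <- clipped
  y_new
}

#' Seeded bank of process-noise realizations
#'
#' In the experiment every subject in a given block experienced exactly the
#' same pseudo-random noise sequences. A noise bank reproduces that design:
#' for a fixed seed it deterministically yields one standard-normal increment
#' sequence (length `T_final/dt`) per trial, independent across trials, to be
#' shared across synthetic subjects within a block.
#'
#' @param seed integer seed.
#' @param n_trials number of trials in the block.
#' @param config a [task_config()].
#' @return object of class `"noise_bank"`: list with `seed` and `sequences`
#'   (an `n_trials x n_steps` matrix of standard-normal draws).
#' @export
make_noise_bank <- function(seed, n_trials, config) {
  stopifnot(n_trials >= 1)
  ns <- n_steps(config)
  eps <- withr::with_seed(as.integer(seed),
                          matrix(stats::rnorm(n_trials * ns), nrow = n_trials))
  structure(list(seed = as.integer(seed), sequences = eps),
            class = "noise_bank")
}

#' Simulate one closed-loop trial
#'
#' Advances the ball with [step_position()] under a feedback policy. The
#' control is held at zero while `t < reaction_time` (the subject has not yet
#' responded), and is clipped at `u_max` (joystick saturation). The stored
#' control vector is the executed (clipped) control; its final sample, at
#' `t = T_final`, is 0 since no further step is applied.
#'
#' @param policy `function(y, t)` returning a control in s^-1, or `NULL` for
#'   the uncontrolled ball.
#' @param config a [task_config()].
#' @param y0 initial position.
#' @param noise standard-normal increment vector of length `T_final/dt`
#'   (ignored when `nu = 0`).
#' @param noise_seed seed recorded in the returned trial's metadata.
#' @param trial_id,subject_id metadata for the returned trial.
#' @return a [trial()]. Attribute `"n_clipped"` counts boundary-clipped steps.
#' @export
simulate_trial <- function(policy, config, y0, noise = NULL,
                           noise_seed = 0L, trial_id = 1L, subject_id = "sim") {
  ns <- n_steps(config)
  if (is.null(noise)) noise <- numeric(ns)
  stopifnot(length(noise) == ns)
  tt <- time_grid(config)
  y <- numeric(ns + 1L)
  u <- numeric(ns + 1L)
  y[1] <- y0
  n_clipped <- 0L
  for (k in seq_len(ns)) {
    tk <- tt[k]
    if (is.null(policy) || tk < config$reaction_time) {
      uk <- 0
    } else {
      uk <- policy(y[k], tk)
      if (!is.finite(uk)) {
        stop(sprintf("policy returned non-finite control at t = %.4f", tk))
      }
      uk <- max(-config$u_max, min(config$u_max, uk))
    }
    u[k] <- uk
    ynext <- step_position(y[k], uk, noise[k], config)
    n_clipped <- n_clipped + sum(attr(ynext, "clipped"))
    y[k + 1L] <- as.numeric(ynext)
  }
  out <- trial(trial_id, subject_id, tt, y, u, noise_seed = noise_seed)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Simulate an uncontrolled ensemble
#'
#' Propagates `n_trials` noise realizations with zero control, vectorized over
#' trials; used for checking the Wiener variance law `Var[y(t)] = nu * t`.
#'
#' @param config a [task_config()].
#' @param bank a [make_noise_bank()] result.
#' @param y0 common start position.
#' @param clip clip positions to `y_bounds` (default TRUE). Set FALSE to study
#'   the unbounded diffusion.
#' @return matrix of positions, `n_trials x (n_steps+1)`.
#' @export
simulate_uncontrolled <- function(config, bank, y0 = 0, clip = TRUE) {
  eps <- bank$sequences
  ns <- n_steps(config)
  stopifnot(ncol(eps) == ns)
  y <- matrix(0, nrow = nrow(eps), ncol = ns + 1L)
  y[, 1] <- y0
  sdv <- step_noise_sd(config)
  for (k in seq_len(ns)) {
    yn <- y[, k] + sdv * eps[, k]
    if (clip) yn <- pmin(pmax(yn, config$y_bounds[1]), config$y_bounds[2])
    y[, k + 1L] <- yn
  }
  y
}
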