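#' Synthetic subject profile
#'
#' A simulated subject is a closed-loop controller embodying one of the two
#' cost models, wrapped in the behavioural nuisances of a human operator: a
#' reaction time during which no control is produced, a sensorimotor feedback
#' delay (the policy sees stale state), additive Gaussian motor noise on the
#' executed control, and an optional joystick dead zone.
#'
#' @param subject_id character label.
#' @param generating_model `"standard"` or `"extended"`.
#' @param params a [standard_params()] or [extended_params()] matching
#'   `generating_model`.
#' @param reaction_time seconds with zero control at trial start (default 0.5).
#' @param feedback_delay sensorimotor delay in seconds (default 0.2); must not
#'   exceed `reaction_time`.
#' @param motor_noise_sd sd of Gaussian noise added to the executed control,
#'   in s^-1 (default 0.03, about a tenth of the typical control scale).
#' @param dead_zone controls of magnitude below this are zeroed (default 0).
#' @param seed integer seed for the subject's motor noise.
#' @return object of class `"subject_profile"`.
#' @export
subject_profile <- function(subject_id, generating_model = c("standard", "extended"),
                            params = NULL, reaction_time = 0.5,
                            feedback_delay = 0.2, motor_noise_sd = 0.03,
                            dead_zone = 0, seed = 1L) {
  generating_model <- match.arg(generating_model)
  if (is.null(params)) {
    params <- if (generating_model == "standard") standard_params() else extended_params()
  }
  want <- if (generating_model == "standard") "standard_params" else "extended_params"
  if (!inherits(params, want)) stop(sprintf("params must be a %s object", want))
  stopifnot(reaction_time >= feedback_delay, feedback_delay >= 0,
            motor_noise_sd >= 0, dead_zone >= 0)
  structure(list(subject_id = as.character(subject_id),
                 generating_model = generating_model, params = params,
                 reaction_time = reaction_time, feedback_delay = feedback_delay,
                 motor_noise_sd = motor_noise_sd, dead_zone = dead_zone,
                 seed = as.integer(seed)),
            class = "subject_profile")
}

# model policy for a profile in a given block (solves/caches grids as needed)
profile_policy <- function(profile, config, dy = 0.005, du = 0.01) {
  p <- profile$params
  if (profile$generating_model == "standard") {
    if (config$task_kind == "one_target") {
      function(y, t) one_target_control(y, t, p, config)
    } else if (config$nu > 0) {
      function(y, t) two_target_control(y, t, p, config)
    } else {
      function(y, t) two_target_control_deterministic(y, t, p, config)
    }
  } else {
    theta <- c(p$alpha, p$pos_weight, p$pos_steepness)
    grid <- cached_extended_grid(theta, config, dy = dy, du = du)
    policy_fun(grid)
  }
}

#' Generate one block of trials for a synthetic subject
#'
#' Runs the subject's policy in closed loop against a shared [make_noise_bank()].
#' At each frame after the reaction time the executed control is
#' `policy(y(t - feedback_delay), t - feedback_delay)` plus motor noise, zeroed
#' inside the dead zone and clipped at `u_max`; the stored trial records the
#' executed control. Start positions are drawn from the bank's seed (so all
#' subjects sharing a bank also share start positions, as in the experiment);
#' motor noise is drawn from the profile's seed.
#'
#' @param profile a [subject_profile()].
#' @param config a [task_config()].
#' @param bank a [make_noise_bank()] with one sequence per trial.
#' @param block_label label for the returned [trial_set()].
#' @return a [trial_set()] with `nrow(bank$sequences)` trials; attribute
#'   `"n_clipped"` counts screen-boundary clipping events (zero under default
#'   geometries).
#' @export
generate_subject_block <- function(profile, config, bank,
                                   block_label = sprintf("nu=%g", config$nu)) {
  if (profile$generating_model == "standard" &&
      config$task_kind == "two_target" && !inherits(profile$params, "standard_params")) {
    stop("profile/config mismatch")
  }
  n_trials <- nrow(bank$sequences)
  ns <- n_steps(config)
  tt <- time_grid(config)
  dt <- config$dt
  d_steps <- as.integer(round(profile$feedback_delay / dt))
  pol <- profile_policy(profile, config)
  sr <- config$start_range
  y0s <- if (length(sr) == 1L) rep(sr, n_trials) else {
    withr::with_seed(bank$seed + 1L, stats::runif(n_trials, sr[1], sr[2]))
  }
  mns <- withr::with_seed((profile$seed * 10007L + bank$seed) %% 2147483647L,
                          matrix(stats::rnorm(n_trials * ns), nrow = n_trials))
  sdv <- step_noise_sd(config)
  trials <- vector("list", n_trials)
  n_clipped <- 0L
  for (i in seq_len(n_trials)) {
    y <- numeric(ns + 1L); u <- numeric(ns + 1L)
    y[1] <- y0s[i]
    for (k in seq_len(ns)) {
      if (tt[k] < profile$reaction_time) {
        uk <- 0
      } else {
        kd <- max(1L, k - d_steps)
        uk <- pol(y[kd], tt[kd]) + profile$motor_noise_sd * mns[i, k]
        if (!is.finite(uk)) stop(sprintf("non-finite control at t = %.4f", tt[k]))
        if (abs(uk) < profile$dead_zone) uk <- 0
        uk <- max(-config$u_max, min(config$u_max, uk))
      }
      u[k] <- uk
      yn <- y[k] + uk * dt + sdv * bank$sequences[i, k]
      if (yn < config$y_bounds[1] || yn > config$y_bounds[2]) {
        n_clipped <- n_clipped + 1L
      }
      y[k + 1L] <- min(max(yn, config$y_bounds[1]), config$y_bounds[2])
    }
    trials[[i]] <- trial(i, profile$subject_id, tt, y, u, noise_seed = bank$seed)
  }
  out <- trial_set(config, trials, block_label = block_label, validate = FALSE)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Generate a full synthetic experiment
#'
#' One block per noise amplitude for each subject, mirroring the experimental
#' design: blocks of `n_trials` trials at noise amplitudes `nu_values`, with a
#' per-amplitude noise bank shared across subjects so every subject experiences
#' identical noise realizations.
#'
#' @param profiles list of [subject_profile()]s.
#' @param config_template a [task_config()] whose `nu` is overridden per block.
#' @param seed master seed; block `b` uses bank seed `seed + b`.
#' @param nu_values noise amplitudes (default the experimental
#'   `c(0, 0.009, 0.04, 0.08)`).
#' @param n_trials trials per block (default 100).
#' @return named list of [trial_set()]s, keys `"<subject_id>/nu=<nu>"`.
#' @export
generate_experiment <- function(profiles, config_template, seed = 1L,
                                nu_values = c(0, 0.009, 0.04, 0.08),
                                n_trials = 100L) {
  stopifnot(length(profiles) >= 1)
  out <- list()
  for (b in seq_along(nu_values)) {
    cfg <- config_template
    cfg$nu <- nu_values[b]
    cfg <- validate_task_config(cfg)
    bank <- make_noise_bank(seed + b, n_trials, cfg)
    for (pr in profiles) {
      key <- sprintf("%s/nu=%g", pr$subject_id, nu_values[b])
      out[[key]] <- generate_subject_block(pr, cfg, bank)
    }
  }
  out
}
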