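#' Task configuration for the steering experiment
#'
#' Describes the geometry, timing and noise of one experimental block of the
#' joystick-ball task: the ball moves at constant horizontal speed across the
#' screen for `T_final` seconds while the subject controls its vertical
#' velocity; Gaussian white noise of variance rate `nu` is superimposed on the
#' vertical position, so the uncontrolled ball performs a Wiener process.
#'
#' @param task_kind `"one_target"` (single target on the midline) or
#'   `"two_target"` (two targets placed symmetrically about the midline).
#' @param T_final trial duration in seconds. Default 3.
#' @param dt sample interval in seconds; `T_final/dt` must be an integer.
#'   Default 1/75 (the 75 Hz projector frame rate).
#' @param nu noise variance rate (dimensionless position squared per second).
#'   The per-step position increment has variance `nu * dt`. The experimental
#'   blocks used 0, 0.009, 0.04 and 0.08.
#' @param targets numeric vector of vertical target positions; length 1 for the
#'   one-target task, length 2 for the two-target task.
#' @param y_bounds length-2 numeric, lower/upper screen limits in normalized
#'   vertical coordinates.
#' @param u_max control magnitude bound in s^-1 (joystick saturation).
#' @param start_range either a single number (fixed start position) or a
#'   length-2 interval from which the start position is drawn uniformly.
#' @param reaction_time seconds of enforced zero control at trial start.
#' @param delay sensorimotor feedback delay in seconds (policies are evaluated
#'   on state this much in the past).
#' @param noise_mode `"variance_rate"` (increment sd `sqrt(nu*dt)`, default) or
#'   `"amplitude"` (increment sd `nu*sqrt(dt)`, i.e. `nu` read as a per-sqrt-s
#'   standard deviation).
#'
#' @return An object of class `"task_config"` (a validated list).
#' @export
#' @examples
#' cfg <- task_config()
#' cfg2 <- task_config(task_kind = "two_target", nu = 0.04)
task_config <- function(task_kind = c("one_target", "two_target"),
                        T_final = 3.0,
                        dt = 1 / 75,
                        nu = 0.04,
                        targets = NULL,
                        y_bounds = c(-1, 1),
                        u_max = 2.0,
                        start_range = NULL,
                        reaction_time = 0.5,
                        delay = 0.2,
                        noise_mode = c("variance_rate", "amplitude")) {
  task_kind <- match.arg(task_kind)
  noise_mode <- match.arg(noise_mode)
  if (is.null(targets)) {
    targets <- if (task_kind == "one_target") 0 else c(-0.5, 0.5)
  }
  if (is.null(start_range)) {
    start_range <- if (task_kind == "one_target") c(-0.5, 0.5) else 0
  }
  cfg <- structure(list(
    task_kind = task_kind, T_final = T_final, dt = dt, nu = nu,
    targets = sort(as.numeric(targets)), y_bounds = as.numeric(y_bounds),
    u_max = u_max, start_range = as.numeric(start_range),
    reaction_time = reaction_time, delay = delay, noise_mode = noise_mode
  ), class = "task_config")
  validate_task_config(cfg)
}

#' Validate a task configuration
#'
#' Checks every structural invariant of a [task_config()]: positive integer
#' number of steps, non-negative noise, targets inside the screen, target count
#' matching the task kind, and `0 <= delay < reaction_time < T_final`.
#'
#' @param cfg a `task_config` object or plain list with the same fields.
#' @return the validated object, invisibly classed as `"task_config"`.
#' @export
validate_task_config <- function(cfg) {
  stopifnot(is.list(cfg))
  with(cfg, {
    if (!(dt > 0)) stop("dt must be positive")
    n_steps <- T_final / dt
    if (abs(n_steps - round(n_steps)) > 1e-8) {
      stop("T_final/dt must be an integer number of steps")
    }
    if (nu < 0) stop("nu must be >= 0")
    if (length(y_bounds) != 2 || y_bounds[1] >= y_bounds[2]) {
      stop("y_bounds must be an increasing pair")
    }
    if (any(targets < y_bounds[1] | targets > y_bounds[2])) {
      stop("targets must lie within y_bounds")
    }
    n_t <- if (task_kind == "one_target") 1L else 2L
    if (length(targets) != n_t) {
      stop(sprintf("%s task requires %d target(s), got %d",
                   task_kind, n_t, length(targets)))
    }
    if (!(length(start_range) %in% c(1L, 2L))) {
      stop("start_range must be a point or an interval")
    }
    if (!(delay >= 0 && delay < reaction_time && reaction_time < T_final)) {
      stop("need 0 <= delay < reaction_time < T_final")
    }
    if (u_max <= 0) stop("u_max must be positive")
  })
  if (!inherits(cfg, "task_config")) class(cfg) <- "task_config"
  invisible(cfg)
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf("<task_config> %s task: T = %g s, dt = 1/%g s, nu = %g\n",
              x$task_kind, x$T_final, round(1 / x$dt), x$nu))
  cat(sprintf("  targets: %s; y in [%g, %g]; |u| <= %g\n",
              paste(x$targets, collapse = ", "),
              x$y_bounds[1], x$y_bounds[2], x$u_max))
  cat(sprintf("  reaction_time = %g s, delay = %g s\n",
              x$reaction_time, x$delay))
  invisible(x)
}

# number of Euler steps (= samples - 1)
n_steps <- function(cfg) as.integer(round(cfg$T_final / cfg$dt))

# sample times 0, dt, ..., T_final computed without cumulative rounding
time_grid <- function(cfg) (0:n_steps(cfg)) * cfg$dt

# per-step noise increment standard deviation
step_noise_sd <- function(cfg) {
  if (cfg$noise_mode == "variance_rate") sqrt(cfg$nu * cfg$dt) else cfg$nu * sqrt(cfg$dt)
}

#' Read / write a task configuration as YAML
#'
#' The YAML keys mirror the [task_config()] fields, so a config file is a
#' complete, human-editable description of an experimental block.
#'
#' @param path file path.
#' @return `read_task_config()` returns a validated `task_config`.
#' @export
read_task_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(task_config, raw)
}

#' @rdname read_task_config
#' @param cfg a `task_config`.
#' @export
write_task_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$T_final <- as.numeric(out$T_final)
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}
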