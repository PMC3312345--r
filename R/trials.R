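#' Construct a single trial
#'
#' A trial is one 3-second pass of the ball across the screen: aligned vectors
#' of sample time `t`, vertical ball position `y` and executed control `u`
#' (vertical velocity command, s^-1), plus identifying metadata.
#'
#' @param trial_id integer trial number within its block.
#' @param subject_id character subject label.
#' @param t,y,u numeric vectors of equal length `T_final/dt + 1`.
#' @param noise_seed integer seed of the process-noise sequence used (0 if not
#'   applicable).
#' @param config the [task_config()] the trial belongs to; when supplied the
#'   trial invariants are checked.
#' @return an object of class `"steer_trial"`.
#' @export
trial <- function(trial_id, subject_id, t, y, u, noise_seed = 0L, config = NULL) {
  tr <- structure(list(
    trial_id = as.integer(trial_id), subject_id = as.character(subject_id),
    noise_seed = as.integer(noise_seed),
    t = as.numeric(t), y = as.numeric(y), u = as.numeric(u)
  ), class = "steer_trial")
  if (!is.null(config)) validate_trial(tr, config)
  tr
}

validate_trial <- function(tr, cfg) {
  n <- n_steps(cfg) + 1L
  if (!(length(tr$t) == length(tr$y) && length(tr$y) == length(tr$u))) {
    stop(sprintf("trial %d: t, y, u must have equal length", tr$trial_id))
  }
  if (length(tr$t) != n) {
    stop(sprintf("trial %d: expected %d samples, got %d",
                 tr$trial_id, n, length(tr$t)))
  }
  if (any(diff(tr$t) <= 0)) stop(sprintf("trial %d: t not strictly increasing", tr$trial_id))
  if (abs(tr$t[1]) > 1e-9 || abs(tr$t[n] - cfg$T_final) > 1e-9) {
    stop(sprintf("trial %d: t must run from 0 to T_final", tr$trial_id))
  }
  if (any(tr$y < cfg$y_bounds[1] - 1e-12 | tr$y > cfg$y_bounds[2] + 1e-12)) {
    stop(sprintf("trial %d: position outside y_bounds", tr$trial_id))
  }
  if (any(abs(tr$u) > cfg$u_max + 1e-12)) {
    stop(sprintf("trial %d: control exceeds u_max", tr$trial_id))
  }
  invisible(tr)
}

#' Construct a set of trials sharing one configuration
#'
#' @param config a [task_config()].
#' @param trials list of [trial()] objects.
#' @param block_label character label for the block (e.g. `"nu=0.04"`).
#' @param validate check all trial invariants (default TRUE).
#' @return an object of class `"trial_set"`.
#' @export
trial_set <- function(config, trials, block_label = "", validate = TRUE) {
  ts <- structure(list(config = config, trials = trials,
                       block_label = as.character(block_label)),
                  class = "trial_set")
  if (validate) for (tr in trials) validate_trial(tr, config)
  ts
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials, %s task, block '%s'\n",
              length(x$trials), x$config$task_kind, x$block_label))
  invisible(x)
}

#' @export
length.trial_set <- function(x) length(x$trials)

#' Read trials from a delimited text file
#'
#' Expects a CSV with one row per sample and header columns `subject_id`,
#' `trial_id`, `block_label`, `t`, `y`, `u` (plus an optional `noise_seed`).
#' Rows are grouped by `trial_id` and sorted by `t`; every trial must satisfy
#' the trial invariants for `config`.
#'
#' @param path CSV file path.
#' @param config the [task_config()] the trials are validated against.
#' @return a [trial_set()].
#' @export
read_trials <- function(path, config) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "trial_id", "block_label", "t", "y", "u")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("trial file schema error: missing column(s) %s",
                 paste(missing, collapse = ", ")))
  }
  if (!("noise_seed" %in% names(df))) df$noise_seed <- 0L
  block <- if (nrow(df) > 0) df$block_label[1] else ""
  trials <- list()
  if (nrow(df) > 0) {
    if (length(unique(df$block_label)) > 1) {
      stop("trial file contains more than one block_label")
    }
    for (id in unique(df$trial_id)) {
      rows <- df[df$trial_id == id, , drop = FALSE]
      rows <- rows[order(rows$t), , drop = FALSE]
      tr <- trial(id, rows$subject_id[1], rows$t, rows$y, rows$u,
                  noise_seed = rows$noise_seed[1])
      validate_trial(tr, config)
      trials[[length(trials) + 1L]] <- tr
    }
  }
  trial_set(config, trials, block_label = block, validate = FALSE)
}

#' Write trials to a delimited text file
#'
#' Inverse of [read_trials()]: numeric columns are serialized with 17
#' significant digits so that a read/write round trip reproduces every stored
#' value exactly.
#'
#' @param ts a [trial_set()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_trials <- function(ts, path) {
  cols <- c("subject_id", "trial_id", "block_label", "noise_seed", "t", "y", "u")
  if (length(ts$trials) == 0) {
    writeLines(paste(cols, collapse = ","), path)
    return(invisible(path))
  }
  pieces <- lapply(ts$trials, function(tr) {
    data.frame(subject_id = tr$subject_id, trial_id = tr$trial_id,
               block_label = ts$block_label, noise_seed = tr$noise_seed,
               t = sprintf("%.17g", tr$t), y = sprintf("%.17g", tr$y),
               u = sprintf("%.17g", tr$u), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Classify which target a two-target trial aimed for
#'
#' Returns the index (into `config$targets`, sorted increasing) of the target
#' nearest to the final ball position. An exact tie at the midpoint is assigned
#' to the upper target, so symmetry folding is reproducible.
#'
#' @param tr a [trial()].
#' @param config a two-target [task_config()].
#' @return integer target index (1 = lower, 2 = upper).
#' @export
classify_target_choice <- function(tr, config) {
  if (config$task_kind != "two_target") {
    stop("classify_target_choice requires a two-target config")
  }
  yT <- tr$y[length(tr$y)]
  d <- abs(yT - config$targets)
  # tie -> upper target (targets sorted increasing, so prefer the larger index)
  if (d[2] <= d[1]) 2L else 1L
}

#' Fold trials by task symmetry
#'
#' Both tasks are symmetric about the midline, so trials on the lower half are
#' mirror images of trials on the upper half. Before averaging or display, the
#' sign of position and control is inverted for one-target trials that started
#' below the midline and for two-target trials classified (by
#' [classify_target_choice()]) as aiming at the lower target, so that all
#' trials read as upper-half trials. Trials starting exactly on the midline
#' (one-target) are left unflipped; a final position exactly at the midpoint
#' (two-target) counts as the upper target. The trial count is unchanged and
#' folding is idempotent.
#'
#' @param ts a [trial_set()]. The task must be symmetric about the midline
#'   (one-target: target on the midline; two-target: targets at equal and
#'   opposite offsets).
#' @return a [trial_set()] with flipped copies substituted where needed.
#' @export
fold_by_symmetry <- function(ts) {
  cfg <- ts$config
  mid <- mean(cfg$targets)
  if (cfg$task_kind == "one_target") {
    if (abs(cfg$targets[1] - mid) > 1e-12) stop("one-target fold requires target on the midline")
  } else {
    offs <- cfg$targets - mid
    if (abs(offs[1] + offs[2]) > 1e-9) stop("two-target fold requires symmetric targets")
  }
  flip <- function(tr) {
    trial(tr$trial_id, tr$subject_id,
          tr$t, 2 * mid - tr$y, -tr$u, noise_seed = tr$noise_seed)
  }
  new_trials <- lapply(ts$trials, function(tr) {
    if (cfg$task_kind == "one_target") {
      if (tr$y[1] < mid) flip(tr) else tr
    } else {
      if (classify_target_choice(tr, cfg) == 1L) flip(tr) else tr
    }
  })
  trial_set(cfg, new_trials, block_label = ts$block_label, validate = FALSE)
}
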