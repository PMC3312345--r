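#' Fitting window for the trajectory MSE
#'
#' The model-to-data comparison is restricted to `t` in `[t_start, t_end]`:
#' the lower bound excludes the reaction-time period (subjects' median
#' reaction time was just under 0.5 s), and the upper bound leaves room for
#' the sensorimotor delay before the final time. With the defaults and a
#' 75 Hz sample rate the window contains 151 samples per trial.
#'
#' @param t_start window start, s (default 0.8).
#' @param t_end window end, s (default 2.8).
#' @param delay sensorimotor delay, s (default 0.2): the model control
#'   compared at time `t` is the policy evaluated at the delayed state and
#'   delayed time `(y(t - delay), t - delay)`.
#' @return object of class `"fit_window"`.
#' @export
fit_window <- function(t_start = 0.8, t_end = 2.8, delay = 0.2) {
  stopifnot(0 <= t_start, t_start < t_end, delay >= 0)
  if (t_start < delay) stop("window error: t_start must be >= delay")
  structure(list(t_start = t_start, t_end = t_end, delay = delay),
            class = "fit_window")
}

check_window <- function(window, config) {
  if (window$t_end > config$T_final - window$delay + config$dt / 2) {
    stop("window error: t_end must be <= T_final - delay + dt/2")
  }
  invisible(window)
}

#' Policy factory for the standard model
#'
#' Returns a function mapping `theta = alpha` to a feedback policy
#' `function(y, t)` for the given task and noise amplitude (closed-form in all
#' cases; the noiseless two-target limit uses the nearest-target rule).
#'
#' @param config a [task_config()].
#' @return `function(theta)` returning a policy function.
#' @export
standard_policy_factory <- function(config) {
  force(config)
  function(theta) {
    p <- standard_params(alpha = theta[1])
    if (config$task_kind == "one_target") {
      function(y, t) one_target_control(y, t, p, config)
    } else if (config$nu > 0) {
      function(y, t) two_target_control(y, t, p, config)
    } else {
      function(y, t) two_target_control_deterministic(y, t, p, config)
    }
  }
}

#' Policy factory for the extended model
#'
#' Returns a function mapping `theta = c(alpha, pos_weight, pos_steepness)` to
#' a feedback policy. For `pos_weight > 0` the policy grid is solved (by
#' [solve_backward()] for `nu > 0`, [solve_backward_deterministic()] for
#' `nu = 0`) and interpolated bilinearly; solved grids are cached keyed by the
#' quantized parameters. At `pos_weight = 0` the model reduces exactly to the
#' standard model and the closed-form standard policy is used.
#'
#' @param config a [task_config()].
#' @param dy,du grid steps passed to the solvers.
#' @return `function(theta)` returning a policy function.
#' @export
extended_policy_factory <- function(config, dy = 0.005, du = 0.01) {
  force(config); force(dy); force(du)
  std <- standard_policy_factory(config)
  function(theta) {
    if (theta[2] == 0) return(std(theta[1]))
    policy_fun(cached_extended_grid(theta, config, dy = dy, du = du))
  }
}

# solve (or fetch) an extended-model policy grid, cache keyed by quantized
# parameters, task, noise amplitude and grid resolution
cached_extended_grid <- function(theta, config, dy = 0.005, du = 0.01) {
  key <- paste(config$task_kind, sprintf("%.10g", config$nu),
               sprintf("%.6g", dy), sprintf("%.6g", du),
               paste(sprintf("%.6g", theta), collapse = ","), sep = "|")
  hit <- .policy_cache[[key]]
  if (!is.null(hit)) return(hit)
  params <- extended_params(alpha = theta[1], pos_weight = theta[2],
                            pos_steepness = theta[3])
  grid <- if (config$nu > 0) {
    solve_backward(params, config, dy = dy)
  } else {
    solve_backward_deterministic(params, config, dy = dy, du = du)
  }
  # keep only what interpolation needs; cap the cache size
  slim <- grid
  slim$log_psi <- NULL
  slim$J <- NULL
  if (length(ls(.policy_cache)) > 256) clear_policy_cache()
  .policy_cache[[key]] <- slim
  slim
}

#' Clear the cached policy grids
#' @return invisibly, the number of entries removed.
#' @export
clear_policy_cache <- function() {
  n <- length(ls(.policy_cache))
  rm(list = ls(.policy_cache), envir = .policy_cache)
  invisible(n)
}

#' Trajectory mean-squared-error objective
#'
#' The fitting criterion: the mean over all trials and all window samples of
#' the squared difference between the recorded control `u_data(t)` and the
#' model control evaluated at the delayed state and time,
#' `pi_theta(y_data(t - delay), t - delay)`. The model control is zero while
#' the delayed time is inside the reaction period. The mean pools all samples
#' of all trials.
#'
#' @param theta parameter vector passed to `policy_factory`.
#' @param trials list of [trial()]s.
#' @param policy_factory e.g. [standard_policy_factory()] output.
#' @param window a [fit_window()].
#' @param config a [task_config()].
#' @return pooled mean squared error.
#' @export
mse_objective <- function(theta, trials, policy_factory, window, config) {
  stopifnot(length(trials) >= 1)
  check_window(window, config)
  pol <- policy_factory(theta)
  tt <- time_grid(config)
  idx <- which(tt >= window$t_start - 1e-9 & tt <= window$t_end + 1e-9)
  td <- tt[idx] - window$delay
  shift <- window$delay / config$dt
  whole <- abs(shift - round(shift)) < 1e-9
  active <- td >= config$reaction_time
  ss <- 0; n <- 0L
  for (tr in trials) {
    y_del <- if (whole) tr$y[idx - as.integer(round(shift))] else {
      stats::approx(tt, tr$y, xout = td)$y
    }
    u_pred <- numeric(length(idx))
    if (any(active)) u_pred[active] <- pol(y_del[active], td[active])
    r <- tr$u[idx] - u_pred
    ss <- ss + sum(r * r)
    n <- n + length(r)
  }
  ss / n
}

#' Optimizer settings for model fitting
#'
#' @param dy,du grid steps for extended-model policy solves.
#' @param alpha_bounds,pos_weight_bounds,steepness_bounds box constraints.
#' @param alpha_grid 1-D scan used to bracket the standard-model minimum.
#' @param seed_alpha,seed_pos_weight,seed_steepness coarse log-grid used to
#'   seed the extended-model simplex search.
#' @param nm_maxit,nm_reltol Nelder-Mead iteration cap and relative tolerance.
#' @param snap_tol the interior (`pos_weight > 0`) solution must beat the
#'   `pos_weight = 0` boundary profile by this relative margin on training MSE,
#'   otherwise the fit reduces to the standard model.
#' @return list of settings.
#' @export
fit_control <- function(dy = 0.005, du = 0.01,
                        alpha_bounds = c(0, 10),
                        pos_weight_bounds = c(0, 1000),
                        steepness_bounds = c(0.1, 50),
                        alpha_grid = c(0, 10^seq(-3, 1, length.out = 15)),
                        seed_alpha = 10^seq(-1.5, 0.5, length.out = 4),
                        seed_pos_weight = 10^seq(-1, 1.7, length.out = 4),
                        seed_steepness = 10^seq(0, 1.3, length.out = 4),
                        nm_maxit = 60, nm_reltol = 1e-3, snap_tol = 1e-3) {
  list(dy = dy, du = du, alpha_bounds = alpha_bounds,
       pos_weight_bounds = pos_weight_bounds, steepness_bounds = steepness_bounds,
       alpha_grid = alpha_grid, seed_alpha = seed_alpha,
       seed_pos_weight = seed_pos_weight, seed_steepness = seed_steepness,
       nm_maxit = nm_maxit, nm_reltol = nm_reltol, snap_tol = snap_tol)
}

fit_standard_model <- function(trials, window, config, control) {
  factory <- standard_policy_factory(config)
  f <- function(a) mse_objective(a, trials, factory, window, config)
  grid <- control$alpha_grid
  grid <- grid[grid >= control$alpha_bounds[1] & grid <= control$alpha_bounds[2]]
  vals <- vapply(grid, f, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  best_a <- grid[i]; best_v <- vals[i]
  if (hi > lo) {
    opt <- stats::optimize(f, c(lo, hi), tol = 1e-6)
    if (opt$objective < best_v) { best_a <- opt$minimum; best_v <- opt$objective }
  }
  structure(list(model = "standard", params = standard_params(alpha = best_a),
                 train_mse = best_v, test_mse = NA_real_, fold_id = NA_integer_,
                 diagnostics = list(converged = TRUE, n_eval = length(grid))),
            class = "fit_result")
}

fit_extended_model <- function(trials, window, config, control) {
  efact <- extended_policy_factory(config, dy = control$dy, du = control$du)
  fE <- function(th) mse_objective(th, trials, efact, window, config)
  # boundary profile: pos_weight = 0 is exactly the standard model
  std <- fit_standard_model(trials, window, config, control)
  seeds <- expand.grid(a = control$seed_alpha, w = control$seed_pos_weight,
                       s = control$seed_steepness)
  seed_vals <- apply(seeds, 1, function(r) fE(as.numeric(r)))
  j <- which.min(seed_vals)
  lb <- log10(c(max(control$alpha_bounds[1], 1e-4),
                max(control$pos_weight_bounds[1], 1e-4),
                control$steepness_bounds[1]))
  ub <- log10(c(control$alpha_bounds[2], control$pos_weight_bounds[2],
                control$steepness_bounds[2]))
  g <- function(lth) {
    if (any(lth < lb) || any(lth > ub)) return(1e10)
    fE(10^lth)
  }
  nm <- stats::optim(log10(as.numeric(seeds[j, ])), g, method = "Nelder-Mead",
                     control = list(maxit = control$nm_maxit,
                                    reltol = control$nm_reltol))
  int_theta <- 10^nm$par
  int_mse <- nm$value
  if (seed_vals[j] < int_mse) { int_theta <- as.numeric(seeds[j, ]); int_mse <- seed_vals[j] }
  reduced <- !(int_mse < std$train_mse * (1 - control$snap_tol))
  if (reduced) {
    params <- extended_params(alpha = std$params$alpha, pos_weight = 0,
                              pos_steepness = 1)
    train <- std$train_mse
  } else {
    params <- extended_params(alpha = int_theta[1], pos_weight = int_theta[2],
                              pos_steepness = int_theta[3])
    train <- int_mse
  }
  structure(list(model = "extended", params = params, train_mse = train,
                 test_mse = NA_real_, fold_id = NA_integer_,
                 diagnostics = list(converged = nm$convergence == 0,
                                    nm_convergence = nm$convergence,
                                    n_eval = nrow(seeds) + nm$counts[["function"]],
                                    reduced = reduced)),
            class = "fit_result")
}

#' Fit one cost model to a set of trials
#'
#' Minimizes the trajectory MSE ([mse_objective()]) over the model's free
#' parameters. The standard model has one parameter (`alpha`), minimized by a
#' log-spaced scan plus Brent refinement. The extended model has three
#' (`alpha`, `pos_weight`, `pos_steepness`), minimized by coarse log-grid
#' seeding followed by Nelder-Mead in log-parameter space, each evaluation
#' re-solving (or fetching from cache) the policy grid; the interior solution
#' is kept only if it beats the `pos_weight = 0` boundary profile on training
#' MSE beyond the optimizer's tolerance, otherwise the fit reduces to the
#' standard model. Deterministic given the settings. Non-convergence of the
#' simplex is flagged in `diagnostics`, never silent.
#'
#' @param trials list of [trial()]s (nonempty).
#' @param model `"standard"` or `"extended"`.
#' @param window a [fit_window()].
#' @param config a [task_config()].
#' @param control a [fit_control()].
#' @return object of class `"fit_result"`: `model`, `params`, `train_mse`,
#'   `diagnostics`.
#' @export
fit_model <- function(trials, model = c("standard", "extended"),
                      window = fit_window(), config, control = fit_control()) {
  model <- match.arg(model)
  stopifnot(length(trials) >= 1)
  if (model == "standard") fit_standard_model(trials, window, config, control)
  else fit_extended_model(trials, window, config, control)
}

#' @export
print.fit_result <- function(x, ...) {
  p <- x$params
  th <- if (x$model == "standard") sprintf("alpha = %.4g", p$alpha) else {
    sprintf("alpha = %.4g, pos_weight = %.4g, pos_steepness = %.4g",
            p$alpha, p$pos_weight, p$pos_steepness)
  }
  cat(sprintf("<fit_result> %s model: %s; train MSE = %.5g\n",
              x$model, th, x$train_mse))
  invisible(x)
}

#' Exact two-sided sign test on paired differences
#'
#' The model-comparison statistic: under the null that the paired differences
#' have median zero, the number of positive signs among the nonzero
#' differences is Binomial(n, 1/2). Zeros are dropped (the classical
#' conditional sign test); the two-sided p-value is twice the smaller tail,
#' capped at 1. If every difference is zero the test is vacuous and returns
#' p = 1 with a warning.
#'
#' @param diffs numeric vector of paired differences.
#' @return p-value in (0, 1].
#' @export
sign_test <- function(diffs) {
  stopifnot(length(diffs) >= 1)
  pos <- sum(diffs > 0); neg <- sum(diffs < 0)
  n <- pos + neg
  if (n == 0) {
    warning("all paired differences are zero; sign test is vacuous (p = 1)")
    return(1)
  }
  k <- min(pos, neg)
  min(1, 2 * stats::pbinom(k, n, 0.5))
}

#' Cross-validated comparison of the two cost models
#'
#' For each fold, 50 trials are drawn without replacement from the block; 45
#' of them train both models and the remaining 5 are held out. The paired
#' difference "test error of standard model minus test error of extended
#' model" is collected over folds, and an exact two-sided [sign_test()] asks
#' whether its median is zero. Positive differences favour the extended
#' model. Reproducible given `seed` and `control`.
#'
#' @param block a [trial_set()] with at least 50 trials.
#' @param window a [fit_window()].
#' @param n_folds number of folds (the full design uses 100).
#' @param seed integer seed for the fold draws.
#' @param control a [fit_control()].
#' @return object of class `"comparison_result"`: `condition`, `paired_diffs`,
#'   `median`, `q25`, `q75`, `sign_test_p`, per-fold fitted parameters.
#' @export
cross_validate <- function(block, window = fit_window(), n_folds = 100,
                           seed = 1L, control = fit_control()) {
  n <- length(block$trials)
  if (n < 50) stop(sprintf("cross_validate needs >= 50 trials, got %d", n))
  cfg <- block$config
  folds <- withr::with_seed(as.integer(seed), lapply(seq_len(n_folds), function(k) {
    sel <- sample.int(n, 50)
    perm <- sample(sel, 50)
    list(train = perm[1:45], test = perm[46:50])
  }))
  diffs <- numeric(n_folds)
  fits <- vector("list", n_folds)
  sfact <- standard_policy_factory(cfg)
  efact <- extended_policy_factory(cfg, dy = control$dy, du = control$du)
  for (k in seq_len(n_folds)) {
    train <- block$trials[folds[[k]]$train]
    test <- block$trials[folds[[k]]$test]
    fs <- fit_model(train, "standard", window, cfg, control)
    fe <- fit_model(train, "extended", window, cfg, control)
    ps <- fs$params; pe <- fe$params
    fs$test_mse <- mse_objective(ps$alpha, test, sfact, window, cfg)
    fe$test_mse <- mse_objective(c(pe$alpha, pe$pos_weight, pe$pos_steepness),
                                 test, efact, window, cfg)
    fs$fold_id <- fe$fold_id <- k
    diffs[k] <- fs$test_mse - fe$test_mse
    fits[[k]] <- list(standard = fs, extended = fe)
  }
  structure(list(
    condition = sprintf("%s %s", cfg$task_kind, block$block_label),
    paired_diffs = diffs,
    median = stats::median(diffs),
    q25 = unname(stats::quantile(diffs, 0.25)),
    q75 = unname(stats::quantile(diffs, 0.75)),
    sign_test_p = sign_test(diffs),
    n_folds = n_folds, window = window, fits = fits
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: median diff = %.4g [%.4g, %.4g], sign-test p = %.4g (%d folds)\n",
              x$condition, x$median, x$q25, x$q75, x$sign_test_p, x$n_folds))
  invisible(x)
}

#' Sensitivity of the model comparison to the sensorimotor delay
#'
#' Repeats the cross-validated comparison at each candidate delay (default
#' 0.15 s and 0.2 s, with identical fold draws) and tests whether the two
#' distributions of per-fold test-error differences share a median, using a
#' two-sided Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @param block a [trial_set()].
#' @param delays numeric vector of delays in seconds.
#' @param window base [fit_window()]; its `delay` is overridden.
#' @param n_folds,seed,control passed to [cross_validate()].
#' @return list with `delays`, the per-delay `comparisons`, and `p_value` of
#'   the rank-sum test between the first two delays.
#' @export
delay_sensitivity <- function(block, delays = c(0.15, 0.2),
                              window = fit_window(), n_folds = 100,
                              seed = 1L, control = fit_control()) {
  stopifnot(length(delays) >= 2)
  comps <- lapply(delays, function(d) {
    w <- fit_window(window$t_start, window$t_end, delay = d)
    cross_validate(block, w, n_folds = n_folds, seed = seed, control = control)
  })
  names(comps) <- sprintf("delay=%g", delays)
  p <- suppressWarnings(stats::wilcox.test(comps[[1]]$paired_diffs,
                                           comps[[2]]$paired_diffs,
                                           alternative = "two.sided")$p.value)
  list(delays = delays, comparisons = comps, p_value = p)
}

#' Per-time summaries of data and fitted-model traces
#'
#' Computes, at each sample time, the mean and standard deviation across
#' trials of the observed position and control, together with each fitted
#' model's predicted control evaluated along the observed (delayed) states,
#' zero before the reaction time. The block should be folded by symmetry
#' ([fold_by_symmetry()]) first so averages are meaningful.
#'
#' @param block a [trial_set()].
#' @param fits named list of [fit_model()] results (e.g.
#'   `list(standard = ..., extended = ...)`).
#' @param window a [fit_window()] (supplies the delay convention).
#' @return a tidy data frame with columns `t`, `series`, `variable`, `mean`,
#'   `sd`; model rows carry `variable = "u"` only.
#' @export
summarize_traces <- function(block, fits, window = fit_window()) {
  cfg <- block$config
  tt <- time_grid(cfg)
  nt <- length(tt)
  ymat <- vapply(block$trials, function(tr) tr$y, numeric(nt))
  umat <- vapply(block$trials, function(tr) tr$u, numeric(nt))
  rows <- list(
    data.frame(t = tt, series = "data", variable = "y",
               mean = rowMeans(ymat), sd = apply(ymat, 1, stats::sd)),
    data.frame(t = tt, series = "data", variable = "u",
               mean = rowMeans(umat), sd = apply(umat, 1, stats::sd))
  )
  shift <- as.integer(round(window$delay / cfg$dt))
  for (nm in names(fits)) {
    fit <- fits[[nm]]
    fact <- if (fit$model == "standard") standard_policy_factory(cfg) else
      extended_policy_factory(cfg)
    theta <- if (fit$model == "standard") fit$params$alpha else
      c(fit$params$alpha, fit$params$pos_weight, fit$params$pos_steepness)
    pol <- fact(theta)
    pred <- vapply(block$trials, function(tr) {
      up <- numeric(nt)
      for (k in seq_len(nt)) {
        kd <- k - shift
        tdk <- tt[k] - window$delay
        if (tdk >= cfg$reaction_time && kd >= 1 && tdk < cfg$T_final) {
          up[k] <- pol(tr$y[kd], tdk)
        }
      }
      up
    }, numeric(nt))
    rows[[length(rows) + 1L]] <-
      data.frame(t = tt, series = nm, variable = "u",
                 mean = rowMeans(pred), sd = apply(pred, 1, stats::sd))
  }
  do.call(rbind, rows)
}
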