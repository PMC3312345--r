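test_that("the MSE objective equals a hand-computed mean of squared residuals", {
  cfg <- toy_cfg()
  w <- fit_window(t_start = 0.3, t_end = 0.4, delay = 0.1)
  tt <- time_grid_for_tests(cfg)
  # two fabricated trials with simple ramps
  t1 <- trial(1, "s", tt, y = 0.1 * tt, u = rep(0.25, 21))
  t2 <- trial(2, "s", tt, y = -0.2 * tt, u = rep(-0.5, 21))
  factory <- function(theta) function(y, t) theta * y
  # spreadsheet oracle: residuals at t = 0.3, 0.35, 0.4 against policy on the
  # state two frames earlier
  oracle <- 0
  for (tr in list(t1, t2)) {
    for (tk in c(0.3, 0.35, 0.4)) {
      k <- which.min(abs(tt - tk))
      pred <- 2 * tr$y[k - 2]
      oracle <- oracle + (tr$u[k] - pred)^2
    }
  }
  oracle <- oracle / 6
  expect_equal(mse_objective(2, list(t1, t2), factory, w, cfg), oracle)
  # zero data, zero policy -> zero error
  t0 <- trial(3, "s", tt, y = rep(0, 21), u = rep(0, 21))
  expect_equal(mse_objective(0, list(t0), factory, w, cfg), 0)
  # windows that would need state before the delay are rejected
  expect_error(fit_window(t_start = 0.05, t_end = 0.4, delay = 0.1), "window")
  expect_error(mse_objective(2, list(t1), factory,
                             fit_window(0.3, 0.99, delay = 0.1), cfg), "window")
})

test_that("self-generated noiseless data gives zero MSE at the true parameters", {
  cfg <- one_target_cfg(nu = 0)
  bank <- make_noise_bank(2, 3, cfg)
  prof <- subject_profile("s", "standard", standard_params(alpha = 0.3),
                          motor_noise_sd = 0, seed = 1)
  blk <- generate_subject_block(prof, cfg, bank)
  factory <- standard_policy_factory(cfg)
  w <- fit_window()
  expect_lt(mse_objective(0.3, blk$trials, factory, w, cfg), 1e-20)
  # and the true value beats 50 random draws
  draws <- withr::with_seed(3, runif(50, 0, 10))
  vals <- vapply(draws, function(a) mse_objective(a, blk$trials, factory, w, cfg),
                 numeric(1))
  expect_true(all(vals >= 0))
  expect_lt(mse_objective(0.3, blk$trials, factory, w, cfg), min(vals))
})

test_that("the exact sign test matches closed forms and brute-force enumeration", {
  expect_equal(sign_test(rep(1, 6)), 2 * 0.5^6)
  expect_equal(sign_test(c(1, -1, 1, -1)), 1)
  expect_warning(p0 <- sign_test(rep(0, 5)), "vacuous")
  expect_equal(p0, 1)

  # enumeration oracle: P(|#pos - n/2| >= |observed|) over all sign patterns
  enum_p <- function(diffs) {
    d <- diffs[diffs != 0]
    n <- length(d)
    k_obs <- sum(d > 0)
    pats <- as.matrix(expand.grid(rep(list(0:1), n)))
    ks <- rowSums(pats)
    mean(abs(ks - n / 2) >= abs(k_obs - n / 2))
  }
  cases <- withr::with_seed(8, lapply(1:12, function(n) {
    sample(c(-2, -1, 1, 2), n, replace = TRUE)
  }))
  for (d in cases) expect_equal(sign_test(d), enum_p(d))
  # agrees with the exact binomial test (independent implementation)
  for (d in cases[vapply(cases, length, 1L) >= 3]) {
    bt <- binom.test(sum(d > 0), length(d), 0.5)$p.value
    expect_equal(sign_test(d), bt)
  }
})

test_that("the objective is invariant to trial order and to symmetry folding", {
  cfg <- one_target_cfg(nu = 0.04)
  blk <- make_block("standard", cfg, n_trials = 12)
  factory <- standard_policy_factory(cfg)
  w <- fit_window()
  base <- mse_objective(0.4, blk$trials, factory, w, cfg)
  expect_equal(mse_objective(0.4, rev(blk$trials), factory, w, cfg), base)
  folded <- fold_by_symmetry(blk)
  expect_equal(mse_objective(0.4, folded$trials, factory, w, cfg), base)
})

test_that("standard-model fitting recovers the generating alpha", {
  cfg <- one_target_cfg(nu = 0.04)
  blk <- make_block("standard", cfg, n_trials = 30, motor_noise_sd = 0.02)
  fit <- fit_model(blk$trials, "standard", fit_window(), cfg)
  expect_equal(fit$params$alpha, 0.3, tolerance = 0.15)
  expect_lt(fit$train_mse, 0.02^2 * 1.5)  # at the motor-noise floor
})

test_that("extended-model fitting recovers position-cost parameters and reduces cleanly", {
  clear_policy_cache()
  cfg <- one_target_cfg(nu = 0.04)
  w <- fit_window()
  blk_e <- make_block("extended", cfg, n_trials = 30)
  fe <- fit_model(blk_e$trials, "extended", w, cfg)
  expect_false(fe$diagnostics$reduced)
  expect_equal(fe$params$pos_weight, 2, tolerance = 0.5)
  expect_equal(fe$params$pos_steepness, 4, tolerance = 1)
  # the recovered policy reproduces the generating control surface over the
  # states the data actually visits (those are what trajectory MSE identifies)
  gen <- extended_params(alpha = 0.3, pos_weight = 2, pos_steepness = 4)
  pol_true <- policy_fun(solve_backward(gen, cfg))
  pol_fit <- policy_fun(solve_backward(fe$params, cfg))
  tt <- time_grid_for_tests(cfg)
  idx <- which(tt >= 0.8 & tt <= 2.8)
  sq <- unlist(lapply(blk_e$trials, function(tr) {
    td <- tt[idx] - 0.2; yd <- tr$y[idx - 15]
    (pol_true(yd, td) - pol_fit(yd, td))^2
  }))
  expect_lt(sqrt(mean(sq)), 0.05)

  # data from a standard subject: extended fit reduces to the standard model
  blk_s <- make_block("standard", cfg, n_trials = 30)
  fs <- fit_model(blk_s$trials, "standard", w, cfg)
  fe_s <- fit_model(blk_s$trials, "extended", w, cfg)
  expect_true(fe_s$diagnostics$reduced)
  expect_equal(fe_s$params$pos_weight, 0)
  expect_equal(fe_s$params$alpha, fs$params$alpha)
  expect_equal(fe_s$train_mse, fs$train_mse)
})

test_that("degenerate cross-validation (identical models) yields all ties and p = 1", {
  cfg <- one_target_cfg(nu = 0.04)
  blk <- make_block("standard", cfg, n_trials = 50, motor_noise_sd = 0)
  expect_error(cross_validate(trial_set(cfg, blk$trials[1:10]), n_folds = 2),
               ">= 50 trials")
  cmp <- suppressWarnings(cross_validate(blk, n_folds = 3, seed = 5))
  expect_equal(cmp$paired_diffs, rep(0, 3))
  expect_equal(cmp$sign_test_p, 1)
})

test_that("cross-validation is reproducible and favours the generating extended model", {
  clear_policy_cache()
  cfg <- one_target_cfg(nu = 0.04)
  blk <- make_block("extended", cfg, n_trials = 50)
  cmp1 <- cross_validate(blk, n_folds = 3, seed = 7)
  cmp2 <- cross_validate(blk, n_folds = 3, seed = 7)
  expect_identical(cmp1$paired_diffs, cmp2$paired_diffs)
  expect_true(all(cmp1$paired_diffs > 0))
  expect_gt(cmp1$median, 0)
})

test_that("identical delays give identical comparisons (rank-sum near 1)", {
  cfg <- one_target_cfg(nu = 0.04)
  blk <- make_block("extended", cfg, n_trials = 50)
  ds <- suppressWarnings(delay_sensitivity(blk, delays = c(0.2, 0.2),
                                           n_folds = 2, seed = 3))
  expect_identical(ds$comparisons[[1]]$paired_diffs,
                   ds$comparisons[[2]]$paired_diffs)
  expect_gt(ds$p_value, 0.5)
})

test_that("rank-sum delay comparison matches enumeration on a small example", {
  # 6 vs 6 toy: exact Mann-Whitney by enumerating all 924 assignments
  x <- c(1.1, 2.3, 0.7, 3.5, 1.9, 2.8)
  y <- c(2.0, 4.1, 3.3, 2.9, 5.0, 3.8)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[1:6]) - 6 * 7 / 2
  combs <- utils::combn(12, 6)
  all_r <- rank(c(x, y))
  ws <- apply(combs, 2, function(i) sum(all_r[i]) - 21)
  p_enum <- mean(abs(ws - 18) >= abs(w_obs - 18))
  p_wil <- wilcox.test(x, y, exact = TRUE)$p.value
  expect_equal(p_wil, p_enum)
})

test_that("trace summaries behave on degenerate and self-consistent inputs", {
  cfg <- one_target_cfg(nu = 0)
  bank <- make_noise_bank(13, 5, cfg)
  cfg_fixed <- cfg
  cfg_fixed$start_range <- 0.4
  prof <- subject_profile("s", "standard", standard_params(alpha = 0.3),
                          motor_noise_sd = 0, seed = 1)
  blk <- generate_subject_block(prof, cfg_fixed, bank)
  fit <- fit_model(blk$trials, "standard", fit_window(), cfg_fixed)
  tr <- summarize_traces(blk, list(standard = fit), fit_window())
  # identical trials -> zero spread everywhere
  expect_true(all(tr$sd < 1e-12))
  # model trace equals the recorded control inside the fitted window
  du <- merge(subset(tr, series == "data" & variable == "u"),
              subset(tr, series == "standard" & variable == "u"), by = "t")
  mid <- du$t >= 0.8 & du$t <= 2.8
  expect_lt(max(abs(du$mean.x[mid] - du$mean.y[mid])), 1e-3)
})
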