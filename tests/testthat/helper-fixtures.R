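# shared fixtures: small configs and canned subjects built in code

one_target_cfg <- function(nu = 0.04, ...) task_config("one_target", nu = nu, ...)
two_target_cfg <- function(nu = 0.04, ...) task_config("two_target", nu = nu, ...)

# a tiny, fast config for arithmetic-level tests (20 Hz, 1 s trials)
toy_cfg <- function(nu = 0, ...) {
  task_config("one_target", T_final = 1, dt = 0.05, nu = nu,
              start_range = c(-0.5, 0.5), reaction_time = 0.2, delay = 0.1, ...)
}

time_grid_for_tests <- function(cfg) (0:round(cfg$T_final / cfg$dt)) * cfg$dt

# deterministic small block from a synthetic subject
make_block <- function(model = "standard", cfg = one_target_cfg(),
                       n_trials = 20, bank_seed = 11, subj_seed = 5,
                       motor_noise_sd = 0.03, params = NULL) {
  if (is.null(params)) {
    params <- if (model == "standard") standard_params(alpha = 0.3) else
      extended_params(alpha = 0.3, pos_weight = 2, pos_steepness = 4)
  }
  bank <- make_noise_bank(bank_seed, n_trials, cfg)
  prof <- subject_profile("s1", model, params, motor_noise_sd = motor_noise_sd,
                          seed = subj_seed)
  generate_subject_block(prof, cfg, bank)
}
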