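# shared fixtures: load the frozen configuration once per test run
frozen_cfg <- load_model_config()

# a fast low-resolution simulation used where only coarse features matter
quick_sim <- function(cfg = frozen_cfg, dose = 80, interval = 24,
                      n_days = 14, subject = mean_subject(cfg), ...) {
  simulate_regimen(build_body_model(cfg, subject),
                   dose_regimen(dose, interval = interval, n_days = n_days),
                   ...)
}

# memoised baseline 80 mg OD x 14 d mean-subject simulation
base_sim_env <- new.env()
base_sim <- function() {
  if (is.null(base_sim_env$sim)) base_sim_env$sim <- quick_sim()
  base_sim_env$sim
}
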