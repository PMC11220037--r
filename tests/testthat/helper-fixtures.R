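# shared fixtures: plausible parameter sets, compact priors, tiny cohorts

fixture_params <- function() {
  ddm_parameters(
    v_0back = c(2.2, 2.7, 2.0), a_0back = 1.15, t0_0back = 0.33,
    st0_0back = 0.12, z_0back = 0.52, p_contam_0back = 0.03,
    v_2back = c(1.9, 2.4, 1.5), a_2back = 1.25, t0_2back = 0.40,
    st0_2back = 0.18, z_2back = 0.48, p_contam_2back = 0.05)
}

# informative priors centred on the generating population (fast to sample)
fixture_priors <- function() {
  b <- ddm_parameter_bounds()
  loc <- c(2.6, 3.0, 2.4, 1.1, 0.35, 0.15, 0.5, 0.05,
           1.6, 2.2, 1.2, 1.3, 0.38, 0.15, 0.5, 0.05)
  sc <- c(rep(0.9, 3), 0.3, 0.08, 0.08, 0.07, 0.06,
          rep(0.9, 3), 0.3, 0.08, 0.08, 0.07, 0.06)
  prior_spec(loc, sc, b$lower, b$upper, parameters = b$parameter)
}

fixture_trials <- function(params = fixture_params(), seed = 11,
                           schedule_seed = 5, dt = 1e-3) {
  sched <- build_task_schedule(seed = schedule_seed)
  set.seed(seed)
  simulate_trials(params, sched, dt = dt)
}

# one-row trial helper
one_trial <- function(condition, stimulus_class, response, rt = NA_real_) {
  data.frame(condition = condition, stimulus_class = stimulus_class,
             response = response, rt = rt, stringsAsFactors = FALSE)
}
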