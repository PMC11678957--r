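# Shared fixtures, all generated in code.

default_params <- function() model_parameters(4e-4, 1.2e-3, 1.5e-2, 1.9e-2)

# A generated sprint session smoothed back to the 1 Hz energy series.
prepared_sprint <- function(seed = 1L, noise = 0.02, ...) {
  ses <- gen_sprint_session(noise_sd_fraction = noise, seed = seed, ...)
  sm <- smooth_to_1hz(data.frame(t = ses$raw$timestamp, speed = ses$raw$speed))
  en <- speed_to_energy(sm, ses$athlete$mass)
  ses$smoothed <- sm
  ses$energy <- en
  # empirical measurement-noise floor against the generating trajectory
  ses$noise_floor <- cost_epsilon(ses$trajectory, en)
  ses
}

# Random demand square wave and bounded parameters for property tests.
random_step_demand <- function(duration = 60L, level_max = 1) {
  n_blocks <- sample(2:6, 1)
  edges <- sort(sample(1:(duration - 1), n_blocks))
  vals <- numeric(duration + 1)
  lv <- runif(n_blocks + 1, 0, level_max)
  lv[sample(seq_along(lv), 1)] <- 0 # ensure some rest
  idx <- findInterval(0:duration, edges) + 1
  demand_profile(lv[idx])
}

random_bounded_params <- function(m0, dt = 0.1) {
  b <- bounds_spec()
  lu <- function(rg) 10^runif(1, log10(rg[1]), log10(rg[2]))
  # keep the single-step overshoot bound dt*M0*rate < 1 satisfied
  bd_hi <- min(b$beta_d[2], 0.9 / (dt * m0))
  aa_hi <- min(b$alpha_a[2], 0.9 / (dt * m0))
  model_parameters(lu(c(b$alpha_a[1], max(aa_hi, 2e-5))),
                   lu(c(b$beta_d[1], max(bd_hi, 2e-5))),
                   lu(b$f), lu(b$r))
}
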