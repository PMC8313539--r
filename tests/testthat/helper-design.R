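# shared fixtures built in code

canonical <- default_design()

slow_cell <- function() design_cell(canonical, 5, 5)    # a=.106, v=.546
fast_cell <- function() design_cell(canonical, 1, 1)    # heavy guessing

# a small but fully populated single-subject dataset
tiny_dataset <- function(seed = 101, n = 40) {
  simulate_dataset(canonical, n_subjects = 1, n_trials_per_cell = n,
                   seed = seed, between_subject_sd = 0)
}

# random valid diffusion parameter sets spanning the canonical ranges
random_param_set <- function() {
  a <- runif(1, 0.05, 0.12)
  list(wiener = wiener_params(a = a, v = runif(1, 0.05, 0.6)),
       var = trial_variability(eta = runif(1, 0, 0.25),
                               sz = runif(1, 0, 0.4) * a,
                               ter = runif(1, 0.25, 0.45),
                               st = runif(1, 0, 0.15)))
}
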