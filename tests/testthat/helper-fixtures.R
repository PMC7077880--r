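# Shared fixtures, all generated in code.

# A bare two-stimulus trial table (context 1 of experiment 1) from explicit
# outcome vectors, alternating the two stimuli. Used by brute-force oracles.
two_stim_trials <- function(x_s, x_os, design = experiment_design(1)) {
  stopifnot(length(x_s) == length(x_os))
  n <- length(x_s)
  data.frame(
    session = "main",
    block_index = 0L,
    trial_index = 0:(2L * n - 1L),
    context_id = 1L,
    stimulus_id = rep(c(1L, 2L), n),
    true_prob = rep(design$stimuli$true_prob[1:2], n),
    outcome = as.integer(rbind(x_s, x_os)),
    magnitude = 0L,
    estimate_interval = NA_integer_,
    estimate_value = NA_real_,
    rt = NA_real_
  )
}

# Quick small cohort used by several suites.
small_cohort <- function(n = 4, experiment = 2, model = "URD-g",
                         params = list(gamma = 0.6, n_past = 30L),
                         noise_sd = 0.05, master_seed = 1234) {
  simulate_cohort(
    experiment_design(experiment), n,
    generative_agent(model, params, noise_sd = noise_sd),
    master_seed = master_seed
  )
}

# Replace a subject's main-session estimates with supplied values.
set_main_estimates <- function(subject, values) {
  tr <- subject$trials[order(subject$trials$trial_index), ]
  stopifnot(sum(tr$session == "main") == length(values))
  tr$estimate_value[tr$session == "main"] <- values
  subject$trials <- tr
  subject
}
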