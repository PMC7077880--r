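test_that("frequency matching makes realized main-session frequencies exact", {
  d2 <- experiment_design(2)
  for (seed in c(1, 99)) {
    oc <- generate_outcomes(d2, seed)
    n_main <- 40L
    counts <- vapply(oc$main, sum, integer(1))
    expect_equal(unname(counts),
                 as.integer(round(d2$stimuli$true_prob * n_main)))
    expect_true(all(lengths(oc$main) == n_main))
  }
  # warning when p * n is not an integer
  d_odd <- d2
  d_odd$stimuli$true_prob[1] <- 0.123
  expect_warning(generate_outcomes(d_odd, 1), "infeasible")
})

test_that("Bernoulli outcome sampling is unbiased", {
  d1 <- experiment_design(1)
  n_subj <- 10000L
  n_main <- 30L
  # direct binomial oracle: mean realized frequency within 3 SE of truth
  sums <- matrix(0, nrow = n_subj, ncol = 6)
  seeds <- contextprob:::derive_seeds(7, n_subj)
  for (i in seq_len(n_subj)) {
    oc <- generate_outcomes(d1, seeds[i])
    sums[i, ] <- vapply(oc$main, mean, numeric(1))
  }
  p <- d1$stimuli$true_prob
  se <- sqrt(p * (1 - p) / (n_main * n_subj))
  expect_true(all(abs(colMeans(sums) - p) < 3 * se))
})

test_that("degenerate certain-reward stimuli always pay out", {
  d <- experiment_design(1)
  d$stimuli$true_prob[] <- 1
  d$contexts$prob_lo[] <- 1 - 1e-9  # keep validation out of the way
  oc <- generate_outcomes(d, 5)
  expect_true(all(unlist(oc$pre) == 1))
  expect_true(all(unlist(oc$main) == 1))
})

test_that("simulated subjects are reproducible and structurally valid", {
  d1 <- experiment_design(1)
  ag <- generative_agent(seed = 321)
  s1 <- simulate_subject(d1, ag)
  s2 <- simulate_subject(d1, ag)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$choices, s2$choices)
  tr <- s1$trials
  # session structure: 120 pre + 180 main, balanced per stimulus
  expect_equal(sum(tr$session == "pre"), 120L)
  expect_equal(sum(tr$session == "main"), 180L)
  expect_true(all(table(tr$stimulus_id[tr$session == "main"]) == 30L))
  # within a block only that context's two stimuli appear
  for (b in unique(tr$block_index)) {
    blk <- tr[tr$block_index == b, ]
    expect_equal(length(unique(blk$context_id)), 1L)
    expect_setequal(
      unique(blk$stimulus_id),
      d1$stimuli$stimulus_id[d1$stimuli$context_id == blk$context_id[1]]
    )
  }
  # magnitudes accompany rewards only
  expect_true(all(tr$magnitude[tr$outcome == 1] %in% 1:5))
  expect_true(all(tr$magnitude[tr$outcome == 0] == 0L))
  # estimates are valid button presses
  expect_true(all(tr$estimate_interval %in% seq_len(d1$scheme$n_intervals)))
  expect_equal(tr$estimate_value,
               interval_midpoint(tr$estimate_interval, d1$scheme))
  # lottery block: 3 same-probability pairs x 20 + 12 others x 7
  expect_equal(nrow(s1$choices), 3L * 20L + 12L * 7L)
  expect_equal(sum(!is.na(s1$choices$pair_prob)), 60L)
})

test_that("a noiseless URD agent shows the reference-dependent ordering", {
  d1 <- experiment_design(1)
  st <- d1$stimuli
  id_lo <- st$stimulus_id[st$true_prob == 0.5 & st$partner_prob == 0.1]
  id_hi <- st$stimulus_id[st$true_prob == 0.5 & st$partner_prob == 0.9]
  for (seed in 1:5) {
    ag <- generative_agent("URD", list(n_past = 30L), noise_sd = 1e-9,
                           seed = seed)
    s <- simulate_subject(d1, ag)
    tr <- s$trials[s$trials$session == "main", ]
    m_lo <- mean(tr$estimate_value[tr$stimulus_id == id_lo])
    m_hi <- mean(tr$estimate_value[tr$stimulus_id == id_hi])
    expect_gt(m_lo, m_hi)
  }
})

test_that("a pure frequency tracker shows no context effect", {
  # DN-2 with a = 1, b = 0 is exactly the raw frequency: under
  # frequency-matched outcomes the two 50% stimuli get equal latent
  # estimates on average
  d2 <- experiment_design(2)
  coh <- simulate_cohort(
    d2, 40, generative_agent("DN-2", list(a = 1, b = 0, n_past = 30L),
                             noise_sd = 1e-9),
    master_seed = 88
  )
  cd <- context_delta(coh, 0.5, half = "all")
  expect_lt(abs(cd$group_mean), 0.02)
})

test_that("cohorts derive independent subject seeds and keep the truth", {
  d2 <- experiment_design(2)
  coh <- small_cohort(n = 5, master_seed = 555)
  expect_s3_class(coh, "cohort")
  expect_length(coh, 5L)
  seeds <- vapply(coh, function(s) s$agent_truth$seed, integer(1))
  expect_equal(anyDuplicated(seeds), 0L)
  # identical reruns
  coh2 <- small_cohort(n = 5, master_seed = 555)
  expect_identical(coh[[3]]$trials, coh2[[3]]$trials)
  # parameter sampler is honored and bounds are enforced
  coh3 <- simulate_cohort(d2, 3, generative_agent(),
                          master_seed = 1,
                          param_sampler = function(i) list(gamma = 0.4 + 0.1 * i,
                                                           n_past = 30L))
  expect_equal(vapply(coh3, function(s) s$agent_truth$params$gamma, numeric(1)),
               c(0.5, 0.6, 0.7))
  expect_error(
    simulate_cohort(d2, 2, generative_agent(), master_seed = 1,
                    param_sampler = function(i) list(gamma = -1)),
    "bounds"
  )
  # singleton cohort is valid
  expect_length(simulate_cohort(d2, 1, generative_agent(), master_seed = 2), 1L)
})

test_that("missing-response simulation produces NA estimates at the set rate", {
  d2 <- experiment_design(2)
  ag <- generative_agent(miss_rate = 0.2, seed = 9)
  s <- simulate_subject(d2, ag)
  miss <- mean(is.na(s$trials$estimate_value))
  expect_gt(miss, 0.1)
  expect_lt(miss, 0.3)
  expect_true(all(is.na(s$trials$estimate_interval[is.na(s$trials$estimate_value)])))
})

test_that("fitting the generating model recovers parameters and orderings", {
  d2 <- experiment_design(2)
  gammas <- seq(0.4, 1.0, length.out = 10)
  coh <- simulate_cohort(
    d2, 10, generative_agent("URD-g", list(gamma = 0.6, n_past = 30L),
                             noise_sd = 0.05),
    master_seed = 31,
    param_sampler = function(i) list(gamma = gammas[i], n_past = 30L)
  )
  fits <- lapply(coh, function(s) fit_model(s, "URD-g", n_past = 30))
  ghat <- vapply(fits, function(f) coef(f)[["gamma"]], numeric(1))
  expect_true(all(abs(ghat - gammas) <= 0.15))
  # the fitted models' predicted context deltas preserve the observed
  # per-subject ordering
  d50_obs <- context_delta(coh, 0.5)$per_subject
  pred_coh <- lapply(seq_along(coh), function(i) {
    s <- coh[[i]]
    ps <- predict(fits[[i]], s, sessions = "main")
    tr <- s$trials[order(s$trials$trial_index), ]
    tr$estimate_value[tr$session == "main"] <- ps$prediction
    s$trials <- tr
    s
  })
  attributes(pred_coh) <- attributes(coh)
  d50_fit <- context_delta(pred_coh, 0.5)$per_subject
  expect_gt(cor(d50_obs, d50_fit, method = "spearman"), 0.8)
})

test_that("written cohorts land on disk with a complete manifest", {
  dir <- withr::local_tempdir()
  coh <- small_cohort(n = 2)
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "subject_01_trials.csv")))
  expect_true(file.exists(file.path(dir, "subject_02_choices.csv")))
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                            simplifyVector = FALSE)
  expect_equal(man$n_subjects, 2L)
  expect_length(man$subjects, 2L)
  tr <- utils::read.csv(file.path(dir, "subject_01_trials.csv"))
  expect_named(tr, c("session", "block_index", "trial_index", "context_id",
                     "stimulus_id", "true_prob", "outcome", "magnitude",
                     "estimate_interval", "estimate_value", "rt"))
})
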