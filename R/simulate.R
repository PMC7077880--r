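# Synthetic subjects: seeded outcome sequences, model-driven interval
# estimates, and post-task lottery choices.

#' Define a generative agent
#'
#' An agent couples an estimation model (and its parameters) with report
#' noise and a lottery choice rule. On each trial the agent's model produces
#' a latent estimate from its own experienced history; Gaussian noise
#' (`noise_sd`) is added, the result is clipped to `[0, 1]` and discretised
#' to the design's report buttons. Lottery choices are sampled from a
#' softmax over the two stimuli's end-of-session model estimates with
#' inverse temperature `choice_temperature` (estimates live on a 0-1 scale,
#' so the default of 10 gives moderately reliable choices).
#'
#' @param model model name (see [model_registry()]) or [model_spec()].
#' @param params named list of model parameters; may include `n_past`
#'   (window framework, default 30) or `alpha` (RW framework).
#' @param noise_sd report noise SD, `> 0` (use a tiny value such as 1e-8 for
#'   an effectively noiseless agent).
#' @param choice_temperature softmax inverse temperature, `> 0`.
#' @param miss_rate probability that a trial's estimate is missing
#'   (default 0: every trial answered).
#' @param seed integer seed making the simulated subject fully reproducible.
#' @return An object of class `generative_agent`.
#' @export
generative_agent <- function(model = "URD-g", params = list(gamma = 0.6),
                             noise_sd = 0.05, choice_temperature = 10,
                             miss_rate = 0, seed = 1L) {
  spec <- if (inherits(model, "model_spec")) model else model_spec(model)
  stopifnot(noise_sd > 0, choice_temperature > 0,
            miss_rate >= 0, miss_rate < 1)
  structure(list(
    spec = spec, params = params, noise_sd = noise_sd,
    choice_temperature = choice_temperature, miss_rate = miss_rate,
    seed = as.integer(seed)
  ), class = "generative_agent")
}

#' Generate per-stimulus outcome sequences
#'
#' Pre-session outcomes are always i.i.d. Bernoulli draws at the stimulus's
#' true probability. Main-session outcomes are Bernoulli for
#' non-frequency-matched designs; for frequency-matched designs each
#' stimulus's realized main-session reward frequency equals its true
#' probability exactly (the reward count is `round(p * n)`, a permuted
#' fixed-count sequence), with a warning when `p * n` is not an integer.
#'
#' @param design an [experiment_design()].
#' @param seed integer seed.
#' @return A list with elements `pre` and `main`, each a list of binary
#'   vectors named by stimulus id.
#' @export
generate_outcomes <- function(design, seed) {
  with_seed(seed, generate_outcomes_rng(design))
}

# RNG-stream version used inside simulate_subject.
generate_outcomes_rng <- function(design) {
  st <- design$stimuli
  n_pre <- design$pre_trials_per_stimulus
  n_main <- design$main_trials_per_stimulus_per_block *
    design$main_blocks_per_context
  pre <- lapply(seq_len(nrow(st)), function(i) {
    stats::rbinom(n_pre, 1L, st$true_prob[i])
  })
  main <- lapply(seq_len(nrow(st)), function(i) {
    p <- st$true_prob[i]
    if (!design$frequency_matched) return(stats::rbinom(n_main, 1L, p))
    k <- round(p * n_main)
    if (abs(k - p * n_main) > 1e-8) {
      warning(sprintf(
        "frequency matching infeasible for p = %g over %d trials; using %d rewards",
        p, n_main, k
      ))
    }
    sample(rep(c(1L, 0L), c(k, n_main - k)))
  })
  names(pre) <- names(main) <- as.character(st$stimulus_id)
  list(pre = pre, main = main)
}

# Block / trial ordering for one subject (uses the current RNG stream).
# Pre: one block per context, order randomized; main: blocks_per_context
# repetitions of each context, order randomized; within a block the two
# stimuli are interleaved at random with fixed per-stimulus counts.
trial_skeleton <- function(design) {
  st <- design$stimuli
  mk_block <- function(ctx, per_stim, session, block_index) {
    ids <- st$stimulus_id[st$context_id == ctx]
    order <- sample(rep(ids, each = per_stim))
    data.frame(session = session, block_index = block_index,
               context_id = ctx, stimulus_id = order)
  }
  blocks <- list()
  bi <- 0L
  if (design$pre_trials_per_stimulus > 0L) {
    for (ctx in sample(design$contexts$context_id)) {
      blocks[[length(blocks) + 1L]] <-
        mk_block(ctx, design$pre_trials_per_stimulus, "pre", bi)
      bi <- bi + 1L
    }
  }
  main_seq <- sample(rep(design$contexts$context_id,
                         design$main_blocks_per_context))
  for (ctx in main_seq) {
    blocks[[length(blocks) + 1L]] <-
      mk_block(ctx, design$main_trials_per_stimulus_per_block, "main", bi)
    bi <- bi + 1L
  }
  out <- do.call(rbind, blocks)
  out$trial_index <- seq_len(nrow(out)) - 1L
  out
}

#' Simulate one subject
#'
#' Builds a full subject dataset: randomized block/trial ordering, outcome
#' sequences, the agent's trial-by-trial interval estimates, and lottery
#' choices over all stimulus pairs. Fully reproducible from `agent$seed`.
#'
#' @param design an [experiment_design()].
#' @param agent a [generative_agent()].
#' @param subject_id identifier stored in the result.
#' @return An object of class `subject_data`: list with `subject_id`,
#'   `design`, `trials` (one row per presentation: session, block_index,
#'   trial_index, context_id, stimulus_id, true_prob, outcome, magnitude,
#'   estimate_interval, estimate_value, rt), `choices` (pair_a, pair_b,
#'   pair_prob, chosen, trial_index) and `agent_truth`.
#' @export
simulate_subject <- function(design, agent, subject_id = 1L) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(agent, "generative_agent"))
  with_seed(agent$seed, {
    outc <- generate_outcomes_rng(design)
    tr <- trial_skeleton(design)
    st <- design$stimuli
    tr$true_prob <- st$true_prob[match(tr$stimulus_id, st$stimulus_id)]
    # consume each stimulus's outcome stream in presentation order
    tr$outcome <- NA_integer_
    for (s in st$stimulus_id) {
      key <- as.character(s)
      rows_pre <- which(tr$stimulus_id == s & tr$session == "pre")
      rows_main <- which(tr$stimulus_id == s & tr$session == "main")
      tr$outcome[rows_pre] <- outc$pre[[key]]
      tr$outcome[rows_main] <- outc$main[[key]]
    }
    tr$magnitude <- ifelse(
      tr$outcome == 1L,
      sample(design$reward_magnitudes, nrow(tr), replace = TRUE),
      0L
    )
    # latent model estimate -> noise -> clip -> button
    states <- trial_states(
      tr, design, framework = agent$spec$framework,
      n_past = agent$params$n_past %||% 30L,
      alpha = agent$params$alpha %||% 0.3, pool = TRUE
    )
    latent <- predict_core(states, agent$spec, agent$params)
    noisy <- clip01(latent + stats::rnorm(nrow(tr), 0, agent$noise_sd))
    tr$estimate_interval <- interval_of(noisy, design$scheme)
    tr$estimate_value <- interval_midpoint(tr$estimate_interval, design$scheme)
    if (agent$miss_rate > 0) {
      miss <- stats::runif(nrow(tr)) < agent$miss_rate
      tr$estimate_interval[miss] <- NA_integer_
      tr$estimate_value[miss] <- NA_real_
    }
    tr$rt <- NA_real_
    tr <- tr[, c("session", "block_index", "trial_index", "context_id",
                 "stimulus_id", "true_prob", "outcome", "magnitude",
                 "estimate_interval", "estimate_value", "rt")]
    choices <- simulate_choices_rng(tr, design, agent)
    structure(list(
      subject_id = subject_id, design = design, trials = tr,
      choices = choices, agent_truth = agent
    ), class = "subject_data")
  })
}

# Lottery block: end-of-session model estimates drive a softmax choice rule.
# Same-probability pairs are ordered so pair_a is the stimulus from the
# context with the lower-probability partner (the option expected to be
# preferred under reference-dependent inflation).
simulate_choices_rng <- function(trials, design, agent) {
  fin <- final_states(trials, design, framework = agent$spec$framework,
                      n_past = agent$params$n_past %||% 30L,
                      alpha = agent$params$alpha %||% 0.3)
  est <- predict_core(fin, agent$spec, agent$params)
  names(est) <- as.character(fin$stimulus_id)
  st <- design$stimuli
  pairs <- utils::combn(st$stimulus_id, 2)
  out <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    pa <- st$true_prob[st$stimulus_id == a]
    pb <- st$true_prob[st$stimulus_id == b]
    same <- isTRUE(all.equal(pa, pb))
    if (same) {
      # order by partner probability: lower-partner context first
      if (st$partner_prob[st$stimulus_id == a] >
          st$partner_prob[st$stimulus_id == b]) {
        tmp <- a; a <- b; b <- tmp
      }
    }
    n <- if (same) design$lottery_trials_same_prob_pair
         else design$lottery_trials_other_pair
    p_first <- stats::plogis(agent$choice_temperature *
                               (est[[as.character(a)]] - est[[as.character(b)]]))
    out[[j]] <- data.frame(
      pair_a = a, pair_b = b,
      pair_prob = if (same) pa else NA_real_,
      chosen = stats::rbinom(n, 1L, 1 - p_first)
    )
  }
  ch <- do.call(rbind, out)
  ch <- ch[sample.int(nrow(ch)), , drop = FALSE]
  ch$trial_index <- seq_len(nrow(ch)) - 1L
  rownames(ch) <- NULL
  ch
}

#' Simulate a cohort of subjects
#'
#' Derives independent per-subject seeds from `master_seed` and simulates
#' `n_subjects` datasets. Population heterogeneity is introduced through
#' `param_sampler`, a function of the subject index returning that subject's
#' model parameter list (default: every subject uses `agent`'s parameters).
#' The generating agents are retained in each dataset for recovery studies.
#'
#' @param design an [experiment_design()].
#' @param n_subjects cohort size, `>= 1`.
#' @param agent template [generative_agent()].
#' @param master_seed integer seed for the whole cohort.
#' @param param_sampler optional `function(i)` returning a parameter list;
#'   called inside the cohort's seeded stream.
#' @return An object of class `cohort`: a list of `subject_data` with
#'   attributes `design` and `master_seed`.
#' @export
simulate_cohort <- function(design, n_subjects, agent = generative_agent(),
                            master_seed = 1L, param_sampler = NULL) {
  stopifnot(n_subjects >= 1)
  seeds <- derive_seeds(master_seed, n_subjects)
  params_list <- with_seed(master_seed + 1L, {
    lapply(seq_len(n_subjects), function(i) {
      if (is.null(param_sampler)) agent$params else param_sampler(i)
    })
  })
  subjects <- lapply(seq_len(n_subjects), function(i) {
    ag <- agent
    ag$params <- check_param_bounds(agent$spec, params_list[[i]])
    ag$seed <- seeds[i]
    simulate_subject(design, ag, subject_id = i)
  })
  structure(subjects, class = "cohort", design = design,
            master_seed = as.integer(master_seed))
}

check_param_bounds <- function(spec, params) {
  info <- param_info(spec)
  for (i in seq_len(nrow(info))) {
    nm <- info$name[i]
    v <- params[[nm]]
    if (!is.null(v) && (v < info$lower[i] || v > info$upper[i])) {
      stop(sprintf("parameter `%s` = %g outside bounds [%g, %g]",
                   nm, v, info$lower[i], info$upper[i]))
    }
  }
  params
}

#' @export
print.subject_data <- function(x, ...) {
  cat(sprintf("<subject_data %s: %d trials, %d lottery choices (experiment %d)>\n",
              x$subject_id, nrow(x$trials), nrow(x$choices),
              x$design$experiment_id))
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d subjects, experiment %d, master seed %d>\n",
              length(x), attr(x, "design")$experiment_id,
              attr(x, "master_seed")))
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' Emits one trials CSV and one choices CSV per subject plus a manifest JSON
#' recording seeds and generating-model truth.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    n_subjects = length(cohort),
    experiment_id = attr(cohort, "design")$experiment_id,
    master_seed = attr(cohort, "master_seed"),
    subjects = lapply(cohort, function(s) {
      list(subject_id = s$subject_id, seed = s$agent_truth$seed,
           model = s$agent_truth$spec$name,
           params = s$agent_truth$params,
           noise_sd = s$agent_truth$noise_sd)
    })
  )
  for (s in cohort) {
    utils::write.csv(
      s$trials, file.path(dir, sprintf("subject_%02d_trials.csv", s$subject_id)),
      row.names = FALSE
    )
    utils::write.csv(
      s$choices, file.path(dir, sprintf("subject_%02d_choices.csv", s$subject_id)),
      row.names = FALSE
    )
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
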