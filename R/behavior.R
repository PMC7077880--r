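# Behavioral statistics: context-effect deltas, the trial-level frequency
# regression, choice-probability analysis and the permutation-count rule.

#' Context-effect delta for one reward probability
#'
#' For each subject, the mean estimate of the probability's stimulus in its
#' lower-partner context minus the mean estimate in its higher-partner
#' context, restricted to the requested portion of each stimulus's
#' main-session presentations. Positive values mean the estimate is inflated
#' when the context partner carries the lower reward probability.
#'
#' @param cohort a `cohort` (or list of `subject_data` sharing a design).
#' @param probability one of the design's reward probabilities.
#' @param half `"second"` (default), `"first"` or `"all"`: which half of
#'   each stimulus's main-session presentations enters the per-subject mean.
#' @return An object of class `context_delta`: `probability`, `half`,
#'   `per_subject` (named by subject id), `group_mean`.
#' @export
context_delta <- function(cohort, probability, half = c("second", "first",
                                                        "all")) {
  half <- match.arg(half)
  design <- attr(cohort, "design") %||% cohort[[1]]$design
  st <- design$stimuli
  rows <- st[abs(st$true_prob - probability) < 1e-9, , drop = FALSE]
  if (nrow(rows) != 2L) {
    stop("`probability` must be carried by exactly two stimuli of the design")
  }
  lo_stim <- rows$stimulus_id[which.min(rows$partner_prob)]
  hi_stim <- rows$stimulus_id[which.max(rows$partner_prob)]
  subj_mean <- function(s, sid) {
    tr <- s$trials[s$trials$session == "main" & s$trials$stimulus_id == sid, ]
    tr <- tr[order(tr$trial_index), ]
    n <- nrow(tr)
    keep <- switch(half,
      all = seq_len(n),
      first = seq_len(floor(n / 2)),
      second = seq.int(floor(n / 2) + 1L, n)
    )
    mean(tr$estimate_value[keep], na.rm = TRUE)
  }
  per <- vapply(cohort, function(s) {
    d <- subj_mean(s, lo_stim) - subj_mean(s, hi_stim)
    if (is.nan(d)) NA_real_ else d
  }, numeric(1))
  names(per) <- vapply(cohort, function(s) as.character(s$subject_id),
                       character(1))
  if (anyNA(per)) {
    warning(sprintf("%d subject(s) excluded: no valid trials in one context",
                    sum(is.na(per))))
    per <- per[!is.na(per)]
  }
  structure(list(
    probability = probability, half = half,
    per_subject = per, group_mean = mean(per)
  ), class = "context_delta")
}

#' @export
print.context_delta <- function(x, ...) {
  cat(sprintf(
    "<context_delta at %g%% reward (%s half): group mean %.4f over %d subjects>\n",
    100 * x$probability, x$half, x$group_mean, length(x$per_subject)
  ))
  invisible(x)
}

#' Trial-level frequency regression
#'
#' For one subject and one reward probability, regresses the trial-by-trial
#' estimates of the two stimuli carrying that probability on the
#' reward-history statistics `f_S(t; n_past)` and `f_overall(t; n_past)`,
#' without intercept. The window length is scanned over `n_past_range` and
#' the best fit (maximum R^2, equivalently minimum SSE) kept. Under the URD
#' model with a fixed context gain tau the coefficients identify
#' `beta_fS = 1 + tau` and `beta_foverall = -tau`, so
#' `delta = beta_fS - (1 - beta_foverall)` is 0.
#'
#' @param subject a `subject_data`.
#' @param probability a reward probability of the design.
#' @param n_past_range integer window lengths to scan (default 1..30).
#' @param intercept include an intercept (default FALSE, the regression as
#'   specified).
#' @param sessions sessions whose estimates enter the regression
#'   (default main session only; history always pools both).
#' @return An object of class `freq_regression`: `probability`, `beta_fS`,
#'   `beta_foverall`, `n_past`, `r_squared`, `delta`, `n_obs`.
#' @export
fit_frequency_regression <- function(subject, probability,
                                     n_past_range = 1:30,
                                     intercept = FALSE,
                                     sessions = "main") {
  stopifnot(inherits(subject, "subject_data"))
  design <- subject$design
  st <- design$stimuli
  sids <- st$stimulus_id[abs(st$true_prob - probability) < 1e-9]
  if (length(sids) != 2L) {
    stop("`probability` must be carried by exactly two stimuli of the design")
  }
  best <- NULL
  for (np in n_past_range) {
    states <- trial_states(subject$trials, design, framework = "window",
                           n_past = np, pool = TRUE)
    keep <- states$session %in% sessions & states$stimulus_id %in% sids
    est <- subject$trials$estimate_value[order(subject$trials$trial_index)][keep]
    ok <- !is.na(est)
    y <- est[ok]
    X <- cbind(f_S = states$f_S[keep][ok],
               f_overall = states$f_overall[keep][ok])
    if (intercept) X <- cbind(`(Intercept)` = 1, X)
    if (qr(X)$rank < ncol(X)) {
      stop("collinear regressors: f_S and f_overall are linearly dependent ",
           "for this window")
    }
    fit <- stats::lm.fit(X, y)
    sse <- sum(fit$residuals^2)
    r2 <- 1 - sse / sum(y^2)  # no-intercept R^2
    if (is.null(best) || r2 > best$r_squared) {
      cf <- fit$coefficients
      best <- list(
        probability = probability,
        beta_fS = unname(cf["f_S"]),
        beta_foverall = unname(cf["f_overall"]),
        intercept = if (intercept) unname(cf["(Intercept)"]) else NULL,
        n_past = as.integer(np),
        r_squared = r2,
        n_obs = length(y)
      )
    }
  }
  best$delta <- best$beta_fS - (1 - best$beta_foverall)
  class(best) <- "freq_regression"
  best
}

#' @export
print.freq_regression <- function(x, ...) {
  cat(sprintf(
    "<freq_regression at %g%%: beta_fS %.4f, beta_foverall %.4f, delta %.2e (n_past %d, R2 %.3f, n %d)>\n",
    100 * x$probability, x$beta_fS, x$beta_foverall, x$delta, x$n_past,
    x$r_squared, x$n_obs
  ))
  invisible(x)
}

#' Choice probability for a stimulus pair
#'
#' Fraction of the pair's lottery trials on which the first-listed option
#' was chosen. 0.5 means indifference.
#'
#' @param choices a choices data frame (see [simulate_subject()]).
#' @param pair length-2 vector of stimulus ids; order matters (the
#'   probability refers to the first element).
#' @return Scalar in `[0, 1]`.
#' @export
choice_probability <- function(choices, pair) {
  stopifnot(length(pair) == 2L)
  fwd <- choices$pair_a == pair[1] & choices$pair_b == pair[2]
  rev <- choices$pair_a == pair[2] & choices$pair_b == pair[1]
  n <- sum(fwd) + sum(rev)
  if (n == 0L) stop("no lottery trials for this pair")
  (sum(choices$chosen[fwd] == 0L) + sum(choices$chosen[rev] == 1L)) / n
}

# Cohort-level choice probabilities for the same-probability pairs:
# first option = stimulus from the lower-partner context.
same_prob_choice_probabilities <- function(cohort) {
  design <- attr(cohort, "design") %||% cohort[[1]]$design
  st <- design$stimuli
  probs <- sort(unique(st$true_prob))
  out <- lapply(probs, function(p) {
    rows <- st[abs(st$true_prob - p) < 1e-9, ]
    pair <- c(rows$stimulus_id[which.min(rows$partner_prob)],
              rows$stimulus_id[which.max(rows$partner_prob)])
    cp <- vapply(cohort, function(s) choice_probability(s$choices, pair),
                 numeric(1))
    data.frame(probability = p,
               subject = vapply(cohort, function(s) s$subject_id, numeric(1)),
               cp = cp)
  })
  do.call(rbind, out)
}

#' Model-based choice simulation
#'
#' Regenerates lottery choices from each subject's fitted model: the fitted
#' parameters produce end-of-session latent estimates from that subject's
#' experienced history, and choices are sampled from the softmax rule.
#' Returns per-pair, per-subject choice probabilities for the
#' same-probability pairs (first option = lower-partner-context stimulus).
#'
#' @param fits list of `cpfit` objects, one per subject of `cohort`.
#' @param cohort the cohort the fits belong to.
#' @param seed integer seed.
#' @param choice_temperature softmax inverse temperature.
#' @param n_trials_per_pair lottery trials simulated per pair; defaults to
#'   the design's same-probability pair count.
#' @return Data frame: `probability`, `subject`, `cp`.
#' @export
simulate_choice_probability <- function(fits, cohort, seed = 1L,
                                        choice_temperature = 10,
                                        n_trials_per_pair = NULL) {
  design <- attr(cohort, "design") %||% cohort[[1]]$design
  if (length(fits) != length(cohort)) {
    stop("need one fit per subject")
  }
  n_tr <- n_trials_per_pair %||% design$lottery_trials_same_prob_pair
  st <- design$stimuli
  probs <- sort(unique(st$true_prob))
  seeds <- derive_seeds(seed, length(cohort))
  rows <- list()
  for (i in seq_along(cohort)) {
    fit <- fits[[i]]
    if (!inherits(fit, "cpfit")) stop("missing fit for subject ", i)
    params <- fit$params
    if (fit$spec$framework == "window") params$n_past <- fit$n_past_selected
    fin <- final_states(cohort[[i]]$trials, design,
                        framework = fit$spec$framework,
                        n_past = params$n_past %||% 30L,
                        alpha = params$alpha %||% 0.3)
    est <- predict_core(fin, fit$spec, params)
    names(est) <- as.character(fin$stimulus_id)
    cps <- with_seed(seeds[i], {
      vapply(probs, function(p) {
        r <- st[abs(st$true_prob - p) < 1e-9, ]
        a <- r$stimulus_id[which.min(r$partner_prob)]
        b <- r$stimulus_id[which.max(r$partner_prob)]
        p_first <- stats::plogis(choice_temperature *
                                   (est[[as.character(a)]] -
                                      est[[as.character(b)]]))
        mean(stats::rbinom(n_tr, 1L, p_first))
      }, numeric(1))
    })
    rows[[i]] <- data.frame(probability = probs,
                            subject = cohort[[i]]$subject_id, cp = cps)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation count for Bonferroni-corrected voxelwise tests
#'
#' The number of label permutations needed so that the smallest achievable
#' p-value matches a Bonferroni-corrected threshold over `n_voxels` tests:
#' `1 / (alpha / n_voxels)`.
#'
#' @param n_voxels number of tested voxels, `>= 1`.
#' @param alpha significance level in (0, 1).
#' @return Integer permutation count.
#' @examples
#' permutation_count(1350)  # 27000
#' @export
permutation_count <- function(n_voxels, alpha = 0.05) {
  if (!is.numeric(n_voxels) || any(n_voxels < 1)) {
    stop("`n_voxels` must be >= 1")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)")
  }
  as.integer(round(n_voxels / alpha))
}
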