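# Maximum-likelihood fitting. Reports are modelled as Gaussian around the
# latent model prediction: the log-likelihood is
#   sum_i log N(obs_i; pred_i(theta), sigma_noise^2).
# sigma_noise is profiled analytically (its MLE is the RMS residual,
# clamped to [1e-4, 1]) so the numerical search runs only over the model's
# free parameters. BIC = ln(n) k - 2 ln(Lmax) with k counting the model's
# free parameters plus one for sigma_noise.

SIGMA_BOUNDS <- c(1e-4, 1)

#' Gaussian report likelihood
#'
#' Sum of Gaussian log-densities of observed estimates around model
#' predictions with a common noise SD. Missing observations must already be
#' excluded.
#'
#' @param observed,predicted equal-length numeric series in `[0, 1]`.
#' @param noise_sd report noise SD, `> 0`.
#' @return The log-likelihood (scalar).
#' @export
gaussian_loglik <- function(observed, predicted, noise_sd) {
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal length")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("`noise_sd` must be > 0")
  sum(stats::dnorm(observed, predicted, noise_sd, log = TRUE))
}

#' Bayesian information criterion
#'
#' `BIC = ln(n_trials) * k_free - 2 * loglik_max`.
#'
#' @param loglik_max maximized log-likelihood.
#' @param k_free number of free parameters (model parameters plus one for
#'   the report noise SD).
#' @param n_trials number of observations entering the likelihood.
#' @return The BIC (smaller is better).
#' @export
compute_bic <- function(loglik_max, k_free, n_trials) {
  stopifnot(n_trials >= 1)
  log(n_trials) * k_free - 2 * loglik_max
}

# ---- fitting surfaces -----------------------------------------------------
# A "fit surface" packages observed estimates with a prediction closure so
# that individual-subject and group-average fitting share one optimiser.
#
# Individual: observed = the subject's estimate series (estimate-bearing
# trials of the requested sessions); predicted = model predictions from that
# subject's history.
# Group: observed = across-subject mean estimate at the k-th presentation of
# each stimulus (main session); predicted = the same average over per-subject
# model predictions. `weights` supports bootstrap resamples (multiplicity of
# each subject) without reassembling the data.

surface_individual <- function(subject, sessions) {
  trials <- subject$trials
  keep <- trials$session %in% sessions & !is.na(trials$estimate_value)
  list(
    observed = trials$estimate_value[keep],
    n = sum(keep),
    states_for = function(spec, n_past, alpha) {
      st <- trial_states(trials, subject$design, framework = spec$framework,
                         n_past = n_past, alpha = alpha, pool = TRUE)
      st[keep, , drop = FALSE]
    },
    predicted = function(states, spec, params) {
      predict_core(states, spec, params, check = FALSE)
    }
  )
}

# Align each subject's main-session estimates by (stimulus, presentation
# index); designs fix the per-stimulus counts so the alignment is exact.
surface_group <- function(cohort, sessions = "main", weights = NULL) {
  design <- attr(cohort, "design")
  n_sub <- length(cohort)
  weights <- weights %||% rep(1 / n_sub, n_sub)
  align <- function(df) {
    df <- df[df$session %in% sessions, , drop = FALSE]
    ord <- order(df$stimulus_id, df$trial_index)
    df[ord, , drop = FALSE]
  }
  est_mat <- vapply(cohort, function(s) align(s$trials)$estimate_value,
                    numeric(nrow(align(cohort[[1]]$trials))))
  key <- align(cohort[[1]]$trials)[, c("stimulus_id", "context_id")]
  # weighted across-subject mean, skipping missing estimates
  w_mat <- matrix(weights, nrow = nrow(est_mat), ncol = n_sub, byrow = TRUE)
  w_mat[is.na(est_mat)] <- 0
  est_mat[is.na(est_mat)] <- 0
  obs <- rowSums(est_mat * w_mat) / pmax(rowSums(w_mat), 1e-12)
  list(
    observed = obs,
    n = length(obs),
    key = key,
    states_for = function(spec, n_past, alpha) {
      lapply(cohort, function(s) {
        st <- trial_states(s$trials, design, framework = spec$framework,
                           n_past = n_past, alpha = alpha, pool = TRUE)
        align(st)
      })
    },
    predicted = function(states, spec, params) {
      pred <- vapply(states, function(st) {
        predict_core(st, spec, params, check = FALSE)
      }, numeric(length(obs)))
      as.numeric(pred %*% weights) / sum(weights)
    }
  )
}

profiled_nll <- function(observed, predicted) {
  if (anyNA(predicted)) return(list(nll = 1e10, sigma = NA_real_))
  r <- observed - predicted
  sigma <- sqrt(mean(r^2))
  sigma <- min(max(sigma, SIGMA_BOUNDS[1]), SIGMA_BOUNDS[2])
  list(nll = -gaussian_loglik(observed, predicted, sigma), sigma = sigma)
}

# Optimize one model on one surface at a fixed window / with RW alpha free.
fit_one <- function(surface, spec, n_past, n_restarts, seed) {
  info <- param_info(spec)
  k_model <- nrow(info)
  window_states <- NULL
  if (spec$framework == "window") {
    window_states <- surface$states_for(spec, n_past, NULL)
  }
  obj <- function(theta) {
    if (any(theta < info$lower) || any(theta > info$upper)) return(1e10)
    params <- as.list(theta)
    names(params) <- info$name
    states <- if (spec$framework == "rw") {
      surface$states_for(spec, n_past, params$alpha)
    } else {
      window_states
    }
    pred <- surface$predicted(states, spec, params)
    val <- profiled_nll(surface$observed, pred)$nll
    if (!is.finite(val)) 1e10 else val
  }
  if (k_model == 0L) {
    pred <- surface$predicted(window_states, spec, list())
    pr <- profiled_nll(surface$observed, pred)
    return(list(params = list(), loglik = -pr$nll, sigma = pr$sigma,
                converged = TRUE))
  }
  starts <- with_seed(seed, {
    rand <- matrix(stats::runif(n_restarts * k_model, info$lower, info$upper),
                   ncol = k_model, byrow = TRUE)
    rand[1, ] <- info$init
    rand
  })
  # Simplex search from each start (robust to the flat regions that
  # clipping and denominator guards create), then a bounded quasi-Newton
  # polish. One-parameter models use golden-section search directly.
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    fitr <- tryCatch({
      if (k_model == 1L) {
        # the 1-D profile need not be unimodal: bracket the global optimum
        # with a coarse grid, then refine by golden-section
        grid <- seq(info$lower, info$upper, length.out = 41L)
        vals <- vapply(grid, obj, numeric(1))
        i <- which.min(vals)
        lo <- grid[max(1L, i - 1L)]
        hi <- grid[min(length(grid), i + 1L)]
        o <- stats::optimize(function(x) obj(x), c(lo, hi), tol = 1e-9)
        if (o$objective <= vals[i]) {
          list(par = o$minimum, value = o$objective, convergence = 0L)
        } else {
          list(par = grid[i], value = vals[i], convergence = 0L)
        }
      } else {
        nm <- stats::optim(starts[r, ], obj, method = "Nelder-Mead",
                           control = list(maxit = 1000))
        pol <- tryCatch(
          stats::optim(pmin(pmax(nm$par, info$lower), info$upper), obj,
                       method = "L-BFGS-B", lower = info$lower,
                       upper = info$upper, control = list(maxit = 200)),
          error = function(e) nm
        )
        if (pol$value <= nm$value) pol else nm
      }
    }, error = function(e) NULL)
    if (is.null(fitr)) next
    if (is.null(best) || fitr$value < best$value) best <- fitr
    if (k_model == 1L) break  # golden-section is start-independent
  }
  if (is.null(best)) {
    return(list(params = as.list(stats::setNames(rep(NA_real_, k_model),
                                                 info$name)),
                loglik = -Inf, sigma = NA_real_, converged = FALSE))
  }
  params <- as.list(best$par)
  names(params) <- info$name
  states <- if (spec$framework == "rw") {
    surface$states_for(spec, n_past, params$alpha)
  } else {
    window_states
  }
  pr <- profiled_nll(surface$observed,
                     surface$predicted(states, spec, params))
  list(params = params, loglik = -pr$nll, sigma = pr$sigma,
       converged = best$convergence == 0 && is.finite(pr$nll))
}

#' Fit an estimation model by maximum likelihood
#'
#' Fits any registered model to a single subject's estimate series or to a
#' cohort's group-average series, maximizing the Gaussian report likelihood
#' over the model's free parameters (bounded L-BFGS-B with seeded random
#' restarts; the noise SD is profiled analytically). In the window
#' framework, passing a vector `n_past` refits per window length and keeps
#' the window with the largest maximized likelihood.
#'
#' @param data a `subject_data` (individual fit) or `cohort` (group-average
#'   fit over the across-subject mean estimate at each presentation).
#' @param model model name (see [model_registry()]) or [model_spec()].
#' @param framework `"window"` or `"rw"`; ignored if `model` is already a
#'   `model_spec`.
#' @param n_past window length(s), each in 1..30 (window framework only).
#' @param uncertainty_stat `"sd"` or `"variance"` (URD family).
#' @param sessions sessions entering the likelihood. Defaults follow the
#'   fitting conventions for each framework: `"main"` for window models,
#'   both sessions for RW models.
#' @param n_restarts number of optimizer starts (first start at default
#'   values, the rest uniform within bounds).
#' @param seed seed for the restart draws.
#' @return An object of class `cpfit` with components `spec`, `params`
#'   (including `sigma_noise`), `loglik_max`, `n_trials`, `k_free`, `bic`,
#'   `n_past_selected`, `converged`, `n_restarts`, `seed`. Methods:
#'   [print()], [summary()], [coef()], [logLik()] (so [stats::BIC()] agrees
#'   with `$bic`), [predict()], [residuals()], [fitted()].
#' @examples
#' \donttest{
#' des <- experiment_design(2)
#' subj <- simulate_subject(des, generative_agent(seed = 7))
#' fit <- fit_model(subj, "URD", n_past = 30)
#' fit$bic
#' }
#' @export
fit_model <- function(data, model, framework = c("window", "rw"),
                      n_past = 30L, uncertainty_stat = c("sd", "variance"),
                      sessions = NULL, n_restarts = 10L, seed = 1L) {
  framework <- match.arg(framework)
  uncertainty_stat <- match.arg(uncertainty_stat)
  spec <- if (inherits(model, "model_spec")) model
          else model_spec(model, framework = framework,
                          uncertainty_stat = uncertainty_stat)
  sessions <- sessions %||%
    (if (spec$framework == "rw") c("pre", "main") else "main")
  surface <- if (inherits(data, "cohort")) {
    surface_group(data, sessions = sessions)
  } else if (inherits(data, "subject_data")) {
    surface_individual(data, sessions = sessions)
  } else {
    stop("`data` must be a subject_data or cohort object")
  }
  if (surface$n == 0L) stop("no estimate-bearing trials to fit")
  if (spec$framework == "rw") n_past <- NA_integer_
  grid <- if (spec$framework == "window") as.integer(n_past) else NA_integer_
  if (spec$framework == "window" &&
      (any(grid < 1L) || any(grid > 30L))) {
    stop("`n_past` values must lie in 1..30")
  }
  best <- NULL
  best_np <- NA_integer_
  for (np in grid) {
    res <- fit_one(surface, spec, np, n_restarts, seed)
    if (is.null(best) || res$loglik > best$loglik) {
      best <- res
      best_np <- np
    }
  }
  k_free <- nrow(param_info(spec)) + 1L
  fit <- list(
    spec = spec,
    params = c(best$params, list(sigma_noise = best$sigma)),
    loglik_max = best$loglik,
    n_trials = surface$n,
    k_free = k_free,
    bic = compute_bic(best$loglik, k_free, surface$n),
    n_past_selected = best_np,
    converged = best$converged,
    n_restarts = as.integer(n_restarts),
    seed = as.integer(seed),
    sessions = sessions,
    data_kind = if (inherits(data, "cohort")) "group" else "individual"
  )
  class(fit) <- "cpfit"
  fit
}
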