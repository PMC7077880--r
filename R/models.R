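# The estimation-model families.
#
# URD (uncertainty- and reference-dependent):
#   P = w + tau (w - f_overall),  w = f_S or its gamma-weighted transform,
#   tau = sigma_hat (or sigma_sq_hat); an optional loss-aversion multiplier
#   lambda scales the context term when w < f_overall. Clipped to [0, 1].
# DN-1 (divisive normalization): P = (a + f_S) / (b + f_S + f_OS).
# DN-2: P = a f_S / (1 + b f_overall).
# RN (range normalization):  P = (a + f_S) / (b + |f_S - f_OS|).
# DN/RN gamma variants apply the probability-weighting transform to the
# normalized (clipped) output; URD-gamma applies it to f_S before the
# context term.

#' Model registry
#'
#' The nine named models and their free parameters (excluding the report
#' noise SD, which every model carries):
#' \tabular{lll}{
#'   `URD`     \tab URD, tau = sigma_hat \tab none \cr
#'   `URD-g`   \tab + probability weighting \tab gamma \cr
#'   `URD-g-l` \tab + loss aversion \tab gamma, lambda \cr
#'   `DN-1`, `DN-2` \tab divisive normalization \tab a, b \cr
#'   `DN-1-g`, `DN-2-g` \tab + probability weighting \tab a, b, gamma \cr
#'   `RN`      \tab range normalization \tab a, b \cr
#'   `RN-g`    \tab + probability weighting \tab a, b, gamma
#' }
#' In the Rescorla-Wagner framework each model additionally carries the
#' learning rate `alpha`.
#'
#' @return Character vector of model names.
#' @export
model_registry <- function() {
  c("URD", "URD-g", "URD-g-l", "DN-1", "DN-2", "DN-1-g", "DN-2-g",
    "RN", "RN-g")
}

#' Resolve a model specification
#'
#' @param model a name from [model_registry()].
#' @param framework `"window"` (equal-weight sliding window over the last
#'   `n_past` outcomes) or `"rw"` (Rescorla-Wagner delta-rule trackers).
#' @param uncertainty_stat `"sd"` (tau = sigma_hat, the default) or
#'   `"variance"` (tau = sigma_hat^2), URD family only.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(model, framework = c("window", "rw"),
                       uncertainty_stat = c("sd", "variance")) {
  framework <- match.arg(framework)
  uncertainty_stat <- match.arg(uncertainty_stat)
  model <- match.arg(model, model_registry())
  family <- c("URD" = "URD", "URD-g" = "URD", "URD-g-l" = "URD",
              "DN-1" = "DN1", "DN-1-g" = "DN1", "DN-2" = "DN2",
              "DN-2-g" = "DN2", "RN" = "RN", "RN-g" = "RN")[[model]]
  structure(list(
    name = model,
    family = family,
    weighted = grepl("-g", model, fixed = TRUE),
    loss_averse = identical(model, "URD-g-l"),
    uncertainty_stat = uncertainty_stat,
    framework = framework
  ), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %s (%s framework, tau = %s)>\n",
              x$name, x$framework,
              if (x$uncertainty_stat == "sd") "sigma" else "sigma^2"))
  invisible(x)
}

# Free-parameter table (name, lower, upper, default start) for a spec.
param_info <- function(spec) {
  rows <- list()
  add <- function(name, lower, upper, init) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, lower = lower, upper = upper, init = init
    )
  }
  if (spec$family %in% c("DN1", "RN")) {
    add("a", -2, 2, 0.1)
    add("b", -2, 5, 1)
  } else if (spec$family == "DN2") {
    add("a", -2, 2, 1)
    add("b", -2, 5, 0.5)
  }
  if (spec$weighted) add("gamma", 0.01, 5, 1)
  if (spec$loss_averse) add("lambda", 0.01, 10, 1)
  if (spec$framework == "rw") add("alpha", 0, 1, 0.3)
  if (length(rows) == 0L) {
    return(data.frame(name = character(), lower = numeric(),
                      upper = numeric(), init = numeric()))
  }
  do.call(rbind, rows)
}

#' Probability-weighting transform
#'
#' The one-parameter weighting function
#' `w(f) = f^gamma / (f^gamma + (1 - f)^gamma)^(1/gamma)`.
#' For `0 < gamma < 1` small probabilities are overweighted and large ones
#' underweighted; `gamma = 1` is the identity, and the endpoints 0 and 1 are
#' fixed for every `gamma > 0`.
#'
#' @param f probability in `[0, 1]` (vectorised).
#' @param gamma curvature parameter, `> 0`.
#' @return Weighted probability in `[0, 1]`.
#' @export
weight_probability <- function(f, gamma) {
  if (!is.numeric(gamma) || gamma <= 0) stop("`gamma` must be > 0")
  stop_if_not_scalar_prob(f, "f")
  fg <- f^gamma
  fg / (fg + (1 - f)^gamma)^(1 / gamma)
}

# Vectorised model prediction from a frequency-state table. Internal core
# shared by the exported per-family predictors, the simulator and the
# fitting objective. Returns predictions clipped to [0, 1]; `check = TRUE`
# raises errors on invalid denominators, `check = FALSE` returns NA there
# (the optimiser penalises those parameter values).
predict_core <- function(state, spec, params, check = TRUE) {
  f_S <- state$f_S
  f_OS <- state$f_OS
  fo <- state$f_overall %||% ((f_S + f_OS) / 2)
  eps <- 1e-10
  weight_out <- function(p) {
    p <- clip01(p)
    if (!spec$weighted) return(p)
    ok <- !is.na(p)
    p[ok] <- weight_probability(p[ok], params$gamma)
    p
  }
  if (spec$family == "URD") {
    tau <- if (spec$uncertainty_stat == "sd") sqrt(f_S * (1 - f_S))
           else f_S * (1 - f_S)
    w <- if (spec$weighted) weight_probability(f_S, params$gamma) else f_S
    d <- w - fo
    gain <- rep(1, length(d))
    if (spec$loss_averse) gain[d < 0] <- params$lambda
    return(clip01(w + gain * tau * d))
  }
  if (spec$family == "DN1") {
    den <- params$b + f_S + f_OS
    if (any(den <= eps)) {
      if (check) stop("DN-1 denominator b + f_S + f_OS must be positive")
      den[den <= eps] <- NA_real_
    }
    return(weight_out((params$a + f_S) / den))
  }
  if (spec$family == "DN2") {
    den <- 1 + params$b * fo
    if (any(den <= eps)) {
      if (check) stop("DN-2 denominator 1 + b f_overall must be positive")
      den[den <= eps] <- NA_real_
    }
    return(weight_out(params$a * f_S / den))
  }
  # RN
  den <- params$b + abs(f_S - f_OS)
  if (any(den <= eps)) {
    if (check) stop("RN denominator b + range must be positive")
    den[den <= eps] <- NA_real_
  }
  weight_out((params$a + f_S) / den)
}

#' URD-family prediction
#'
#' `P = w + tau (w - f_overall)` clipped to `[0, 1]`, where `w` is `f_S` or
#' its gamma-weighted transform and `tau` is the outcome SD (or variance)
#' implied by `f_S`. With loss aversion the context term is multiplied by
#' `lambda` when `w < f_overall`.
#'
#' @param state a [frequency_state()] (one or more rows).
#' @param spec a URD-family [model_spec()]; defaults to plain `URD`.
#' @param params named list of the spec's free parameters (`gamma`,
#'   `lambda` as applicable).
#' @return Predicted probability estimate(s) in `[0, 1]`.
#' @examples
#' st <- frequency_state(f_S = 0.5, f_OS = 0.1)  # f_overall = 0.3
#' predict_urd(st)  # 0.5 + 0.5 * 0.2 = 0.6
#' @export
predict_urd <- function(state, spec = model_spec("URD"), params = list()) {
  stopifnot(spec$family == "URD")
  predict_core(state, spec, params)
}

#' Divisive-normalization predictions
#'
#' `predict_dn1` computes `(a + f_S) / (b + f_S + f_OS)`; `predict_dn2`
#' computes `a f_S / (1 + b f_overall)`. Results are clipped to `[0, 1]`;
#' when `gamma` is supplied the probability-weighting transform is applied
#' to the clipped output.
#'
#' With `a = b = 0`, `predict_dn1` is the parameter-free divisive
#' normalization `f_S / (f_S + f_OS)`.
#'
#' @param state a [frequency_state()].
#' @param params named list with `a`, `b` and optionally `gamma`.
#' @return Predicted probability estimate(s).
#' @examples
#' predict_dn1(frequency_state(0.1, 0.5), list(a = 0, b = 0))  # 0.1667
#' predict_dn1(frequency_state(0.9, 0.5), list(a = 0, b = 0))  # 0.6429
#' @export
predict_dn1 <- function(state, params = list(a = 0, b = 0)) {
  spec <- model_spec(if (is.null(params$gamma)) "DN-1" else "DN-1-g")
  predict_core(state, spec, params)
}

#' @rdname predict_dn1
#' @export
predict_dn2 <- function(state, params = list(a = 1, b = 0)) {
  spec <- model_spec(if (is.null(params$gamma)) "DN-2" else "DN-2-g")
  predict_core(state, spec, params)
}

#' Range-normalization prediction
#'
#' `(a + f_S) / (b + max(f_S, f_OS) - min(f_S, f_OS))`, clipped to `[0, 1]`,
#' optionally gamma-weighted.
#'
#' @inheritParams predict_dn1
#' @export
predict_rn <- function(state, params = list(a = 0, b = 1)) {
  spec <- model_spec(if (is.null(params$gamma)) "RN" else "RN-g")
  predict_core(state, spec, params)
}

#' Model predictions over a recorded trial sequence
#'
#' Evolves the history state over a subject's trials (window statistics or
#' Rescorla-Wagner trackers, per the spec's framework) and returns one
#' latent model prediction per trial, in presentation order. Statistics for
#' trial t use outcomes up to trial t - 1; pre- and main-session history is
#' pooled by default.
#'
#' @param subject a subject dataset from [simulate_subject()], or a trial
#'   data frame with the same columns plus an `experiment_design` in
#'   `design`.
#' @param model model name (see [model_registry()]) or a [model_spec()].
#' @param params named list of free parameters; for the window framework
#'   `n_past` (default 30) may be included, for the RW framework `alpha`.
#' @param design required when `subject` is a bare trial data frame.
#' @param sessions which sessions to return predictions for (history always
#'   pools the sessions in `pool`).
#' @param pool pool pre- and main-session outcomes when forming history
#'   statistics (default TRUE).
#' @return A data frame: `trial_index`, `stimulus_id`, the frequency state
#'   and the model `prediction`.
#' @export
predict_series <- function(subject, model, params = list(), design = NULL,
                           sessions = c("pre", "main"), pool = TRUE) {
  trials <- if (is.data.frame(subject)) subject else subject$trials
  design <- design %||% subject$design
  stopifnot(inherits(design, "experiment_design"))
  spec <- if (inherits(model, "model_spec")) model else model_spec(model)
  st <- trial_states(
    trials, design, framework = spec$framework,
    n_past = params$n_past %||% 30L, alpha = params$alpha %||% 0.3,
    pool = pool
  )
  st <- st[st$session %in% sessions, , drop = FALSE]
  st$prediction <- predict_core(st, spec, params)
  st
}
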