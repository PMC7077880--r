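# S3 methods for fitted models.

#' @export
print.cpfit <- function(x, ...) {
  cat(sprintf("<cpfit %s (%s framework, %s data)>\n",
              x$spec$name, x$spec$framework, x$data_kind))
  cat(sprintf("  logLik %.3f on %d trials; k = %d; BIC = %.3f\n",
              x$loglik_max, x$n_trials, x$k_free, x$bic))
  if (!is.na(x$n_past_selected)) {
    cat(sprintf("  selected window: %d past trials\n", x$n_past_selected))
  }
  cat("  coefficients:\n")
  print(round(coef(x), 4))
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.cpfit <- function(object, ...) {
  unlist(object$params)
}

#' @export
logLik.cpfit <- function(object, ...) {
  structure(object$loglik_max, df = object$k_free, nobs = object$n_trials,
            class = "logLik")
}

#' @export
summary.cpfit <- function(object, ...) {
  out <- list(
    model = object$spec$name,
    framework = object$spec$framework,
    coefficients = coef(object),
    loglik = object$loglik_max,
    n_trials = object$n_trials,
    k_free = object$k_free,
    bic = object$bic,
    n_past = object$n_past_selected,
    converged = object$converged
  )
  class(out) <- "summary.cpfit"
  out
}

#' @export
print.summary.cpfit <- function(x, ...) {
  cat(sprintf("Model: %s (%s framework)\n", x$model, x$framework))
  cat(sprintf("Log-likelihood: %.4f  (n = %d, k = %d)\nBIC: %.4f\n",
              x$loglik, x$n_trials, x$k_free, x$bic))
  if (!is.na(x$n_past)) cat(sprintf("Selected window: %d\n", x$n_past))
  cat("Coefficients:\n")
  print(x$coefficients)
  invisible(x)
}

#' Predictions from a fitted model
#'
#' Recomputes the latent model predictions for a subject's trials under the
#' fitted parameters (and selected window, for window-framework fits).
#'
#' @param object a `cpfit`.
#' @param newdata a `subject_data`; required for group-level fits.
#' @param sessions sessions to predict for; defaults to the fit's sessions.
#' @param ... unused.
#' @return A data frame from [predict_series()] with a `prediction` column.
#' @export
predict.cpfit <- function(object, newdata, sessions = NULL, ...) {
  stopifnot(inherits(newdata, "subject_data"))
  sessions <- sessions %||% object$sessions
  params <- object$params
  if (object$spec$framework == "window") {
    params$n_past <- object$n_past_selected
  }
  predict_series(newdata, object$spec, params, sessions = sessions)
}

#' @export
residuals.cpfit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    stop("residuals require the data: pass `newdata = <subject_data>`")
  }
  ps <- predict.cpfit(object, newdata)
  tr <- newdata$trials[order(newdata$trials$trial_index), ]
  tr <- tr[tr$session %in% (object$sessions), ]
  keep <- !is.na(tr$estimate_value)
  tr$estimate_value[keep] - ps$prediction[ps$trial_index %in% tr$trial_index[keep]]
}
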