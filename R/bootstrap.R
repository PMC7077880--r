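# Nonparametric bootstrap inference: subject-resampling confidence
# intervals for scalar statistics and for group-level BIC.

new_bootstrap_result <- function(stat_name, point, ci, n_boot, seed,
                                 significant, extra = list()) {
  structure(c(list(
    stat_name = stat_name, point = point,
    ci_low = ci[[1]], ci_high = ci[[2]],
    n_boot = as.integer(n_boot), seed = as.integer(seed),
    significant = significant
  ), extra), class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap %s: point %.4f, 95%% CI [%.4f, %.4f] (%d resamples)%s>\n",
              x$stat_name, x$point, x$ci_low, x$ci_high, x$n_boot,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Nonparametric bootstrap test for a subject-level statistic
#'
#' Resamples subjects with replacement, recomputes the mean of the supplied
#' per-subject values for each resample, and returns the 95% percentile
#' confidence interval. The statistic is flagged significant (alpha = 0.05)
#' when `null_value` falls outside the interval.
#'
#' @param values per-subject statistics (length >= 2).
#' @param null_value null value tested against (default 0).
#' @param n_boot number of resamples (default 10000).
#' @param seed integer seed.
#' @return A `bootstrap_result` with the point estimate (sample mean), CI
#'   bounds and significance flag.
#' @export
bootstrap_test <- function(values, null_value = 0, n_boot = 10000L,
                           seed = 1L) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  means <- with_seed(seed, {
    idx <- sample.int(n, n * n_boot, replace = TRUE)
    colMeans(matrix(values[idx], nrow = n))
  })
  ci <- stats::quantile(means, c(0.025, 0.975), names = FALSE)
  new_bootstrap_result(
    "mean", mean(values), ci, n_boot, seed,
    significant = null_value < ci[1] || null_value > ci[2],
    extra = list(null_value = null_value)
  )
}

#' Bootstrap confidence interval for group-level BIC
#'
#' Resamples the subject pool with replacement; for each resample the
#' group-average estimate series is recomputed (resampled subjects weighted
#' by multiplicity), the model refit, and the BIC recorded. Returns the 95%
#' percentile CI of the BIC distribution. Refits keep the supplied window
#' length fixed. Non-convergent resamples are excluded and counted.
#'
#' @param cohort a `cohort` (size >= 2).
#' @param model model name or [model_spec()].
#' @param n_boot number of resamples; the default mirrors full-scale use,
#'   desk-scale analyses typically use a few hundred.
#' @param seed integer seed.
#' @param n_past fixed window length for the refits.
#' @param n_restarts optimizer restarts per refit (fewer than a full fit;
#'   each refit starts near plausible optima anyway).
#' @return A `bootstrap_result` with the full-sample BIC as point estimate
#'   and extra fields `n_failed` and `bics`.
#' @export
bootstrap_bic <- function(cohort, model, n_boot = 10000L, seed = 1L,
                          n_past = 30L, n_restarts = 3L) {
  stopifnot(inherits(cohort, "cohort"), length(cohort) >= 2L)
  spec <- if (inherits(model, "model_spec")) model else model_spec(model)
  full <- fit_model(cohort, spec, n_past = n_past, seed = seed)
  n_sub <- length(cohort)
  seeds <- derive_seeds(seed, n_boot + 1L)
  bics <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- with_seed(seeds[b], sample.int(n_sub, n_sub, replace = TRUE))
    w <- tabulate(idx, nbins = n_sub) / n_sub
    surface <- surface_group(cohort, weights = w)
    res <- fit_one(surface, spec, n_past, n_restarts, seeds[n_boot + 1L])
    if (res$converged) {
      k <- nrow(param_info(spec)) + 1L
      bics[b] <- compute_bic(res$loglik, k, surface$n)
    }
  }
  ok <- bics[!is.na(bics)]
  if (length(ok) < 2L) stop("too few convergent bootstrap refits")
  ci <- stats::quantile(ok, c(0.025, 0.975), names = FALSE)
  new_bootstrap_result(
    paste0("BIC[", spec$name, "]"), full$bic, ci, n_boot, seed,
    significant = NA,
    extra = list(n_failed = sum(is.na(bics)), bics = ok,
                 model = spec$name, fit = full)
  )
}

#' Rank models and flag indistinguishable pairs
#'
#' Orders fits (or bootstrap BIC results) by BIC and flags models whose 95%
#' CIs overlap the best model's as "not significantly different".
#'
#' @param fits a list of `cpfit` and/or `bootstrap_result` objects from
#'   [bootstrap_bic()], all fit to the same series definition.
#' @return A data frame of class `model_comparison`: `model`, `bic`,
#'   `ci_low`, `ci_high`, `rank`, `overlaps_best`.
#' @export
compare_models <- function(fits) {
  rows <- lapply(fits, function(f) {
    if (inherits(f, "bootstrap_result")) {
      data.frame(model = f$model, bic = f$point,
                 ci_low = f$ci_low, ci_high = f$ci_high,
                 n_trials = f$fit$n_trials)
    } else if (inherits(f, "cpfit")) {
      data.frame(model = f$spec$name, bic = f$bic,
                 ci_low = NA_real_, ci_high = NA_real_,
                 n_trials = f$n_trials)
    } else {
      stop("`fits` must contain cpfit or bootstrap_result objects")
    }
  })
  out <- do.call(rbind, rows)
  if (length(unique(out$n_trials)) != 1L) {
    stop("fits use different series definitions (n_trials differ)")
  }
  out <- out[order(out$bic), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  best <- out[1, ]
  out$overlaps_best <- if (all(is.na(out$ci_low))) {
    NA
  } else {
    !(out$ci_low > best$ci_high | out$ci_high < best$ci_low)
  }
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (ascending BIC; overlaps_best flags 95% CI overlap",
      "with the best model):\n")
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}
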