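# Reward-history statistics: the frequency state that every estimation model
# reads. For a trial t and stimulus S the state holds
#   f_S       reward frequency of S over its recent presentations,
#   f_OS      the same for the other stimulus of the context,
#   f_overall (f_S + f_OS) / 2, the context's reference point,
#   sigma_hat sqrt(f_S (1 - f_S)), the Bernoulli outcome SD implied by f_S.
# Statistics for trial t use outcomes strictly before t (the estimate is
# given before that trial's feedback); a never-seen stimulus contributes the
# uninformative prior 0.5.

#' Construct a frequency state
#'
#' A frequency state carries the reward-history statistics that the
#' estimation models consume. `f_overall` defaults to the mean of `f_S` and
#' `f_OS`; the outcome SD `sigma_hat` is derived from `f_S` as the Bernoulli
#' population value `sqrt(f_S (1 - f_S))`.
#'
#' @param f_S reward frequency of the current stimulus, in `[0, 1]`
#'   (vectorised).
#' @param f_OS reward frequency of the other stimulus in the context.
#' @param f_overall reference point; defaults to `(f_S + f_OS) / 2`.
#' @return A data frame with columns `f_S`, `f_OS`, `f_overall`,
#'   `sigma_hat`, `sigma_sq_hat`.
#' @examples
#' frequency_state(f_S = 0.5, f_OS = 0.1)
#' @export
frequency_state <- function(f_S, f_OS, f_overall = NULL) {
  stop_if_not_scalar_prob(f_S, "f_S")
  stop_if_not_scalar_prob(f_OS, "f_OS")
  f_overall <- f_overall %||% ((f_S + f_OS) / 2)
  data.frame(
    f_S = f_S, f_OS = f_OS, f_overall = f_overall,
    sigma_hat = sqrt(f_S * (1 - f_S)),
    sigma_sq_hat = f_S * (1 - f_S)
  )
}

# Rolling reward frequency *before* each presentation.
# x: the stimulus's outcome sequence in presentation order.
# Returns length(x) + 1 values; element j is the frequency over the last
# min(n_past, j - 1) outcomes before the j-th presentation (0.5 when j = 1).
freq_before_window <- function(x, n_past) {
  m <- length(x)
  s <- c(0, cumsum(x))
  j <- seq_len(m + 1L)
  lo <- pmax(0L, j - 1L - n_past)
  cnt <- (j - 1L) - lo
  out <- rep(0.5, m + 1L)
  nz <- cnt > 0L
  out[nz] <- (s[j[nz]] - s[lo[nz] + 1L]) / cnt[nz]
  out
}

# Rescorla-Wagner tracker value before each presentation: delta-rule update
# f <- f + alpha (x - f) after each outcome, initialized at 0.5.
freq_before_rw <- function(x, alpha) {
  if (length(x) == 0L) return(0.5)
  y <- stats::filter(alpha * x, 1 - alpha, method = "recursive", init = 0.5)
  c(0.5, as.numeric(y))
}

#' Window statistics for a single trial
#'
#' Computes the frequency state of one stimulus presentation from a trial
#' table, using the last `n_past` presentations of each stimulus strictly
#' before trial `t`. This is the single-trial reference form;
#' [predict_series()] uses an equivalent vectorised path.
#'
#' @param trials a trial data frame (see [simulate_subject()]), ordered by
#'   `trial_index`.
#' @param t the `trial_index` of the presentation of interest.
#' @param stimulus_id stimulus presented at `t`.
#' @param n_past window length, 1..30.
#' @param design the [experiment_design()] (identifies the context partner).
#' @return A one-row frequency state (see [frequency_state()]).
#' @export
window_stats <- function(trials, t, stimulus_id, n_past, design) {
  stopifnot(n_past >= 1, n_past <= 30)
  row <- which(trials$trial_index == t)
  if (length(row) != 1L || trials$stimulus_id[row] != stimulus_id) {
    stop("`t` must index a presentation of `stimulus_id`")
  }
  other <- partner_of(design, stimulus_id)
  past <- trials[seq_len(row - 1L), , drop = FALSE]
  tail_freq <- function(sid) {
    x <- past$outcome[past$stimulus_id == sid]
    if (length(x) == 0L) return(0.5)
    mean(utils::tail(x, n_past))
  }
  frequency_state(f_S = tail_freq(stimulus_id), f_OS = tail_freq(other))
}

#' One Rescorla-Wagner update
#'
#' Updates the presented stimulus's frequency tracker by the delta rule
#' `f_S <- f_S + alpha (outcome - f_S)` and recomputes the derived
#' statistics. The other stimulus's tracker is untouched.
#'
#' @param state a one-row frequency state ([frequency_state()]).
#' @param outcome 0 or 1.
#' @param alpha learning rate in `[0, 1]`.
#' @return The updated frequency state.
#' @examples
#' st <- frequency_state(f_S = 0.5, f_OS = 0.1)
#' rw_update(st, outcome = 1, alpha = 0.2)$f_S  # 0.6
#' @export
rw_update <- function(state, outcome, alpha) {
  stopifnot(alpha >= 0, alpha <= 1, outcome %in% c(0, 1))
  f <- state$f_S + alpha * (outcome - state$f_S)
  frequency_state(f_S = f, f_OS = state$f_OS)
}

partner_of <- function(design, stimulus_id) {
  st <- design$stimuli
  ctx <- st$context_id[match(stimulus_id, st$stimulus_id)]
  vapply(seq_along(stimulus_id), function(i) {
    ids <- st$stimulus_id[st$context_id == ctx[i]]
    ids[ids != stimulus_id[i]]
  }, integer(1))
}

# Frequency states for every row of a trial table (vectorised).
# framework "window" uses the equal-weight rolling window (n_past);
# "rw" uses per-stimulus delta-rule trackers (alpha). History pools the
# pre- and main sessions (pool = TRUE) or main only.
trial_states <- function(trials, design, framework = c("window", "rw"),
                         n_past = 30L, alpha = NULL, pool = TRUE) {
  framework <- match.arg(framework)
  tr <- trials[order(trials$trial_index), , drop = FALSE]
  if (!pool) tr <- tr[tr$session == "main", , drop = FALSE]
  sids <- design$stimuli$stimulus_id
  fb <- lapply(sids, function(s) {
    x <- tr$outcome[tr$stimulus_id == s]
    if (framework == "window") freq_before_window(x, n_past)
    else freq_before_rw(x, alpha)
  })
  names(fb) <- as.character(sids)
  # presentation counts: for each row, how often each stimulus occurred before
  n <- nrow(tr)
  f_S <- numeric(n)
  f_OS <- numeric(n)
  other <- partner_of(design, tr$stimulus_id)
  cnt <- integer(max(sids))
  for (i in seq_len(n)) {
    s <- tr$stimulus_id[i]
    o <- other[i]
    f_S[i] <- fb[[as.character(s)]][cnt[s] + 1L]
    f_OS[i] <- fb[[as.character(o)]][cnt[o] + 1L]
    cnt[s] <- cnt[s] + 1L
  }
  st <- frequency_state(f_S = f_S, f_OS = f_OS)
  cbind(
    tr[, c("session", "trial_index", "context_id", "stimulus_id"),
       drop = FALSE],
    st
  )
}

# Final (end-of-session) frequency state per stimulus, used for lottery
# choices: statistics over each stimulus's full recorded history.
final_states <- function(trials, design, framework = c("window", "rw"),
                         n_past = 30L, alpha = NULL) {
  framework <- match.arg(framework)
  sids <- design$stimuli$stimulus_id
  f_end <- vapply(sids, function(s) {
    x <- trials$outcome[trials$stimulus_id == s]
    if (length(x) == 0L) return(0.5)
    if (framework == "window") mean(utils::tail(x, n_past))
    else utils::tail(freq_before_rw(x, alpha), 1)
  }, numeric(1))
  st <- frequency_state(f_S = f_end, f_OS = f_end[match(partner_of(design, sids),
                                                        sids)])
  cbind(data.frame(stimulus_id = sids), st)
}
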