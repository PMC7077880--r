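#' Interval-button report schemes
#'
#' Probability estimates in the task are reported by pressing one of a fixed
#' set of buttons, each covering an interval of probabilities. Two schemes are
#' used: the 8-button scheme with boundaries
#' (0, .05, .20, .35, .50, .65, .80, .95, 1), and the 10-button scheme with a
#' boundary every 10%. Intervals are half-open `[lo, hi)` except the last,
#' which is closed at 1.
#'
#' @param n_buttons 8 or 10, or a numeric vector of custom boundaries
#'   (strictly increasing, starting at 0 and ending at 1).
#' @return An object of class `interval_scheme` with elements `boundaries`
#'   and `n_intervals`.
#' @examples
#' sch <- interval_scheme(8)
#' interval_of(0.5, sch)       # 5: [0.50, 0.65)
#' interval_midpoint(5, sch)   # 0.575
#' @export
interval_scheme <- function(n_buttons = 8) {
  if (length(n_buttons) == 1L) {
    boundaries <- switch(as.character(n_buttons),
      "8"  = c(0, .05, .20, .35, .50, .65, .80, .95, 1),
      "10" = seq(0, 1, by = 0.1),
      stop("only the 8- and 10-button schemes are predefined; ",
           "pass explicit boundaries otherwise")
    )
  } else {
    boundaries <- as.numeric(n_buttons)
  }
  if (boundaries[1] != 0 || boundaries[length(boundaries)] != 1 ||
      any(diff(boundaries) <= 0)) {
    stop("boundaries must increase strictly from 0 to 1")
  }
  structure(
    list(boundaries = boundaries, n_intervals = length(boundaries) - 1L),
    class = "interval_scheme"
  )
}

#' @export
print.interval_scheme <- function(x, ...) {
  cat(sprintf("<interval_scheme: %d buttons>\n", x$n_intervals))
  cat("boundaries:", paste(format(x$boundaries), collapse = " "), "\n")
  invisible(x)
}

#' Map a probability to its report interval
#'
#' @param p probability (vectorised), in `[0, 1]`.
#' @param scheme an [interval_scheme()].
#' @return Integer interval index in `1..n_intervals`. Intervals are
#'   `[lo, hi)`; the last interval is closed so `interval_of(1, scheme)`
#'   returns `n_intervals`.
#' @export
interval_of <- function(p, scheme) {
  stopifnot(inherits(scheme, "interval_scheme"))
  stop_if_not_scalar_prob(p, "p")
  findInterval(p, scheme$boundaries, rightmost.closed = TRUE)
}

#' Midpoint of a report interval
#'
#' The numeric value assigned to an interval report when a point estimate is
#' needed (e.g. in the Gaussian likelihood): the midpoint of the interval,
#' which is unbiased under a uniform within-interval prior.
#'
#' @param i interval index (vectorised), in `1..n_intervals`.
#' @param scheme an [interval_scheme()].
#' @return Numeric midpoint(s).
#' @export
interval_midpoint <- function(i, scheme) {
  stopifnot(inherits(scheme, "interval_scheme"))
  i <- as.integer(i)
  if (any(is.na(i)) || any(i < 1L) || any(i > scheme$n_intervals)) {
    stop("interval index out of range")
  }
  (scheme$boundaries[i] + scheme$boundaries[i + 1L]) / 2
}

# Context table for a probability triplet: each probability appears in
# exactly two of the three pairwise contexts.
context_table <- function(prob_triplet) {
  p <- sort(prob_triplet)
  pairs <- list(c(p[1], p[2]), c(p[1], p[3]), c(p[2], p[3]))
  contexts <- data.frame(
    context_id = 1:3,
    prob_lo = vapply(pairs, `[`, numeric(1), 1),
    prob_hi = vapply(pairs, `[`, numeric(1), 2)
  )
  stimuli <- data.frame(
    stimulus_id = 1:6,
    context_id = rep(1:3, each = 2),
    true_prob = c(t(cbind(contexts$prob_lo, contexts$prob_hi)))
  )
  stimuli$partner_prob <- stimuli$true_prob[c(2, 1, 4, 3, 6, 5)]
  list(contexts = contexts, stimuli = stimuli)
}

#' Build one of the six experiment designs
#'
#' Encodes the six stimulus--reward experiments: three reward probabilities,
#' each carried by two distinct stimuli experienced in two different
#' two-stimulus contexts, a blocked main session, an optional pre-session,
#' interval-button probability reports, and a post-task lottery-choice block.
#'
#' Experiment 1 uses probabilities (.1, .5, .9), the 8-button scheme, a
#' pre-session of 3 blocks x 40 trials (20 per stimulus), a main session of
#' 6 blocks x 30 trials (15 per stimulus, 2 blocks per context), and
#' i.i.d. Bernoulli outcomes. Experiments 2-6 use the 10-button scheme,
#' 40 main trials per stimulus (2 blocks per context of 20), and
#' frequency-matched outcomes (each stimulus's realized main-session reward
#' frequency equals its true probability exactly). The probability triplets
#' are: Exp 2 and 6 (.1, .5, .9); Exp 3 (.1, .3, .5); Exp 4 (.5, .7, .9);
#' Exp 5 (.3, .5, .7). Experiments 5 and 6 are incentivized for estimation
#' accuracy. Lottery blocks use 20 trials per same-probability pair and 7 per
#' remaining pair in all designs.
#'
#' @param experiment_id integer in 1..6.
#' @return An object of class `experiment_design`.
#' @examples
#' d <- experiment_design(1)
#' d$contexts
#' @export
experiment_design <- function(experiment_id) {
  if (!is.numeric(experiment_id) || length(experiment_id) != 1L ||
      !(experiment_id %in% 1:6)) {
    stop("`experiment_id` must be an integer in 1..6")
  }
  experiment_id <- as.integer(experiment_id)
  triplet <- switch(experiment_id,
    c(.1, .5, .9),  # 1
    c(.1, .5, .9),  # 2
    c(.1, .3, .5),  # 3
    c(.5, .7, .9),  # 4
    c(.3, .5, .7),  # 5
    c(.1, .5, .9)   # 6
  )
  ct <- context_table(triplet)
  des <- list(
    experiment_id = experiment_id,
    prob_triplet = triplet,
    contexts = ct$contexts,
    stimuli = ct$stimuli,
    pre_trials_per_stimulus = if (experiment_id == 1L) 20L else 0L,
    main_trials_per_stimulus_per_block = if (experiment_id == 1L) 15L else 20L,
    main_blocks_per_context = 2L,
    scheme = interval_scheme(if (experiment_id == 1L) 8 else 10),
    reward_magnitudes = 1:5,
    frequency_matched = experiment_id != 1L,
    incentivized = experiment_id %in% c(5L, 6L),
    lottery_trials_same_prob_pair = 20L,
    lottery_trials_other_pair = 7L
  )
  class(des) <- "experiment_design"
  validate_design(des)
  des
}

validate_design <- function(des) {
  stopifnot(inherits(des, "experiment_design"))
  st <- des$stimuli
  if (anyDuplicated(st$stimulus_id)) stop("stimulus ids must be unique")
  counts <- table(st$true_prob)
  if (!all(counts == 2L)) {
    stop("each probability of the triplet must appear in exactly two contexts")
  }
  with(des$contexts, {
    if (any(prob_lo >= prob_hi)) stop("context reward probabilities must differ")
  })
  if (des$main_trials_per_stimulus_per_block < 1L ||
      des$main_blocks_per_context < 1L) {
    stop("main-session trial counts must be positive")
  }
  invisible(des)
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "<experiment_design %d: probabilities {%s}, %d-button scheme>\n",
    x$experiment_id, paste(x$prob_triplet, collapse = ", "),
    x$scheme$n_intervals
  ))
  cat(sprintf(
    "  pre: %d trials/stimulus; main: %d block(s)/context x %d trials/stimulus%s\n",
    x$pre_trials_per_stimulus, x$main_blocks_per_context,
    x$main_trials_per_stimulus_per_block,
    if (x$frequency_matched) "; frequency-matched outcomes" else ""
  ))
  print(x$contexts, row.names = FALSE)
  invisible(x)
}

#' Serialize / restore an experiment design
#'
#' Designs round-trip through a plain JSON representation so that users can
#' define variants in configuration files.
#'
#' @param design an [experiment_design()].
#' @param path file to write to (`design_to_json`) or read from
#'   (`design_from_json`); `design_to_json(path = NULL)` returns the JSON
#'   string.
#' @return `design_from_json` returns an `experiment_design`.
#' @export
design_to_json <- function(design, path = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  x <- unclass(design)
  x$scheme <- list(boundaries = design$scheme$boundaries)
  json <- jsonlite::toJSON(x, dataframe = "columns", auto_unbox = TRUE,
                           digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}

#' @rdname design_to_json
#' @export
design_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  x$scheme <- interval_scheme(x$scheme$boundaries)
  x$contexts <- as.data.frame(x$contexts)
  x$stimuli <- as.data.frame(x$stimuli)
  ints <- c("experiment_id", "pre_trials_per_stimulus",
            "main_trials_per_stimulus_per_block", "main_blocks_per_context",
            "lottery_trials_same_prob_pair", "lottery_trials_other_pair")
  for (f in ints) x[[f]] <- as.integer(x[[f]])
  x$reward_magnitudes <- as.integer(x$reward_magnitudes)
  class(x) <- "experiment_design"
  validate_design(x)
  x
}
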