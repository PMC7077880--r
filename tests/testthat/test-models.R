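test_that("probability weighting has the right shape and fixed points", {
  f <- seq(0, 1, by = 0.05)
  # identity at gamma = 1, fixed endpoints for all gamma
  expect_equal(weight_probability(f, 1), f)
  for (g in c(0.3, 0.61, 1, 2.5)) {
    expect_equal(weight_probability(0, g), 0)
    expect_equal(weight_probability(1, g), 1)
    # strictly increasing
    w <- weight_probability(f, g)
    expect_true(all(diff(w) > 0))
    # complement symmetry w(f) + w(1-f) = 1 holds only at gamma = 1
    sym <- weight_probability(0.3, g) + weight_probability(0.7, g)
    if (g == 1) expect_equal(sym, 1) else expect_false(isTRUE(all.equal(sym, 1)))
  }
  # small probabilities are overweighted for gamma < 1
  expect_gt(weight_probability(0.1, 0.6), 0.1)
  # frozen value from an independent arbitrary-precision evaluation
  expect_equal(weight_probability(0.1, 0.61), 0.186302566377174,
               tolerance = 1e-12)
  expect_error(weight_probability(0.5, 0), "gamma")
  expect_error(weight_probability(1.5, 1), "\\[0, 1\\]")
})

test_that("URD predictions combine frequency, reference and uncertainty", {
  # reference term vanishes when f_S equals the context mean
  st <- frequency_state(f_S = 0.4, f_OS = 0.4)
  expect_equal(predict_urd(st), 0.4)
  # hand-computed: 0.5 + sigma(0.5) * (0.5 - 0.3) = 0.6
  expect_equal(predict_urd(frequency_state(0.5, 0.1)), 0.6)
  # a deterministic stimulus is immune to context (sigma gates the term)
  expect_equal(predict_urd(frequency_state(1, 0.2)), 1)
  expect_equal(predict_urd(frequency_state(0, 0.9)), 0)
  # variance variant uses sigma^2: 0.5 + 0.25 * 0.2 = 0.55
  spec_v <- model_spec("URD", uncertainty_stat = "variance")
  expect_equal(predict_urd(frequency_state(0.5, 0.1), spec_v), 0.55)
  # loss aversion multiplies only negative context terms
  spec_l <- model_spec("URD-g-l")
  below <- frequency_state(0.5, 0.9)  # w - f_overall = -0.2
  above <- frequency_state(0.5, 0.1)
  p_below <- predict_urd(below, spec_l, list(gamma = 1, lambda = 2))
  p_above <- predict_urd(above, spec_l, list(gamma = 1, lambda = 2))
  expect_equal(p_below, 0.5 + 0.5 * 2 * (-0.2))
  expect_equal(p_above, 0.6)
})

test_that("divisive and range normalization match their closed forms", {
  pf <- list(a = 0, b = 0)
  expect_equal(round(predict_dn1(frequency_state(0.1, 0.5), pf), 3), 0.167)
  expect_equal(predict_dn1(frequency_state(0.1, 0.9), pf), 0.1)
  expect_equal(predict_dn1(frequency_state(0.9, 0.1), pf), 0.9)
  expect_equal(round(predict_dn1(frequency_state(0.9, 0.5), pf), 3), 0.643)
  expect_error(predict_dn1(frequency_state(0.2, 0.3), list(a = 0, b = -1)),
               "denominator")
  # DN-2 reduces to the raw frequency at a = 1, b = 0
  expect_equal(predict_dn2(frequency_state(0.3, 0.8), list(a = 1, b = 0)), 0.3)
  expect_equal(predict_dn2(frequency_state(0.5, 0.5), list(a = 2, b = 2)), 0.5)
  # large b drives DN-2 to zero
  expect_lt(predict_dn2(frequency_state(0.5, 0.5), list(a = 1, b = 500)), 0.01)
  # RN: range 0 leaves only b in the denominator
  expect_equal(predict_rn(frequency_state(0.4, 0.4), list(a = 0, b = 1)), 0.4)
  expect_equal(predict_rn(frequency_state(0.5, 0.1), list(a = 0, b = 0.5)),
               0.5 / 0.9)
  expect_error(predict_rn(frequency_state(0.4, 0.4), list(a = 0, b = 0)),
               "denominator")
  # clipping engages when the numerator exceeds the denominator
  expect_equal(predict_rn(frequency_state(0.9, 0.8), list(a = 1, b = 0.2)), 1)
})

test_that("all predictions stay in [0, 1] across parameter sweeps", {
  set.seed(42)
  st <- frequency_state(f_S = runif(200), f_OS = runif(200))
  grids <- list(
    list(name = "URD-g-l", ps = list(gamma = 0.3, lambda = 5)),
    list(name = "URD-g", ps = list(gamma = 3)),
    list(name = "DN-1-g", ps = list(a = 1.5, b = 0.4, gamma = 0.5)),
    list(name = "DN-2-g", ps = list(a = 2, b = 4, gamma = 2)),
    list(name = "RN-g", ps = list(a = 1, b = 0.6, gamma = 0.7))
  )
  for (g in grids) {
    p <- contextprob:::predict_core(st, model_spec(g$name), g$ps)
    expect_true(all(p >= 0 & p <= 1), info = g$name)
  }
})

test_that("URD is monotone in f_S and its context effect peaks at 50%", {
  fo <- 0.5
  fs <- c(.1, .3, .5, .7, .9)
  st <- frequency_state(f_S = fs, f_OS = 2 * fo - fs)  # f_overall = 0.5
  p <- predict_urd(st)
  expect_true(all(diff(p) > 0))
  # |prediction - f_S| is largest at f_S = 0.5 for a fixed reference offset
  # (the uncertainty gain sigma_hat peaks at 50%)
  st_off <- frequency_state(fs, fs, f_overall = fs - 0.2)
  offs <- abs(predict_urd(st_off) - fs)
  expect_equal(which.max(offs), 3L)
  expect_true(all(offs[3] > offs[-3]))
})

test_that("window statistics and RW updates follow their update rules", {
  d1 <- experiment_design(1)
  tr <- two_stim_trials(c(1, 0, 1, 1, 0), c(0, 0, 1, 0, 0))
  # at the 5th presentation of S (trial 8), history is (1,0,1,1): f_S = 0.75
  st <- window_stats(tr, t = 8L, stimulus_id = 1L, n_past = 4, design = d1)
  expect_equal(st$f_S, 0.75)
  expect_equal(st$sigma_hat, sqrt(0.75 * 0.25))
  expect_equal(st$f_OS, 0.25)
  expect_equal(st$f_overall, 0.5)
  # all-reward history: frequency 1, zero uncertainty
  tr2 <- two_stim_trials(c(1, 1, 1, 1), c(1, 1, 1, 1))
  st2 <- window_stats(tr2, t = 6L, stimulus_id = 1L, n_past = 30, design = d1)
  expect_equal(st2$f_S, 1)
  expect_equal(st2$sigma_hat, 0)
  expect_equal(st2$f_overall, 1)  # mean of equals
  expect_error(window_stats(tr, t = 8L, stimulus_id = 2L, n_past = 4,
                            design = d1), "presentation")

  s0 <- frequency_state(0.5, 0.2)
  expect_equal(rw_update(s0, 1, alpha = 1)$f_S, 1)    # full update
  expect_equal(rw_update(s0, 1, alpha = 0)$f_S, 0.5)  # frozen
  expect_equal(rw_update(s0, 1, alpha = 0.2)$f_S, 0.6)
  expect_equal(rw_update(s0, 0, alpha = 0.2)$f_S, 0.4)
})

test_that("window predictions match a brute-force recomputation on all 64 histories", {
  d1 <- experiment_design(1)
  x_os <- c(1, 0, 1, 0, 0, 1)
  n_past <- 3
  specs <- list(
    list(spec = model_spec("URD"), params = list(n_past = n_past)),
    list(spec = model_spec("DN-1"),
         params = list(a = 0.2, b = 0.5, n_past = n_past))
  )
  brute_state <- function(hist_s, hist_os) {
    f <- function(h) if (length(h) == 0) 0.5 else mean(utils::tail(h, n_past))
    c(f_S = f(hist_s), f_OS = f(hist_os))
  }
  for (code in 0:63) {
    x_s <- as.integer(intToBits(code)[1:6])
    tr <- two_stim_trials(x_s, x_os)
    for (sp in specs) {
      got <- predict_series(tr, sp$spec, sp$params, design = d1)
      # brute force, trial by trial
      want <- numeric(nrow(tr))
      for (i in seq_len(nrow(tr))) {
        k_s <- sum(tr$stimulus_id[seq_len(i - 1)] == tr$stimulus_id[i])
        k_o <- sum(tr$stimulus_id[seq_len(i - 1)] != tr$stimulus_id[i])
        own <- if (tr$stimulus_id[i] == 1L) x_s else x_os
        oth <- if (tr$stimulus_id[i] == 1L) x_os else x_s
        fs <- brute_state(own[seq_len(k_s)], oth[seq_len(k_o)])
        fo <- mean(fs)
        want[i] <- if (sp$spec$family == "URD") {
          min(1, max(0, fs[["f_S"]] + sqrt(fs[["f_S"]] * (1 - fs[["f_S"]])) *
                       (fs[["f_S"]] - fo)))
        } else {
          min(1, max(0, (sp$params$a + fs[["f_S"]]) /
                       (sp$params$b + fs[["f_S"]] + fs[["f_OS"]])))
        }
      }
      expect_equal(got$prediction, want, tolerance = 1e-12)
    }
  }
})

test_that("RW and window frameworks agree on short equal-weight histories", {
  # On a 3-trial history, alpha chosen so the delta rule's weights are close
  # to equal-weight averaging; predictions should agree to coarse tolerance.
  d1 <- experiment_design(1)
  for (code in 0:7) {
    x_s <- as.integer(intToBits(code)[1:3])
    x_os <- c(1, 0, 1)
    tr <- two_stim_trials(x_s, x_os)
    w <- predict_series(tr, model_spec("URD"), list(n_past = 3), design = d1)
    r <- predict_series(tr, model_spec("URD", framework = "rw"),
                        list(alpha = 0.45), design = d1)
    expect_lt(max(abs(w$prediction - r$prediction)), 0.35)
  }
})

test_that("the model registry resolves all nine names with correct parameters", {
  expect_length(model_registry(), 9L)
  k <- vapply(model_registry(), function(m) {
    nrow(contextprob:::param_info(model_spec(m)))
  }, integer(1))
  expect_equal(unname(k), c(0L, 1L, 2L, 2L, 2L, 3L, 3L, 2L, 3L))
  # RW framework adds the learning rate
  expect_equal(nrow(contextprob:::param_info(model_spec("URD", "rw"))), 1L)
  expect_error(model_spec("URD-x"))
})
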