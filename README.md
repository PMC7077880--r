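# contextprob

Models, simulation and inference for **context effects on probability
estimation**.

## The problem

When people learn the reward probability of a stimulus from trial-by-trial
feedback, their estimates are biased by the *context*: the other stimulus
they experience in the same block. A stimulus rewarded 50% of the time is
judged more likely to pay off when its block partner pays 10% than when
its partner pays 90% — and this bias is strong at 50% reward but weak at
10% and 90%. The package is for computational cognitive scientists who
want to fit, compare and stress-test the candidate mechanisms behind this
regularity on trial-level estimate data, or to generate fully synthetic
cohorts with the same structure.

## The models

The central account is the **URD (uncertainty- and reference-dependent)
model**: the estimate is the experienced reward frequency plus an
uncertainty-gated deviation from the context's average frequency,

    P̂_S = f_S + σ̂_S (f_S − f_overall),      0 ≤ P̂_S ≤ 1,

where `f_overall = (f_S + f_OS)/2` is the context reference point and
`σ̂_S = sqrt(f_S (1 − f_S))` is the outcome SD implied by the tracked
frequency. Because `σ̂_S` peaks at 50% and vanishes toward 0 and 1, the
50%-peaked context-effect profile falls out of the model with no free
parameter. Variants add probability weighting
(`w(f) = f^γ / (f^γ + (1−f)^γ)^(1/γ)`) and loss aversion (λ). The
competitors are divisive normalization, `(a + f_S)/(b + f_S + f_OS)` and
`a f_S/(1 + b f_overall)`, and range normalization,
`(a + f_S)/(b + |f_S − f_OS|)`, with optional weighting. Histories evolve
either as equal-weight sliding windows over the last `n_past` trials or as
Rescorla–Wagner delta-rule trackers. Fitting is by maximum likelihood with
a Gaussian report model; models are compared by
`BIC = ln(n)k − 2 ln L_max` with subject-resampling bootstrap CIs.

See `vignette("context-effects")` for the full methods account.

## A worked example

Simulate a 34-subject cohort from a probability-weighted URD agent on the
(.1, .5, .9) design, measure the context-effect deltas, and compare five
models on the group-average series:

```r
library(contextprob)

des <- experiment_design(1)
agent <- generative_agent("URD-g", list(gamma = 0.6, n_past = 30L),
                          noise_sd = 0.05)
cohort <- simulate_cohort(des, 34, agent, master_seed = 1)

for (p in c(.1, .5, .9)) {
  bt <- bootstrap_test(context_delta(cohort, p)$per_subject, 0,
                       n_boot = 2000, seed = 7)
  cat(sprintf("Delta_%.0f%%: %+.3f [%+.3f, %+.3f]\n",
              100 * p, bt$point, bt$ci_low, bt$ci_high))
}
#> Delta_10%: +0.041 [+0.024, +0.060]
#> Delta_50%: +0.191 [+0.173, +0.209]
#> Delta_90%: +0.039 [+0.007, +0.075]

fits <- lapply(c("URD", "URD-g", "DN-1-g", "DN-2-g", "RN"),
               function(m) fit_model(cohort, m, n_past = 30))
compare_models(fits)
#>   model      bic ci_low ci_high n_trials rank overlaps_best
#>   URD-g -1071.87     NA      NA      180    1            NA
#>  DN-2-g  -547.25     NA      NA      180    2            NA
#>  DN-1-g  -344.86     NA      NA      180    3            NA
#>      RN  -264.33     NA      NA      180    4            NA
#>     URD  -146.62     NA      NA      180    5            NA

fits[[2]]
#> <cpfit URD-g (window framework, group data)>
#>   logLik 541.130 on 180 trials; k = 2; BIC = -1071.874
#>   selected window: 30 past trials
#>   coefficients:
#>       gamma sigma_noise
#>      0.5983      0.0120
```

The deltas show the characteristic profile — a large positive context
effect at 50% reward, small ones at 10% and 90% — and the fitted
`URD-g` model recovers the generating curvature (γ = 0.598 vs. a true
0.6) and ranks first by a wide BIC margin. `run_pipeline()` wraps this
whole chain (simulate → fit → compare → stats → report bundle) behind a
single seeded configuration.

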