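---
title: "Context-dependent probability estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-dependent probability estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contextprob)
```

## The scientific problem

When people learn the reward probability of a stimulus from trial-by-trial
feedback, their estimates are not a pure running frequency: they are biased
by the *context* — the other stimulus they experience in the same block of
trials. A stimulus rewarded 50% of the time is judged more likely to pay
off when its block partner pays 10% than when its partner pays 90%. The
striking empirical regularity is that this context effect is large at 50%
reward and weak or absent at 10% and 90%.

`contextprob` implements the model families proposed for this phenomenon,
a simulator for the six two-stimulus context experiments in which it is
studied, maximum-likelihood fitting with BIC model comparison, and the
associated behavioral statistics.

## The models

All models read a *frequency state*: the stimulus's recent reward
frequency $f_S$, its context partner's frequency $f_{OS}$, the context
reference point $f_{overall} = (f_S + f_{OS})/2$, and the outcome
uncertainty $\hat\sigma_S = \sqrt{f_S(1-f_S)}$.

**URD (uncertainty- and reference-dependent).** The estimate is the
frequency plus an uncertainty-gated deviation from the reference point:
$$\hat P_S = f_S + \tau\,(f_S - f_{overall}), \qquad 0 \le \hat P_S \le 1,$$
with the susceptibility $\tau$ set to $\hat\sigma_S$ (or, as a variant,
$\hat\sigma_S^2$). Because $\hat\sigma_S$ peaks at $f_S = 0.5$ and falls
toward 0 and 1, the model predicts the 50%-peaked profile of context
effects structurally, with no free parameter. `URD-g` first passes $f_S$
through the probability-weighting transform
$$w(f) = \frac{f^\gamma}{\left(f^\gamma + (1-f)^\gamma\right)^{1/\gamma}},
\qquad \gamma > 0,$$
which overweights small and underweights large probabilities for
$0<\gamma<1$; `URD-g-l` additionally multiplies the context term by a
loss-aversion factor $\lambda$ when $w - f_{overall} < 0$.

**Divisive and range normalization.** The competitors divide the
frequency by context statistics:
$\hat P_S = (a + f_S)/(b + f_S + f_{OS})$ (DN-1),
$\hat P_S = a f_S / (1 + b f_{overall})$ (DN-2), and
$\hat P_S = (a + f_S)/(b + |f_S - f_{OS}|)$ (RN). Their `-g` variants
apply the weighting transform to the normalized output; for URD-g the
transform is applied to $f_S$ *before* the context term, since there the
weighted frequency itself is the quantity compared to the reference. These
families predict a large context effect at 90% as well as 50%, which is
the lever the data use to separate them from URD.

Predictions are clipped to $[0,1]$ after the full model expression and,
for the normalization families, before the weighting transform (whose
domain is $[0,1]$).

## History statistics: two frameworks

The frequency state can evolve in two ways:

* **window** (default): equal-weight mean over the last `n_past`
  presentations of each stimulus, 1–30 trials. Statistics for trial $t$
  use outcomes strictly before $t$ — the estimate is given before that
  trial's feedback. A never-seen stimulus contributes the uninformative
  prior 0.5; shorter-than-window histories use all available trials.
  Group-level fits use `n_past = 30` (one block); individual fits may scan
  1–30 and keep the window with the largest maximized likelihood.
* **rw** (Rescorla–Wagner): one delta-rule tracker per stimulus,
  $f \leftarrow f + \alpha(x - f)$, initialized at 0.5, with a single
  learning rate $\alpha$ shared across stimuli. Trackers persist across
  the blocks of a context; since every stimulus belongs to exactly one
  context, no state crosses contexts.

$\hat\sigma_S^2 = f_S(1-f_S)$ is the Bernoulli population variance implied
by the tracked frequency rather than a small-sample estimator: it is
smooth, parameter-free, defined from the first trial, and equal to the
empirical population variance of binary outcomes at the tracked rate.

Pre-session and main-session outcomes are pooled when forming history
statistics (`pool = TRUE`), while likelihoods are evaluated over
main-session estimates for window fits and both sessions for RW fits —
matching how such data are conventionally fit.

## The simulator

`experiment_design()` encodes six designs: three reward probabilities,
each carried by two distinct stimuli in two different two-stimulus
contexts. Experiment 1 uses probabilities (.1, .5, .9), an 8-button
interval report scheme with boundaries (0, .05, .20, .35, .50, .65, .80,
.95, 1), a 3-block pre-session (20 trials/stimulus), a 6-block main
session (15 trials/stimulus/block, 2 blocks per context) and i.i.d.
Bernoulli outcomes. Experiments 2–6 use a 10-button scheme (10%
intervals), 40 main trials per stimulus, and *frequency-matched* outcomes:
each stimulus's realized main-session reward frequency equals its true
probability exactly (a permuted fixed-count sequence), which removes
sampling variability in experienced frequencies. The probability triplets
are (.1,.5,.9), (.1,.3,.5), (.5,.7,.9), (.3,.5,.7) and (.1,.5,.9) for
Experiments 2–6. Block order is randomized per subject; stimulus order is
randomized within block at fixed per-stimulus counts. Since the written
descriptions of Experiments 2–6 fix only the 40-trials-per-stimulus main
session, the package lays them out as 2 blocks per context of 20
trials/stimulus, mirroring Experiment 1's two-blocks-per-context
structure, and gives them no pre-session by default
(`pre_trials_per_stimulus` is a design field that variants can set).

A `generative_agent()` couples any model with report noise and a choice
rule. Per trial, the model's latent estimate gets Gaussian noise
(`noise_sd`), is clipped to $[0,1]$, and is discretized to the report
buttons; the recorded numeric estimate is the interval *midpoint*, which
is unbiased under a uniform within-interval prior (the mapping is a
convention; boundaries are half-open $[lo, hi)$ with the last interval
closed). Post-task lottery choices are sampled from a softmax over the two
stimuli's end-of-session latent estimates. Defaults, chosen once as
field-typical values: $\gamma = 0.6$ (moderate probability-weighting
curvature), `n_past = 30` (the group-fit window), `noise_sd = 0.05`,
softmax inverse temperature 10 (estimates live on a 0–1 scale, so
temperature 10 yields reliable-but-stochastic choices), RW $\alpha = 0.3$.
The lottery block uses 20 trials for each same-probability pair and 7 for
each remaining pair.

What the simulator does *not* emulate: response times, missing responses
(unless a `miss_rate` is set), attentional or sequential dependencies in
the report noise, and subject-level parameter correlations. Tests passing
on synthetic cohorts therefore certify the estimation machinery, not the
adequacy of any model for real subjects.

## Fitting and model comparison

Reports are modelled as Gaussian around the latent prediction; the
log-likelihood is $\sum_i \log N(\text{obs}_i; \text{pred}_i,
\sigma_{noise}^2)$. $\sigma_{noise}$ is profiled analytically (its MLE is
the RMS residual, clamped to $[10^{-4}, 1]$), which removes one search
dimension; it still counts as a free parameter in
$\mathrm{BIC} = \ln(n)k - 2\ln L_{max}$. Model parameters are bounded:
$\gamma \in (0.01, 5]$, $\lambda \in (0.01, 10]$, $a \in [-2, 2]$,
$b \in [-2, 5]$ under positive-denominator guards, $\alpha \in [0, 1]$.

The search runs Nelder–Mead from 10 seeded starts (defaults plus uniform
draws within bounds) followed by a bounded quasi-Newton polish; the
simplex stage is essential because clipping and denominator guards create
plateaus that defeat finite-difference gradients. One-parameter models are
optimized by a 41-point grid bracket plus golden-section refinement, since
the $\gamma$ profile need not be unimodal. Invalid parameter regions
return a large finite penalty. Non-convergence after all restarts is
reported via `converged = FALSE` rather than an error.

Group-average fitting aligns subjects by the $k$-th presentation of each
stimulus in the main session — the only alignment that is well defined
when block order is randomized per subject — and averages both observed
estimates (skipping missing values) and per-subject model predictions at
each position. `bootstrap_bic()` resamples the subject pool with
replacement, reweights the group series by subject multiplicity, refits,
and returns the 95% percentile interval of the BIC; refits keep the
originally supplied window length (re-scanning windows inside every
resample would conflate window selection noise with parameter
uncertainty). `compare_models()` ranks by BIC and flags models whose CIs
overlap the best model's.

## Behavioral statistics

* `context_delta()`: per subject, mean estimate of a probability's
  stimulus in its lower-partner context minus its higher-partner context;
  "second half" means the last half of each stimulus's main-session
  presentations (the session-half definition is per stimulus, since block
  order varies across subjects). Positive = inflation by the weaker
  partner.
* `bootstrap_test()`: 95% percentile CI of the mean over subject
  resamples; significance at $\alpha = 0.05$ by CI exclusion.
* `fit_frequency_regression()`: no-intercept least squares of trial-level
  estimates on $f_S(t; n_{past})$ and $f_{overall}(t; n_{past})$, scanning
  the window by maximum $R^2$ (equivalently minimum SSE). Under a URD
  generator with fixed gain $\tau$ the coefficients identify $(1+\tau,
  -\tau)$, so $\Delta = \hat\beta_{f_S} - (1 - \hat\beta_{f_{overall}})$
  is 0 — the package's regression-identity test verifies this to $10^{-6}$.
* `choice_probability()` and `simulate_choice_probability()`: observed and
  model-regenerated preference rates for the same-probability stimulus
  pairs.
* `permutation_count()`: the Bonferroni rule $1/(\alpha/n)$ for the number
  of label permutations in voxelwise tests.

## Problem sizes and numerical choices in the test suite

The suite runs entirely on synthetic data at desk scale: cohorts of 4–34
subjects, bootstrap resamples of 40–1000, a 20-cohort model-recovery study
(8 subjects each, four generating families with identifiable parameter
settings), and a 1000-replication calibration study of the bootstrap test
at $n = 34$. The recovery study's generating parameters deliberately avoid
a known degeneracy: DN-1 with $a \approx 0$ is an exact reparameterization
of DN-2 ($ (a+f_S)/(b+2f_{overall}) \to a'f_S/(1+b'f_{overall})$ as
$a \to 0$), so a recovery exercise must give DN-1 an appreciable additive
numerator constant to be meaningful.

## Known limitations

* **Structural context effects at 10%/90%.** Because $\tau = \hat\sigma_S$
  has no free scale, URD-family agents produce a *positive* latent context
  delta of about $\hat\sigma_S \times 0.2 \approx 0.06$ at 10% and 90%
  reward in the (.1,.5,.9) designs — the same direction-but-smaller trend
  the empirical literature reports. With low report noise (0.05) and
  cohorts of ~34, bootstrap CIs resolve this small effect: simulated
  cohorts then show *significant* (not null) 10%/90% deltas and choice
  probabilities. Exactly-null effects at the outer probabilities are not
  reproducible from URD-truth synthetic data; they require the much larger
  report variability of human subjects, coarse report intervals, or both.
* **Percentile-bootstrap calibration.** At $n = 34$ the percentile
  bootstrap for a mean rejects a true null at about 6.5–7%, not 5% — the
  familiar small-sample anticonservatism of percentile intervals (the
  implied critical value is $z_{0.975}\sqrt{(n-1)/n}$ on an MLE scale
  rather than a $t$ quantile). The package implements the standard
  percentile method deliberately, for comparability with common practice.
* The exact update rules of published Rescorla–Wagner re-implementations
  vary; the package's reconstruction (per-stimulus trackers, one shared
  learning rate, 0.5 initialization) is the simplest member of that family
  and is isolated behind the `framework` switch.
* Group-average fitting assumes the per-stimulus presentation alignment
  described above; designs with per-subject trial counts that differ would
  need a different alignment rule.

## A worked example

```{r example, eval = FALSE}
des <- experiment_design(1)
agent <- generative_agent("URD-g", list(gamma = 0.6, n_past = 30L),
                          noise_sd = 0.05)
cohort <- simulate_cohort(des, 34, agent, master_seed = 1)

# context-effect profile
sapply(c(.1, .5, .9), function(p) context_delta(cohort, p)$group_mean)

# model comparison on the group-average series
fits <- lapply(c("URD", "URD-g", "DN-1-g", "DN-2-g", "RN"),
               function(m) fit_model(cohort, m, n_past = 30))
compare_models(fits)
```
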