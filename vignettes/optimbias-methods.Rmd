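---
title: "Modelling the development of optimism bias: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the development of optimism bias: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

`optimbias` studies how an *optimism bias* — systematically expecting larger
rewards than a task actually delivers — can arise from valence-asymmetric
reinforcement learning, and how that asymmetry changes across late childhood
and adolescence. The package contains a complete, self-sufficient pipeline:
a task simulator, a family of belief-learning models with likelihood-based
fitting and recovery diagnostics, the behavioural statistics, a bootstrap
mediation analysis, and a synthetic-cohort generator so every stage can be
exercised without any participant data.

```{r setup}
library(optimbias)
```

## The task

Subjects repeatedly exert physical effort (rapid button presses, calibrated
to their own maximum) to win a displayed reward of 1–7 coins. Both the
reward magnitude and the effort threshold (42–92 % of the subject's maximum
presses) drift slowly and independently over 40 trials. Before each attempt
the subject reports a *reward belief* on a 1–7 scale; after the attempt the
reward magnitude is displayed whether or not the effort sufficed (a failed
trial shows a cross over the coins), so the reward remains learnable on
every trial. That outcome semantics is central: prediction errors in all
models below are computed against the *displayed* reward, success or not.

`generate_schedule()` implements the drifting environment as latent
Gaussian random walks with reflecting boundaries, the reward walk rounded
to whole coins. Reflection (rather than clamping) avoids trajectories
sticking to the bounds. Because reward and effort must carry independent
information, schedules are rejection-sampled until the two sequences'
Pearson correlation is below 0.2 (configurable; a retry budget of 1000
guards against pathological settings). Default step SDs — 0.5 coins and
0.03 threshold units per trial — let each walk traverse roughly half its
range over 40 trials, the intended "slowly drifting" regime. The staircase
(`staircase_update()`) raises a subject's calibrated maximum whenever a
trial exceeds it, and ties at the threshold count as success
(`evaluate_trial()`); a fixed convention keeps tests exact. Button-press
kinetics are abstracted to an exerted *fraction* of the subject maximum —
only success/failure and the displayed reward feed the learning analyses.

## The belief-learning model family

The core model is a Rescorla–Wagner update with valence-split learning
rates. With belief $b_t$ and displayed reward $o_t$, the prediction error
is $\delta_t = o_t - b_t$ and

$$b_{t+1} = b_t + \begin{cases}\alpha^{+}\,\delta_t & \delta_t > 0\\
\alpha^{-}\,\delta_t & \delta_t < 0,\end{cases}$$

starting from a prior $\mu_0$. $\alpha^{+} > \alpha^{-}$ is *optimistic
learning*: good surprises move the belief more than bad ones, so the
long-run belief settles above the true average reward. For i.i.d. symmetric
two-point outcomes the stationary mean has the closed form
$(\alpha^{+} r_{hi} + \alpha^{-} r_{lo})/(\alpha^{+}+\alpha^{-})$
(`asymptotic_bias_oracle()`), which the test suite uses as an analytic
anchor for simulations:

```{r}
asymptotic_bias_oracle(0.4, 0.1, 1, 7)
```

Reported beliefs add noise: reports follow a Gaussian centred on the latent
belief with scale $\xi$, **truncated** to the 1–7 rating scale. The same
truncated density is the observation model of the likelihood and the
sampling distribution of `simulate_agent()`. We deliberately use truncation
on both sides rather than clipping simulated reports at the bounds:
clipping piles probability mass *at* the scale endpoints that a truncated
likelihood cannot represent, and in development-sized data this mismatch
measurably inflates fitted $\alpha^{+}$ for exactly the subjects whose
beliefs ride near the ceiling (low-$\alpha^{-}$, high-prior "child-like"
agents), manufacturing a spurious age effect on the positive learning rate.
Keeping generator and likelihood identical makes every simulation-based
recovery exercise well-specified. How real subjects behave at the scale
ends is unknowable from the model alone; this is a modelling choice, not an
empirical claim.

Six variants nest within the family (`model_variants()`): V1/V2 use a
single learning rate (prior fixed at the scale midpoint 4, or free);
V3/V4 split the rates (fixed or free prior); V5 adds an additive belief
decrement after an effort failure (motivated by the significant
previous-failure regressor in the behavioural analysis); V6 adds decay of
the belief toward the scale midpoint. Every variant frees $\xi$. V4
($\mu_0, \alpha^{+}, \alpha^{-}, \xi$) is the full valence-asymmetric
model of interest.

## Fitting, model comparison, recovery

`fit_subject()` maximises the truncated-Gaussian likelihood by L-BFGS-B
under box constraints ($\mu_0 \in [1,7]$, rates in $[0,1]$,
$\xi \in [0.01, 5]$), from 20 uniform random starts plus a box-midpoint
start — belief-learning likelihoods are multimodal in the rates when trials
are few. The multi-start loop runs natively (compiled recursion and
objective) so that cohort-scale refitting stays cheap; estimation is plain
maximum likelihood, not MAP. The first report is modelled like any other,
with prediction $\mu_0$ — early reports are what identify the prior.
Degenerate data (e.g. constant reports equal to constant outcomes) leave
the rates unidentified; the fit then carries a `flat_likelihood` flag
rather than failing.

Model comparison (`compare_models()`) sums BIC over subjects, with
per-subject win counts as a secondary view; BIC's complexity penalty is
what adjudicates the extra rate/prior parameters. `parameter_recovery()`
and `model_recovery()` implement the standard simulate–refit diagnostics:
correlation/bias/RMSE per parameter, and a row-normalised confusion matrix
of generating versus BIC-best variant. Two design points deserve emphasis:

* Recovery quality is a property of the *truth distribution* as much as of
  the fitter. Agents whose true rates are nearly tied are indistinguishable
  from the single-rate model **by construction**, and BIC is right to file
  them under V1/V2. Model-recovery experiments therefore sample truths from
  the regime where the valence split is expressed (clearly separated rates,
  prior away from the midpoint); the generic box-spanning sampler remains
  the default for parameter recovery.
* At the study's scale (40 trials, $\xi \approx 0.5$) the rates recover
  with correlations around 0.6–0.8, not 0.99; conclusions at that scale
  should rest on group-level statistics, which is what the pipeline does.

## Behavioural statistics

The optimism-bias statistic is the subject's mean reported reward belief
minus the mean displayed reward (`summarize_subject()`); on the 1–7 scale
it is bounded in $[-6, 6]$ and is zero for a perfectly calibrated
reporter. Belief construction is probed with a per-subject lagged OLS of
the current belief on the previous displayed reward, a previous-failure
indicator (failure $+1$, success $-1$), and the previous belief, with the
previously exerted effort optional (`belief_regression()`). Trial 1 has no
lagged predictors and is dropped. A subject who never fails makes the
failure column constant; it is dropped for that subject with its
coefficient recorded as missing rather than silently producing a
rank-deficient solve. Group-level inference uses the summary-statistics
approach: one-sample t-tests of the per-subject coefficients against zero
(`group_level_coefficient_test()`).

Group comparisons are one-way between-subject ANOVAs with partial
$\eta^2$, and independent-samples t-tests with pooled-SD Cohen's $d$
(`one_way_anova()`, `pairwise_t()`). The Welch correction follows an
explicit policy, default `"auto"`: Welch when the larger sample variance
exceeds the smaller by a factor of 1.5 or more, Student otherwise (both
variants are always available by forcing the policy). Finally,
`asymmetry_bias_correlation()` relates the fitted learning asymmetry
$\alpha^{+}-\alpha^{-}$ to the optimism bias, with a partial correlation
controlling for age computed by residualising both variables on age
($n-3$ df for the partial test).

## Mediation

The developmental claim has the form of a three-variable path model:
age (X) → negative learning rate (M) → optimism bias (Y). `fit_paths()`
returns OLS paths $a$ (M on X), $b$ and $c'$ (Y on X and M jointly), $c$
(Y on X), and the indirect effect $ab$; on a common sample
$c = c' + ab$ holds as an algebraic identity, and the package asserts it to
$10^{-10}$. Age enters in continuous years — group codes would change the
units of every path.

Inference uses a case-resampling bootstrap (subjects resampled with rows
kept together) with bias-corrected accelerated (BCa) intervals: the bias
term $z_0$ comes from the fraction of bootstrap draws below the point
estimate and the acceleration from a leave-one-out jackknife; with
$z_0 = 0$ and zero acceleration the interval reduces to the plain
percentile interval (asserted in tests). The primary p-value is the
bootstrap-distribution p, $2\min\{\Pr(\hat\theta^* \le 0),
\Pr(\hat\theta^* \ge 0)\}$ floored at $1/n_{boot}$; a normal-approximation
p from $z = \hat\theta / \widehat{SE}_{boot}$ is reported alongside. The
reference analysis uses 10,000 bootstrap samples (the package default);
calibration experiments in the test suite use 1,000 per replicate to keep
500-replicate ensembles tractable, which widens the p-value floor but does
not change coverage behaviour materially. Degenerate bootstrap draws
(constant X or M) are redrawn with a retry budget.

## The synthetic cohort

`default_cohort_spec()` encodes the study conditions: three groups of
27 / 38 / 34 subjects with ages uniform in 8.9–9.8, 12.6–13.7 and
16.7–17.7 years, 40 trials each. The generative rule makes the negative
learning rate increase with age at 0.03 per year from 0.08 at age 9 —
so the *asymmetry*, and with it the optimism bias, shrinks with age —
while the positive rate is constant in expectation and the prior declines
mildly across groups (5.5 / 5.0 / 4.5). Dispersion across subjects is
SD 0.1 for rates and 0.8 for the prior (clipped to the parameter boxes,
with the clip count logged); $\xi = 0.6$; effort success is Bernoulli with
probability 0.725 per trial, reflecting a staircase-calibrated task in
which success rates do not differ systematically by group.

The positive-rate mean is 0.45 rather than a value close to the oldest
group's negative rate: empirically, optimistic learning
($\alpha^{+} > \alpha^{-}$) and a positive bias are present in *every* age
group, late adolescents included, so the generator keeps a positive
asymmetry (~0.12) even at the top of the age range. All of these values
are configuration, not estimates: the generator emulates the *structure*
of developmental data (group sizes, drifting schedules, age-graded
asymmetry), not individual differences beyond Gaussian parameter
dispersion, practice or fatigue effects, or any effort-belief dynamics.
Passing tests on this cohort show the pipeline recovers the mechanisms it
assumes; they cannot show that real children obey the model.

`headline_replication()` runs the whole pipeline — summaries, fits of all
six variants, BIC comparison, group statistics, mediation — and evaluates
five qualitative checks: positive bias in each group, the
children > early > late ordering of mean bias, a significant age-group
effect on bias, a significant group effect on the fitted $\alpha^{-}$ with
none on $\alpha^{+}$, and a mediation indirect effect whose BCa interval
excludes zero.

```{r, eval = FALSE}
cohort <- generate_cohort(default_cohort_spec(seed = 1))
rep <- headline_replication(cohort$trials, seed = 1)
rep$checks
#> bias_positive_all_groups   bias_ordering   bias_anova   alpha_effects
#>                     TRUE            TRUE         TRUE            TRUE
#> mediation_ab
#>         TRUE
```

## Numerical and problem-size choices

* Optimiser tolerance: `factr = 1e4` (≈ $2\times10^{-12}$ relative), 300
  iterations max per start, finite-difference gradients; ties between
  equally good optima resolve to the first found.
* `headline_replication()` fits with 5 random restarts plus the midpoint
  start by default (`fit_subject()` alone defaults to 20): a full-cohort
  run fits 99 subjects × 6 variants, and on this task size the lighter
  multi-start matches the heavier one's optima while keeping a cohort run
  in seconds. The optimality of the default fitter is checked directly
  against a 20,000-point random search in the test suite.
* Ensemble sizes in the test suite — 20 cohort seeds for the replication
  checks, 500/200 replicates for bootstrap calibration at 1,000 bootstrap
  draws, 100 agents for study-scale recovery — were chosen as the smallest
  sizes at which the corresponding binomial/Monte-Carlo error bands are
  informative.
* Mediation calibration experiments scale the Y-residual to the synthetic
  cohort: regressing the cohort's bias on age and the true negative rate
  leaves a residual SD of ≈ 0.41, so the generative experiments use 0.4.
* Degenerate inputs error loudly (empty records, constant predictors,
  collinear mediator) or are flagged (`flat_likelihood`, dropped
  regression columns) rather than returning silently wrong numbers.

## Known limitations

* Estimation is per-subject ML; there is no hierarchical shrinkage, so
  single-subject rate estimates at 40 trials are noisy (by design the
  analyses aggregate across subjects).
* The effort side of the task is modelled only as a success/failure
  process; effort-belief learning is out of scope.
* The six-variant family spans one-vs-two rates, prior, report noise, a
  failure decrement and midpoint decay; it is a reasonable bracket of the
  mechanism space, not an exhaustive one.
* BCa p-values floor at $1/n_{boot}$; with 10,000 draws the smallest
  reportable two-sided p is $10^{-4}$.
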