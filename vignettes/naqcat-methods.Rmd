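---
title: "Measurement models and adaptive testing in naqcat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement models and adaptive testing in naqcat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(naqcat)
```

`naqcat` measures exposure to workplace bullying with the 22-item
NAQ-R under the Andrich rating scale model (RSM), and administers the
scale adaptively. This vignette documents the model, the algorithms,
the tunable parameters, and the design decisions behind them.

## The rating scale model

Responses use five frequency categories (1 = never … 5 = daily),
internally rescored 0…4. For person measure $\theta$ and item
difficulty $\delta_i$ (both in logits), the probability of internal
category $k$ is

$$P(X_{ni}=k) = \frac{\exp\sum_{j=1}^{k}(\theta_n-\delta_i-\tau_j)}
 {\sum_{m=0}^{K-1}\exp\sum_{j=1}^{m}(\theta_n-\delta_i-\tau_j)},$$

with the empty sum defined as zero. The step thresholds
$\tau_1,\dots,\tau_{K-1}$ are shared by all items — that is what
distinguishes the rating scale model from the partial credit model,
which would give every item its own threshold set. The bank schema
reserves room for per-item overrides but the core operations reject
them in this version. $\tau_j$ is indexed as the step from internal
category $j-1$ to $j$; a calibrated bank has $\sum_j \tau_j = 0$ and
$\bar\delta = 0$, the identification used throughout.

Numerically, the largest cumulative log-numerator is subtracted before
exponentiation, so probabilities are exact up to machine precision even
at $|\theta-\delta| \approx 700$. With $K=2$ the model collapses to the
dichotomous Rasch form $e^{\theta-\delta}/(1+e^{\theta-\delta})$, which
is also the form used for individual victimization probabilities
against a cutoff.

Item information equals the model variance of the item score and also
the derivative of the item's expected score with respect to $\theta$;
test information is additive over administered items and gives
$SE = I^{-1/2}$. The test characteristic curve (TCC) — the expected
summed score on the external 1–5 labels — is strictly increasing and is
inverted by bisection (`raw_to_logit()`, tolerance $10^{-6}$ on the raw
scale) to translate logit cutoffs into traditional summed-score
cutoffs. On the bundled bank the −4.2 logit screening cutoff maps to an
expected summed score of about 30.2, i.e. "raw score above 30".

## Person estimation

`mle_theta()` solves the score equation
$\sum_i (x_i - E_i(\theta)) = 0$ by Newton-Raphson with steps clamped
to ±1 logit, at most 50 iterations, starting from the logit of the
(adjusted) proportion-of-maximum score shifted by the mean difficulty
of the administered items. Missing responses are treated as
not-administered: the likelihood runs over answered items only, which
is the standard item-response-theory treatment and one of the reasons
for preferring it over summed scores. The raw score is sufficient for
$\theta$, so equal raw scores on the same subset give equal measures.

All-floor and all-ceiling strings have no finite maximizer; the raw
score is pulled 0.3 score units inside the boundary (configurable), a
common Rasch convention, and the estimate is flagged
`extreme_adjusted`. The resulting measure is finite and lies outside
the range of all non-extreme measures on the same subset.

## Joint calibration

`jmle_calibrate()` re-implements joint maximum likelihood (JMLE), the
method of the classic Rasch calibration programs: alternating
Newton-Raphson blocks for persons, item difficulties, and thresholds
(a diagonal Newton step on the cumulative category probabilities),
with the identification constraints re-applied every cycle and
convergence declared when no parameter moves by more than $10^{-4}$
logits (default cap 200 cycles; a 300 × 22 matrix typically converges
in about 30 cycles in a couple of seconds). Extreme persons are
excluded during calibration and re-anchored afterwards with adjusted
estimates; how the original toolchain handled them is not documented,
so exclusion-then-anchoring is this package's documented choice.

JMLE is known to bias difficulties outward on short tests (the classic
factor is about $L/(L-1)$ for test length $L$); an optional
$(L-1)/L$ correction flag is provided but off by default, for fidelity
to the reference toolchain. At $L=22$ the bias is small — recovering
the bundled bank from simulated $n=300$ samples reproduces each
threshold within about ±0.25 logits and each difficulty within ±0.35 —
but on a 3-item toy bank the inflation is clearly visible, which is why
short-test absolute magnitudes should not be over-interpreted.

Fit is reported as infit (information-weighted,
$\sum r^2 / \sum W$) and outfit (unweighted mean of $z^2$) mean
squares, both ≈ 1 under model-consistent data, with the survey-scale
usable range 0.5–1.5; the point-measure correlation (PTME) between item
responses and person measures; person separation reliability
$(\mathrm{var}(\hat\theta) - \overline{SE^2})/\mathrm{var}(\hat\theta)$;
and Cronbach's alpha for classical reference. Note that the stopping
rule below uses $\sqrt{1-\text{reliability}}$ as the SE target; an
alternative SEM convention ($SD \times \sqrt{\text{reliability}}$)
circulates in the applied literature but is inconsistent with that
rule and is not used here.

DIF screening re-estimates each item's difficulty separately in two
respondent groups with person measures anchored from the joint
calibration, and tests the contrast with a Wald chi-square
$(\hat\delta^A - \hat\delta^B)^2/(SE_A^2+SE_B^2)$, df 1 — the standard
operationalization of the item-trait interaction chi-square. Under
no-DIF simulation the per-item rejection rate is close to (slightly
under) the nominal 5%, and a +1 logit injected shift with 300 persons
per group is detected essentially always.

## The unidimensionality workflow

Three steps qualify the scale as unidimensional before adaptive use:

1. **Horn's parallel analysis** on the raw responses: observed
   eigenvalues are compared with the 95th percentile (the stricter,
   literature-preferred rule; the mean is also reported) of eigenvalues
   from `n_reps` random normal datasets of the same shape, and the
   count of leading eigenvalues above the reference is the retained
   factor count. This avoids the over-factoring of the
   eigenvalue-greater-than-1 rule, which is what produced multi-factor
   NAQ-R reports elsewhere.
2. **Fit statistics** from the calibration, expected inside 0.5–1.5.
3. **Post-hoc residual checks**: PCA of the item-by-item correlation
   matrix of standardized residuals (`residual_pca()`, reporting the
   first-contrast eigenvalue and loadings), then Smith's subset t test:
   persons are measured separately on the most positive- and most
   negative-loading items (5 + 5 by default, configurable) and
   $t_n = (\hat\theta^A_n-\hat\theta^B_n)/\sqrt{SE_A^2+SE_B^2}$ is
   compared against ±1.96, with fewer than 5% outside expected under
   unidimensionality.

One caveat found while validating this workflow deserves emphasis:
because the subsets are selected from the *same* data via the
first-contrast loadings, the Smith proportion exceeds its nominal 5%
(around 9–11%, largely independent of subset size) even for perfectly
model-consistent data when the person distribution is wide
(e.g. N(0, 2)). In floor-heavy samples typical of workplace-bullying
surveys — emulated by the package's mixture population preset, where
most respondents sit near the minimum raw score — the proportion drops
below 5%, matching published practice. The check is therefore most
meaningful for samples resembling the instrument's actual use, and the
package's tests evaluate it under the floor-heavy emulation.

## The adaptive engine

A session (`run_cat_session()`) proceeds as follows: the first item is
drawn uniformly at random (no measure exists yet); every subsequent
item is the unanswered one with maximum information at the current
provisional measure, ties broken by bank order. The provisional measure
starts at 0 logits — a neutral, least-assumption initialization — and
switches to the Newton-Raphson MLE once three responses have been
collected; if all responses so far sit at one extreme category the
extreme-score-adjusted MLE is used rather than deferring estimation
indefinitely, which guarantees termination. The session stops at the
first step where $SE < SE_{stop}$ with at least `min_items` answered,
or when the configured maximum (or the bank) is exhausted.

Defaults in `cat_config()`: minimum 10 of the 22 items (45% of the
full form), $SE_{stop} = \sqrt{1-0.80} = 0.4472$ from a target
reliability of 0.80, computed at full precision (pass
`se_stop = 0.44` to use the rounded convention). A target reliability
of 0.90 gives $SE_{stop} = 0.32$, which on this bank drives sessions
to nearly the full 22 items — the bank simply lacks easy items, so
precision near the low cutoff is expensive; lowering the target to
0.80 is the documented trade-off. With `se_stop = 0` the session
degenerates to the full test and reproduces the nonadaptive estimate
exactly (same likelihood, same solver).

`run_cat_batch()` replays recorded full-test response vectors through
the engine, the standard way to evaluate an adaptive design against
collected data. Efficiency is summarized by
$1 - \text{(adaptive responses)}/\text{(full-test responses)}$ and by
the time saving *seconds-per-item × items-saved-per-person × persons*;
precision by the Pearson correlation and a paired t test of the two
measure sets.

## Cutoffs and probabilities

`roc_cutoff()` computes the AUROC by the Mann-Whitney rank construction
with midranks for ties, its confidence interval by Hanley-McNeil
(a DeLong-type interval can be obtained from specialized ROC packages;
the tests cross-check against one), and the operating cutoff by
maximizing Youden's $J$ — a standard, reproducible rule, chosen here
because the original cutoff-selection procedure was not documented. The
logit cutoff is mapped to its raw-score equivalent through the TCC.
Individual screening uses
$P = \mathrm{logistic}(\theta - \text{cutoff})$ with an optional
interval from $\theta \pm 1.96\,SE$.

## Synthetic data

`generate_responses()` draws every cell from the RSM by inverse-CDF
sampling at the person's true measure, using the bundled published
bank by default. Populations (`population_spec()`) are either normal —
default N(0, 2), wide enough for a 22-item instrument to reach person
reliability near 0.9 — or a floor-heavy two-component mixture
(0.76·N(−5.4, 1.5) + 0.24·N(−3.1, 1.5)), whose component means mirror
the published non-bullied and bullied group means; the real sample's
distribution is only available graphically, so no exact emulation is
claimed. One master seed drives a single reproducible stream for both
the latent draws and the responses.

Victim labels follow a logistic link
$P(\text{bullied}) = \mathrm{logistic}(-1.39 + 0.52\,\theta)$, fixed
once by numerically calibrating against the N(0, 2) population to give
prevalence ≈ 24% and measure-vs-label AUROC ≈ 0.75, the figures of the
motivating survey.

What the generator does *not* emulate: response times, demographic
covariates, careless/inattentive responding (tests inject it
explicitly where needed), and local dependence between items. Passing
tests on synthetic data therefore demonstrate the correctness of the
algorithms under the model, not the behaviour of the NAQ-R in any new
population.

## Problem sizes and determinism

The test suite and the acceptance script work at the survey's own
scale — 300 persons × 22 items for calibration, adaptive replay and
ROC; up to 1000 persons for bias checks; 30–100 replicates for
size/power simulations — with every stochastic step seeded. A full
calibration at 300 × 22 takes a couple of seconds; a full adaptive
replay of 300 persons a few seconds.

## Known limitations

* Partial credit (per-item thresholds) is out of scope in this
  version.
* JMLE's short-test bias is documented above; for few-item banks the
  correction flag (or a conditional/marginal estimator outside this
  package's scope) should be considered.
* The Smith subset t proportion is anti-conservative for well-spread
  populations, as documented above.
* Bayesian (EAP/MAP) person estimators and CAT exposure control are
  not provided.
* Estimating bullying prevalence by operational criteria beyond the
  self-label (and demographic inference tables) is out of scope.
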