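---
title: "Rasch methods behind the VFQ-28-R scoring engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rasch methods behind the VFQ-28-R scoring engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(vfqr)
```

## The measurement problem

The NEI VFQ-25 is a 25-item vision-related quality-of-life questionnaire
scored classically: each response is mapped linearly onto 0–100, sub-domain
scores are means of their component items, and the composite is the mean of
the 11 sub-domain scores. Classical sums treat ordered response counts as
interval-level measurements, are sample- and scale-dependent, handle missing
data awkwardly, and assume a constant standard error for everyone. In
retinal-disease trial populations the instrument is additionally
mis-targeted — many respondents sit above the range the items measure — and
most items show disordered response thresholds.

`vfqr` implements both the classical scorer (as the reference behaviour) and
a revised instrument, the VFQ-28-R: three mis-fitting items removed (VF2,
VF3, VF4), the six Appendix near/distance-activity items added (VFA3–VFA8),
response levels combined on nine items with threshold disorder, the
"not sure" level of the five true/false items treated as missing, and the
remaining 28 items scored in two domains — Activity Limitation (19 items)
and Socio-Emotional Functioning (9 items) — under the partial credit model,
so each person receives a location in logits with an individual standard
error.

## The model

For item $i$ with $m_i$ thresholds $\tau_{i1},\dots,\tau_{im_i}$ and person
location $\theta_n$, the probability of scoring $x \in \{0,\dots,m_i\}$ is

$$
P(X_{ni}=x) \;=\;
\frac{\exp\!\sum_{k\le x}(\theta_n-\tau_{ik})}
     {\sum_{j=0}^{m_i}\exp\!\sum_{k\le j}(\theta_n-\tau_{ik})},
$$

with the empty sum equal to zero. Thresholds are kept *uncentred*; the item
location $\delta_i$ is the arithmetic mean of the item's thresholds, which
is the quantity shown on item maps. All probabilities are accumulated in
the log domain with log-sum-exp, so the engine is stable for locations up
to several hundred logits. Conditional moments (variance and the third and
fourth central moments) are computed exactly by enumeration over the finite
category set; nothing downstream relies on normal approximations of the
item score.

## Estimation

`rasch_calibrate()` uses joint maximum likelihood: damped Newton–Raphson
steps alternate between all person locations (vectorised; each person's
estimate solves the score equation $\sum_i (x_{ni} - E[X_{ni}\mid\theta])=0$)
and each item's threshold vector (an $m_i$-dimensional Newton step with the
exact Hessian of cumulative-probability covariances). Design choices:

* **Missing data** simply drop out of the likelihood — no imputation, no
  per-person rescaling.
* **Identifiability**: item locations are centred at zero each iteration.
* **Extreme scores**: persons at the minimum or maximum possible raw score
  carry no information about item parameters and are excluded from
  calibration; afterwards their raw score is moved 0.3 score units inside
  the observable range (configurable in `(0, 0.5]`) and solved like any
  other, yielding a finite, flagged location.
* **Bias correction**: joint ML inflates the spread of item parameters by
  roughly $L/(L-1)$ for a test of length $L$; the classical $(L-1)/L$
  correction is applied to the centred thresholds. The package's accuracy
  claim is statistical (parameter recovery), not bit-compatibility with any
  proprietary implementation.
* **Convergence**: largest absolute parameter change `< 1e-5` logits,
  at most 100 outer iterations; non-convergence returns a result with
  `converged = FALSE` and a warning rather than an error.
* **Disordered thresholds are allowed.** Threshold disorder is a *finding*
  of the evaluation, so the estimator must not constrain it away.
* **Null categories** (a response level never observed) make an item's
  thresholds inestimable; calibration stops with an explicit message naming
  the item and level, because silently re-numbering levels would change the
  instrument under evaluation.

Standard errors are $1/\sqrt{I(\hat\theta)}$ with $I$ the test information
(sum of conditional item-score variances) at the estimate.

## The six evaluation areas

`evaluate_instrument()` orchestrates calibration plus:

1. **Scale-to-sample targeting** — person mean/SD against the threshold
   range, the proportion of persons above the highest threshold, the
   proportion at the maximum raw score, and binned person/threshold
   distributions for Wright-style maps (`autoplot()`).
2. **Threshold ordering** — an item is disordered iff any adjacent pair has
   $\tau_{k+1} < \tau_k$.
3. **Item fit** — (a) *fit residuals*: each item's sum of squared
   standardized residuals is standardized by its exact model moments
   (second and fourth conditional moments per cell) and symmetrized with a
   cube-root transform; the acceptable band is $[-2.5, +2.5]$, positive
   values indicating noisier-than-model (underfit), negative values
   more-deterministic-than-model (overfit, the signature of dependence);
   (b) *item–trait interaction*: persons are split into ability class
   intervals, per-interval residual sums are standardized by their exact
   variances, and the squared deviates sum to a $\chi^2$ with
   (intervals − 1) degrees of freedom, Bonferroni-adjusted across items.
4. **Stability (DIF)** — two-way ANOVA of standardized residuals on a
   person factor (main effect = uniform DIF) and factor × class-interval
   interaction (non-uniform DIF). Flags use the F tests after Bonferroni
   adjustment across items; both statistics are reported.
5. **Local dependence** — Pearson correlations of standardized residuals,
   pairwise-complete; pairs with $r > 0.30$ (strictly; the value equals 10%
   shared variance) are flagged.
6. **Reliability** — the person separation index
   $\mathrm{PSI} = (\mathrm{var}(\hat\theta) - \overline{se^2}) /
   \mathrm{var}(\hat\theta)$, floored at zero, over non-extreme persons.

Class intervals default to 10 quantile groups merged from the top until
each holds at least 25 persons; DIF factor levels with fewer than 30
persons are merged into `"other"` with a warning. Each diagnostic applies
its Bonferroni correction within its own family (the number of items),
matching per-analysis usage.

## What the simulator emulates — and what it does not

`simulate_responses()` draws person locations from a normal distribution
and every response cell from the partial credit model, with four injectable
departures: uniform DIF (a location shift for a focal group on one item),
local dependence (copying a partner item's response with a given
probability), threshold disorder (reversing an item's generating
thresholds), and MCAR missingness. Each person has an independent
random sub-stream keyed off the master seed, so enlarging a sample never
perturbs existing rows.

`trial_population_preset()` mirrors the pooled baseline cohort of the six
ranibizumab trials the revision was developed on: $n = 2487$, a 28-item
two-domain bank whose item locations span $-2.25$ to $+2.25$ logits
(threshold spacing 0.75 logits), and a ceiling-shifted ability distribution
$\theta \sim N(+1.0, 1.5)$. Under these conditions roughly 9–10% of
simulated persons sit above the instrument's threshold coverage — the
ceiling effect in the Rasch targeting sense. We deliberately report *two*
ceiling quantities: the proportion above the highest threshold and the
proportion at the maximum raw score. For an ordered polytomous bank of 28
items the probability of a perfect raw score is necessarily small (every
item must land in its top category), so the above-coverage proportion is the
scientifically meaningful ceiling measure for this design; the max-raw-score
share in real VFQ data is additionally driven by response behaviour the
PCM does not model (e.g. acquiescent all-best responding).

Other real-data features the generator does not attempt: informative
missingness (skip patterns, the driving items), multidimensionality across
domains, person misfit, covariate structure (visual acuity, age, study).
Passing the simulation suites therefore shows the machinery is correct and
calibrated *under its own model*, not that any particular clinical dataset
fits that model.

## Numerical and statistical choices

* Newton steps are capped at 1 logit per parameter per iteration; the
  item-step Hessian receives a tiny ridge only if numerically singular.
* Person solves iterate to a $10^{-10}$ score-equation tolerance, so the
  invariant $|\sum_i (x - E)| < 10^{-6}$ holds for every non-extreme person.
* Under joint estimation the item-trait $\chi^2$ and the fit residuals run
  *conservative* on model-generated data (persons and items are fitted to
  the same responses, absorbing part of the residual variance). The
  calibration suite therefore checks the $\chi^2$ and DIF false-positive
  rates against a one-sided 99.9% binomial bound at the nominal Bonferroni
  level — no inflation beyond Monte-Carlo error — and additionally checks
  the DIF F-test (scale-invariant, hence well calibrated) against a
  two-sided interval.
* Rounding of cohort share percentages is half-up to one decimal,
  matching how trial summary tables print.

## Configuration that is provisional by design

The published description of the revision does not print per-item collapse
maps, nor a machine-readable domain assignment. Both therefore live in the
bank configuration (`inst/extdata/banks/vfq28r.json`), not in code:

* Domain membership follows the two-domain structure of the prior
  re-engineering literature and reproduces the printed 19/9 split:
  Activity Limitation = VF5–VF10, VF12, VF15C, VF16, VF16A, VF17–VF19,
  VFA3–VFA8; Socio-Emotional Functioning = VF11, VF13, VF14, VF20–VF25.
* Default collapse maps merge one adjacent category pair — the standard
  remedy for threshold disorder: difficulty items merge their two most
  severe substantive levels (`{1,2,3,4,5} -> {1,2,3,4,4}`), reverse-coded
  frequency/true-false items merge levels 2 and 3
  (`{1,2,3,4,5} -> {1,2,2,3,4}`).
* `recode_missing` renumbers the surviving levels contiguously from 1
  (the "not sure" removal leaves `{1,2,4,5}`, which becomes `{1,2,3,4}`),
  because PCM scoring needs contiguous categories.
* The "stopped doing this for other reasons" level is treated as missing
  in both classical and Rasch scoring.
* Each VFQ-28-R domain is calibrated as its own unidimensional scale
  (`score_responses(..., "vfq28r")`), consistent with reporting two domain
  scores; a joint calibration of all 28 items is what
  `evaluate_instrument()` performs when handed the full item set.

Correcting any of these requires editing a JSON file, not a release.

## Problem sizes used by the validation suites

The parameter-recovery study uses 1000 persons × 20 five-category items at
three seeds (item-location correlation ≥ 0.97, RMSE ≤ 0.15 logits observed
≈ 0.999 / ≈ 0.05). The null-calibration study uses 200 replicates of 300
persons × 8 four-category items; the power study uses 20 replicates of
1000 persons × 10 items with a 0.5-logit uniform DIF, a duplicated-item
pair, and one reversed-threshold item, each detected in well over 80% of
replicates. These sizes were chosen to estimate the relevant rates with
binomial Monte-Carlo error small relative to the margins being tested.

## Limitations

* Joint ML is consistent only as items and persons both grow; at very small
  item counts the $(L-1)/L$ correction under-corrects and locations retain
  mild spread bias.
* The extreme-score extrapolation (0.3 score units) is a convention;
  extreme persons' locations should be interpreted as bounds, not measures.
* The optional 0–100 rescaling of domain logits is a linear convenience
  anchored at the observable raw-score extremes; it has no published
  anchoring and is clearly labelled as such.
* Real VFQ-25 data remain non-public; all statistical guarantees here are
  demonstrated on the simulator described above.
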