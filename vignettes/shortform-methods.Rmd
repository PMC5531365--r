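---
title: "Methods: partial credit calibration and short-form validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partial credit calibration and short-form validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shortscreen)
```

## The problem

An 8-item ordinal screening questionnaire (the CUDIT-R layout: items 1–7
scored 0–4, item 8 scored 0/2/4) is to be shortened to 3 items while keeping
its ability to flag people who meet a DSM-5-style diagnosis (two or more of
10–11 symptoms). The package implements the full construction-and-validation
sequence: polytomous Rasch calibration, four item-selection strategies, ROC
cut-point optimization, and classification-agreement statistics, together
with a synthetic-cohort generator so that every stage can be exercised and
tested without respondent-level data.

## The measurement model

Item responses follow Masters' partial credit model (PCM). For person $n$
with measure $\theta_n$ and item $i$ with step thresholds
$\delta_{i1},\dots,\delta_{im_i}$,

$$
P(X_{ni}=k) =
\frac{\exp \sum_{j \le k} (\theta_n - \delta_{ij})}
     {\sum_{h=0}^{m_i} \exp \sum_{j \le h} (\theta_n - \delta_{ij})},
\qquad k = 0,\dots,m_i,
$$

with the empty sum equal to zero. With a single step this is exactly the
dichotomous Rasch model. Item information is the conditional variance of the
category score, $\operatorname{Var}(X_{ni}\mid\theta)$, which equals the
slope of the item's expected-score curve; test information is the sum over
items. All of this is exercised against hand-derived values and a
central-difference oracle in the test suite.

The PCM requires consecutive category codes starting at 0, so item 8's raw
0/2/4 codes are mapped to 0/1/2 for calibration and mapped back for raw
scoring (`cudit_raw_maps()`); raw totals therefore always match the
instrument (full form 0–32, short form 0–12).

## Estimation

`fit_jmle()` estimates persons and items jointly by alternating
per-parameter Newton–Raphson steps (damped at 1 logit per iteration).
Convergence requires the largest absolute score residual to fall below 0.01
and the largest parameter change below 0.001 logits, within 200 outer
iterations. When no anchors are supplied the scale is identified by
centering the mean item location at zero.

Numerical and degenerate-input choices:

* **Extreme scores.** Persons or items with all-minimum or all-maximum
  observed responses have no finite joint-likelihood estimate. They are
  excluded from estimation and afterwards assigned measures by a
  0.3-score-unit adjustment: the measure solving the score equation for an
  adjusted raw score 0.3 units inside the extreme. Each assignment is
  logged via a message.
* **Unobserved intermediate categories.** A category never observed for an
  item makes the adjacent steps inestimable; such categories are collapsed
  into their lower neighbour for estimation and the order-preserving
  recoding is returned in `category_maps`.
* **Anchoring.** Person measures listed in `anchors` are held fixed
  bit-for-bit; anchored fits skip centering, so items are calibrated on the
  externally supplied scale.
* **Dispersion correction.** Joint estimation with a short test over-spreads
  both person and item estimates: with 8 items we measured a dispersion
  slope of about 1.24 relative to the generating thresholds, in line with
  the classical $L/(L-1)$ inflation result for joint maximum likelihood.
  Unanchored fits therefore rescale the jointly estimated scale by
  $(L-1)/L$ (Wright's correction, $L$ = number of calibrated items) by
  default. In recovery simulations at $n = 500$ this brings the threshold
  root-mean-square error from roughly 0.24–0.37 down to 0.17–0.23 logits
  without affecting the ordering or fit diagnostics. Set
  `bias_correction = FALSE` for the raw joint-maximum-likelihood scale;
  anchored fits never apply the correction because the anchors pin the scale.
* **Recovery experiments** use step thresholds confined to ±1.6 logits
  (`recovery_delta()` in the test helpers). A unit-normal cohort of a few
  hundred persons populates every category in that band; steps placed 3–4
  logits out are informed by a handful of responses and their error is
  dominated by small-sample noise rather than by estimator quality, so they
  are not a useful recovery benchmark at these sizes.

Fit diagnostics are the standard mean squares — outfit (unweighted mean of
squared standardized residuals) and infit (information-weighted) — computed
per item and per person, with zero-variance observations excluded and
counted. `residual_pca()` eigendecomposes the item-by-item correlation
matrix of standardized residuals; a first eigenvalue near or below 2 is the
usual unidimensionality heuristic, and items loading together on the first
contrast share structure the model did not absorb.

## Item selection

Four strategies nominate a $k$-item short form (default $k = 3$); all are
deterministic given the data.

* **Information matching (`select_tcc`).** The full form's test information
  curve is evaluated on a −6..6 grid with step 0.01 (covering the
  instrument's effective range at a resolution below reporting precision)
  and its peak $\theta^*$ located. Every $k$-subset is scored by the
  distance between its own information peak and $\theta^*$; ties go to the
  larger subset information at $\theta^*$, then to item order. The search is
  exhaustive through 12 items (all $\binom{8}{3}=56$ triples are recorded in
  the trace) and greedy beyond. "Most closely matched" admits another
  reading — overall curve similarity — so an integrated
  mean-absolute-difference criterion is available via
  `criterion = "integrated"`. Note that the argmax-distance criterion is
  sensitive at sub-grid scale: a weak off-peak item can tilt the full-form
  peak by one grid step, making subsets that share the tilt look marginally
  closer.
* **Rasch regression (`select_rasch_regression`).** Every person is anchored
  at their diagnosis value (negative = 0, positive = 1 logit; the values are
  configurable because only their gap matters), items are calibrated on that
  anchored scale, and items are ranked primarily by the point-measure
  correlation — the correlation between item scores and the anchored
  measures, i.e. the item's ability to differentiate the two groups — with
  the fit composite $|\mathrm{infit}-1| + |\mathrm{outfit}-1|$ and the
  first-contrast loading as tie-breakers. All three criteria are reported in
  the trace. We found that mean-square fit statistics alone cannot lead this
  ranking: with every person pinned at 0 or 1 logits, any trait-driven item
  calibrates to its own observed rates and its mean squares concentrate near
  1, so a fit-first ordering is essentially noise, while the point-measure
  correlation cleanly and reproducibly prefers items whose thresholds
  straddle the anchor gap.
* **Forward stepwise logistic regression (`select_stepwise_logistic`).**
  Item scores enter a logistic model of the diagnosis as numeric covariates.
  Entry is by Rao score test (p < 0.05), removal by the chosen criterion
  (Wald, likelihood ratio with refit, or the refit-free "conditional"
  likelihood ratio evaluated at the current estimates with the coefficient
  zeroed) at p > 0.10 — the conventional stepwise defaults. Complete
  separation triggers a ridge-penalized refit (penalty $10^{-4}$, intercept
  unpenalized), flagged in the trace. The internal IRLS fitter is verified
  against `glm()` in the tests.
* **Stepwise discriminant analysis (`select_stepwise_dfa`).** Classic
  Wilks'-lambda stepwise selection with F-to-enter 3.84 and F-to-remove
  2.71. Candidates that would make the total SSCP singular (duplicated or
  collinear items) are skipped; a perfectly discriminating candidate drives
  lambda to zero and enters with infinite F.

The stepwise methods stop early when no candidate passes the entry
threshold, so "select all items" is only guaranteed for the threshold-free
methods (information matching, Rasch regression).

## Classification metrics

Conventions, chosen once and applied everywhere:

* Screen-positive means score **at or above** the cut.
* ROC candidate cuts are every distinct observed score plus a sentinel above
  the maximum; AUC is the trapezoidal area, which equals the Mann–Whitney
  statistic with ties counted one half. The optimal cut maximizes Youden's
  $J = se + sp - 100$, with ties resolved toward the **lowest** cut (a
  screen should favour sensitivity).
* The AUC interval uses the Hanley–McNeil standard error. The software used
  for the original tables is closed and its interval method unverifiable, so
  intervals are reported but never treated as reproduction targets.
* Pearson chi-square for a 2×2 table is computed without continuity
  correction and referred to **1** degree of freedom; reports carry a
  footnote because some published tables print df = 2 for the same
  statistic.
* Report statistics are formatted to 2 decimals with ties rounded away from
  zero, matching the convention of the clinical statistics packages whose
  output the report emulates.
* Cronbach's alpha and all total-score analyses use listwise deletion, with
  the number of dropped persons logged.

## The synthetic cohorts

`generate_cohort()` draws a latent problematic-use trait
$\theta \sim N(\mu, \sigma^2)$ per person and makes it drive both sides of
the validation: item responses via the PCM, and each of $S$ diagnostic
symptoms independently via $\Pr(s) = \operatorname{logit}^{-1}(a\theta +
b_s)$. Diagnosis is a symptom count of 2 or more; severity uses the DSM-5
count bands (mild 2–3, moderate 4–5, severe 6+). The slope defaults to
$a = 1.7$ (the usual logistic-for-probit scaling), and everything is
deterministic given the seed, with the global RNG state untouched.

The two default specifications emulate the study conditions: $n = 207$ with
10 symptoms and $n = 369$ with 11. Their constants were calibrated once,
offline, by integrating over the trait distribution: item locations (with
fixed step offsets ±1.5 logits for items 1–7 and ±0.75 for item 8) solve for
the published per-item endorsement margins, and the equally spaced
symptom-intercept ladders (spacing 0.5 and 0.25) solve for the published
diagnosis prevalence (47% / 46%). The achieved mean symptom counts (about
1.9 and 2.1 against 1.84 and 2.27 reported) were checked but not separately
enforced; prevalence was the binding target.

What the generator does **not** emulate: item content; any
diagnosis-specific discrimination structure beyond the single shared trait
(thresholds were calibrated to endorsement margins only, so which items an
algorithm selects on a synthetic cohort need not match the published 3/5/6
short form — on synthetic cohorts the high-endorsement consumption items
often carry the most central information and a fixed short-form cut of 2
then classifies nearly everyone positive); craving-related content
differences between the two samples (only the symptom count differs); and
test–retest structure. Passing tests therefore show that the pipeline's
statistics behave correctly under the assumed generative structure, not that
the published item choice would re-emerge from real data.

## Problem sizes and runtime choices

The test suite calibrates cohorts of 120–1000 persons for estimator checks,
uses 5000 only to demonstrate that threshold error keeps shrinking, checks
generator calibration at $n = 10^4$, and runs the end-to-end study at the
emulated sizes (207/369) plus twenty replicates at $n = 2000$ for the
full-form/short-form AUC comparison. The acceptance script averages
parameter recovery over three $n = 500$ cohorts.

## Known limitations

* Joint maximum likelihood remains inconsistent in the number of items even
  after the dispersion correction; residual threshold bias of a few percent
  of $|\delta|$ persists at any $n$. Marginal or Bayesian estimation is out
  of scope by design.
* The 2-point anchored calibration behind Rasch regression is a coarse
  measurement model; its ranking should be read as a diagnosis-alignment
  screen, not as a calibrated item hierarchy.
* AUC confidence intervals are asymptotic (Hanley–McNeil); exact or DeLong
  intervals are not provided.
* With heavy ties (integer scores), the ROC is evaluated only at observed
  cuts; fractional cuts are never considered, matching how the instrument is
  used.
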