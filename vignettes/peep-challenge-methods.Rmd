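---
title: "Methods: PEEP-challenge dynamic indices and fluid-responsiveness prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PEEP-challenge dynamic indices and fluid-responsiveness prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peepchallenge)
```

## The clinical question and the model

During one-lung ventilation (OLV) the cyclic intrathoracic pressure swings
that drive heart–lung interaction are damped: the non-ventilated lung is
open to atmosphere, tidal volumes are small, and part of the pulmonary
circulation is shunted. The dynamic preload indices that normally predict
fluid responsiveness —

\[
\mathrm{PPV} = \frac{PP_{max} - PP_{min}}{(PP_{max} + PP_{min})/2}\times 100\,\%,
\qquad
\mathrm{SVV} = \frac{SV_{max} - SV_{min}}{(SV_{max} + SV_{min})/2}\times 100\,\%
\]

— therefore read low and discriminate poorly. A transient PEEP challenge
(raising PEEP from 0 to 10 cmH2O for a few minutes) restores larger cyclic
intrathoracic pressure swings; in preload-dependent patients this amplifies
PPV and SVV, so the *change* in the indices across the challenge,
\(\Delta\mathrm{PPV} = \mathrm{PPV}_{T2} - \mathrm{PPV}_{T1}\) and
\(\Delta\mathrm{SVV} = \mathrm{SVV}_{T2} - \mathrm{SVV}_{T1}\), carries the
discriminating signal. The protocol has four time points: T1 (zero-PEEP
baseline), T2 (during the challenge), T3 (second baseline after PEEP
withdrawal) and T4 (after a 6 mL/kg crystalloid bolus). A patient is a
*fluid responder* if stroke volume rises by at least 10% from T3 to T4
(the boundary value counts as a responder).

The package implements this analysis end to end: index computation from
beat-level data, responder classification, empirical ROC curves with
Hanley–McNeil inference, gray-zone analysis, group comparison tables, and a
synthetic cohort generator that makes every stage testable without patient
data.

## Index computation from beats

`segment_cycles()` assigns beats to respiratory cycles using half-open
windows `[mark_k, mark_{k+1})`; a beat exactly on a mark belongs to the
later cycle, which makes the assignment deterministic. A window with fewer
than two beats cannot produce a max/min envelope; it is flagged invalid and
excluded rather than imputed. `averaged_reading()` averages the per-cycle
values over the first run of `k = 3` *consecutive* valid cycles, matching
the bedside convention of recording the index over three consecutive
respiratory cycles; if no such run exists it fails loudly, naming the
deficit. Values are carried at full precision internally and rounded only
for display.

No ectopic-beat or artifact rejection is implemented: the study design this
pipeline serves excludes arrhythmia, and signal processing of the arterial
waveform itself (beat detection, Doppler integration) is out of scope. The
per-window validity flags give callers the hook to apply their own
exclusions.

## The synthetic cohort generator

`generate_cohort()` draws patients from per-group normal distributions
(`default_distributions()` packages the published group means and SDs for
18 responders and 22 non-responders). Three modeling choices matter:

* **Changes are primary.** For every variable with both a baseline row and
  a change row, the post value is *derived* as baseline draw + change draw.
  The within-patient change then follows the published change distribution
  exactly (responder \(\Delta\mathrm{SVV}\sim N(2.3, 1.7^2)\), non-responder
  \(N(-0.5, 1.8^2)\), and so on), and the delta always equals T2 − T1 by
  construction. The price is that the *derived* T2 marginal SD (about 2.9
  for responder SVV) differs from the printed marginal SD (3.3): the
  printed table is not jointly consistent, and we prioritize the change
  column because the deltas are the predictors under study. When a spec
  subset contains only a T2 row, the generator falls back to drawing that
  marginal directly.
* **Correlation.** The source tables report no joint distributions. PPV and
  SVV are drawn jointly with correlation `rho = 0.6` (configurable) within
  each block — baseline pair, change pair — because both indices reflect
  the same cyclic preload variation. Blocks are mutually independent; in
  particular change draws are independent of baseline draws, which keeps
  the change-column SDs exact. Group-level discrimination (AUC) depends
  only on the per-group marginals of each single predictor, so results are
  insensitive to `rho`; it matters only for paired AUC comparisons, where
  it is the quantity being estimated from data anyway.
* **Truncation.** PPV/SVV levels are truncated below at 0.1% (they are
  strictly positive percentages). At the packaged parameters this affects
  roughly 1–3% of draws (most often derived non-responder T2 values); the
  count is reported via the `n_truncated` attribute so users can see it.

`generate_beats()` realizes a target index as a sinusoidal respiratory
modulation of the beat-level series:
\(PP_i = \overline{PP}\,(1 + \tfrac{\mathrm{PPV}^*}{200}\sin(2\pi t_i/T_{resp} + \phi)) + \varepsilon_i\).
With that depth the modulation envelope has exactly the target variation,
so with zero noise and beats sampled at the extremes the computed per-cycle
PPV equals the target. The phase \(\phi\) is randomized per series;
`phase = "aligned"` pins the first beat to the modulation maximum for exact
recovery tests (exact when the beats-per-cycle ratio is an even integer).
With the monitor-like 6 beats per cycle (the typical heart-rate to
respiratory-rate ratio during OLV) the discrete sampling under-reads the
envelope by up to \(1-\cos(\pi/6)\approx 13\%\) relative — a real property
of monitor-displayed indices, reproduced rather than hidden.
`end_to_end_cohort()` composes the two generators: targets drawn from the
cohort distributions, indices *computed* from the simulated beats, labels
optionally re-derived from the simulated stroke-volume response.

What the generator does **not** emulate: physiologic coupling (no
Windkessel/ODE model of the PEEP effect), non-normal tails, measurement
drift of the Doppler probe, or operation-time covariates. Passing tests
therefore demonstrate that the statistical machinery is correct under the
stated distributional assumptions, not that those assumptions hold in any
particular patient population.

## ROC analysis and Hanley–McNeil inference

`empirical_roc()` uses the "score strictly greater than cutoff ⇒ positive"
convention (published cutoffs of the form "> 0%" follow this convention),
takes thresholds at the distinct observed values with a −Inf endpoint, and
computes the AUC by the trapezoidal rule — which on the empirical curve
equals the tie-corrected Mann–Whitney statistic \(U/(n_+ n_-)\) with ties
counted one half (a property-tested identity). Mid-point threshold
refinement between observed values (as some commercial packages do) is not
implemented; cutoffs are observed values.

The AUC standard error is the Hanley–McNeil closed form
\(SE^2 = [\theta(1-\theta) + (n_+-1)(Q_1-\theta^2) + (n_--1)(Q_2-\theta^2)]/(n_+ n_-)\)
with \(Q_1 = \theta/(2-\theta)\), \(Q_2 = 2\theta^2/(1+\theta)\); the 95% CI
is the normal band truncated to [0, 1], and the test against
non-discrimination uses the SE evaluated under \(\theta_0 = 0.5\). A
degenerate empirical AUC of exactly 0 or 1 is nudged inward by half a
concordance step before the SE is evaluated (the formula is undefined at
the boundary). At n = 18/22 the resulting 95% CI covers the true binormal
AUC in about 93% of cohorts (measured by simulation in the test suite) —
slightly anticonservative, as expected of this approximation; p-values are
two-sided throughout.

`compare_aucs()` implements the z-test
\(z = (\theta_a - \theta_b)/\sqrt{SE_a^2 + SE_b^2 - 2 r\,SE_a SE_b}\).
For paired designs the correlation \(r\) is estimated as the average of the
within-class Spearman rank correlations between the two predictors. This is
the quantity with which the classical intermediate-correlation lookup table
is entered, and for mid-range AUCs the table maps it nearly one-to-one onto
\(r\); we use the direct estimate rather than embedding a reconstructed
grid. `permutation_auc_test()` (random within-patient swapping of the two
predictors) is the assumption-free cross-check, and tests confirm the two
agree on the scale that matters for interpretation.

`youden_cutoff()` maximizes \(J = Se + Sp - 1\), breaking ties toward the
smallest cutoff, and reports operating-point Se/Sp/PPV/NPV in percent with
Wald intervals \(p \pm 1.96\sqrt{p(1-p)/n}\) truncated to [0, 100] —
truncated Wald, not Clopper–Pearson, because published bounds of the form
"66–100" follow the truncated-Wald style. Predictive values use the sample
prevalence; an empty denominator yields NA, never 0.

`sample_size_auc()` searches for the smallest per-group n satisfying
\(|\theta_1-\theta_0| \ge z_{1-\alpha/2} SE_0 + z_{1-\beta} SE_1\) with
both SEs from the Hanley–McNeil formula. At the conventional design values
(alternative AUC 0.8 vs null 0.5, two-sided α = 0.05, power 0.9, 1:1
allocation) this gives 17 per group, 34 total. Commercial sample-size
software reports 36 for the same inputs; its internal formula is not
disclosed, so this operation documents its method rather than reproducing
that number — the search itself is exact, monotone in effect size, and
property-tested.

## Gray zones

Two constructions are computed side by side and never merged (no principled
merge rule exists):

* **Bootstrap CI of the optimal cutoff** (`bootstrap_thresholds()` +
  `gray_zone_from_bootstrap()`): 1,000 resamples of the cohort, stratified
  by responder status so every replicate keeps 18/22 (unstratified
  resampling at n = 40 can lose a class), each yielding a Youden-optimal
  cutoff; the zone is the 2.5th–97.5th percentile interval with the
  linear-interpolation quantile definition (pinned so zones are
  bit-reproducible under a fixed seed).
* **Split-curve zone** (`split_curve_zone()`): cutoffs achieving neither
  sensitivity ≥ 90% nor specificity ≥ 90% are inconclusive. Because Se is
  non-increasing and Sp non-decreasing in the cutoff, the zone is the
  interval between the last cutoff keeping Se ≥ 90% and the first reaching
  Sp ≥ 90%; when these overlap the zone is empty and is represented as a
  zero-width interval at the boundary cutoff.

`count_inside()` uses closed-interval membership ("between a and b"
includes the endpoints); an empty zone counts exact boundary ties only.
For a predictor with no discriminating power the bootstrap zone can be
unbounded below (the optimal cutoff degenerates to "call everyone
positive") — reported as is, since an uninformative predictor *should*
show an uninformative zone.

## Group comparison layer

`compare_between_groups()` screens continuous variables for normality
per group (Shapiro–Wilk at α = 0.05 — the screening criterion is a
documented package choice, as reporting conventions rarely state one) and
applies Student's t-test (equal variances) or the Mann–Whitney U test;
categorical variables use the uncorrected chi-square test unless any
expected cell is below 5, in which case Fisher's exact test is substituted.
On the published 2×2 gender contrast (16/2 vs 14/8) the minimum expected
cell is 4.5, the rule selects Fisher, and the p-value reproduces the
printed 0.082 at printed precision. `compare_within_group()` applies the
paired t-test when the paired differences pass the same screen, else the
Wilcoxon signed-rank test; the reported change summary is exactly the
mean ± SD of (after − before). No multiplicity adjustment is applied,
matching the reporting layer this reproduces.

## Problem sizes, determinism and numerical choices

The test suite and the acceptance script size their simulations for
precision commensurate with the assertions made: 1,000 replicate cohorts
for mean-AUC and CI-coverage checks (Monte-Carlo SE of a mean AUC at
n = 18/22 is ≈ 0.002), 50,000 per group for closed-form binormal limits
(tolerance 0.005), 200 simulated series for beat-level recovery, 1,000
random instances for the trapezoid/Mann–Whitney identity at 1e−12.
All randomized stages accept explicit seeds; a fixed seed makes cohorts,
bootstrap zones and the full workflow byte-reproducible. Ties in scores are
handled by the ½-credit convention everywhere (ranks, trapezoid, Youden
enumeration), and all tie-breaks (smallest cutoff, later cycle at a mark)
are deterministic.

## Known limitations

* The gray zones and cutoffs of any single simulated cohort are sampling
  realizations — at n = 40 they vary visibly from seed to seed; only
  distributional statements (mean AUC, CI coverage) are stable targets.
* The Hanley–McNeil SE is an approximation keyed to the AUC alone; it
  ignores the shape of the score distributions and is mildly
  anticonservative at small n (coverage ≈ 93% rather than 95% here).
* The paired-AUC correlation estimate substitutes the within-class rank
  correlation for the classical tabulated intermediate value; for extreme
  AUCs (> 0.95) the two can diverge, which is why the permutation test is
  bundled.
* The beat-level model is a single-frequency modulation; real arterial
  traces carry baroreflex and low-frequency components that bias monitor
  PPV in ways this generator does not emulate.
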