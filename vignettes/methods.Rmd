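---
title: "Methods: trial-based cost-effectiveness and cost-utility analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-effectiveness and cost-utility analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceatrial)
```

`ceatrial` implements a trial-based economic evaluation from the societal
perspective for a three-arm randomized trial of smoking-cessation support:
internet-based multiple computer tailoring plus a practice-nurse counselling
session (MTC), multiple tailoring only (MT), and usual care (UC). This
vignette explains the model, the parameters that matter, the synthetic-data
generator used in place of the (undeposited) participant-level data, the
numerical choices, and the known limitations.

## The evaluation model

The evaluation follows the standard five steps: identify costs and effects
under the chosen perspective, measure them over the 12-month follow-up
(waves at 0, 6 weeks, 6 months, 12 months), value them, compute incremental
ratios, and quantify uncertainty.

**Costs.** Annual cost per participant is the sum of a fixed per-arm
programme cost and valued health-care use. Resource-use counts come from
3-month retrospective recall questionnaires at each wave; each follow-up
window's cost is scaled by (gap since the previous wave)/(recall length,
0.25 y), and the baseline window — which covers the three months *before*
randomization — is excluded. With the default wave grid the follow-up
weights are 0.46, 1.54 and 2.0, summing to 4, so a constant per-window cost
`c` annualizes to `4c`. This gap-weighting covers the full 12-month horizon
exactly once; it is our choice where the source design was silent on
annualization, and it also resolves the overlap between the 6-week recall
window and the baseline window without double counting (hence
`annualize_costs()` validates strictly increasing wave times rather than
literal window disjointness).

Unit prices are 2009 Dutch standard prices (with real costs, tariffs, or the
lowest price where no standard price exists), indexed multiplicatively to
the 2011 price year with consumer price indices 105.38 → 109.02. Medication
is costed per defined daily dose with 6% VAT, a €6.00 prescription charge
per dispensed course, and the statutory pharmacist clawback; the clawback
rate (default 6.82%) and the charge are configuration defaults, overridable,
since only the concepts — not the rates — are fixed by the costing manual
convention. Euro amounts are kept at full precision internally and rounded
to 2 decimals only when artifacts are written.

Programme costs per participant are €57.70 (MTC), €7.70 (MT) and €0 (UC) in
the primary scenario. The sensitivity scenario monetises participants' time
and travel into the programme cost: €141.89 and €82.24, i.e. per-participant
increments of €84.19 and €74.54.

**Effects.** The cost-effectiveness outcome is prolonged abstinence at 12
months (status 2 = abstinent, internally coded 0/1; differences are
unaffected by the coding). The cost-utility outcome is the QALY, accumulated
by area under the utility–time curve over the 12-month horizon, with
utilities scored from EQ-5D-3L item levels by the Dutch tariff — an additive
model over the 243 states anchored at 11111 → 1.0 with floor −0.329. Any
complete value set can be substituted via a 243-row CSV.

**Incremental analysis and uncertainty.** For each pair of arms we report
ΔC, ΔE, the ratio ΔC/ΔE when ΔE ≠ 0, and the cost-effectiveness-plane class
(dominant / dominated / trade-off). Because ratios only compare two arms,
multi-arm comparison uses the net monetary benefit NMB = ΔE·λ − ΔC at
willingness-to-pay λ; the headline λ is €18,000, the accepted Dutch
threshold per QALY. Sampling uncertainty is handled by a nonparametric
bootstrap that resamples participants with replacement *within* arms,
preserving the randomized arm sizes — our choice where the source design was
silent; it respects the design and keeps per-arm contrasts interpretable.
Defaults are 5,000 replicates for cost confidence intervals (95% percentile
intervals, linear-interpolation quantiles) and 1,000 for acceptability
curves, both configurable. The acceptability curve reports, at each λ on a
default grid of 0–100,000 by 500, the fraction of replicates in which each
arm attains the strictly highest per-arm NMB `E·λ − C` (the common reference
cancels); exact ties are split equally among the tied arms, so the
probabilities sum to 1 at every λ, which is unbiased for degenerate
replicates.

## Missing data

All analyses are intention-to-treat. For costs, EQ-5D items and the FTND
score, an interior missing wave whose two immediate neighbours are observed
takes their mean; all other gaps use last observation carried forward, and
leading gaps next observation carried backward. Imputed EQ-5D items are
rounded back to levels 1–3; a neighbour mean of exactly x.5 rounds *up*,
toward the more severe level — our choice where the rounding direction was
open, conservative on utility and symmetric in spirit with the abstinence
rule. Missing abstinence always takes the negative scenario: participants
lost to follow-up are considered still smoking, so imputation can never
increase the number of abstainers. A series that is missing at every wave
cannot be imputed; such records are excluded from cost (or QALY) analyses
but retained for abstinence, which is always imputable. When only one
neighbour of an interior gap is observed, LOCF applies (the other open
question in the rules); item-level rather than utility-level imputation is
used so that every imputed state is a valid EQ-5D state.

## The synthetic-trial generator

The generator exists so that every downstream stage is testable without the
original data; its defaults *are* the study conditions and are not tuned per
analysis.

- **Design**: arms of 163/132/119; waves at 0, 0.115, 0.5, 1.0 years.
- **Abstinence**: a per-participant prolonged-quit indicator drawn with arm
  probabilities .086/.152/.101 fixes the 6- and 12-month status; transient
  early quitting adds realistic point-prevalence noise at 6 weeks.
- **Costs**: per-category counts per recall window are negative-binomial
  (dispersion 1.5) with per-arm euro means taken from the trial's baseline
  3-month cost profile, divided by the indexed unit price; costs are then
  counts × price, which reproduces the heavy-tailed pattern of annual cost
  data (hospital SD far exceeding its mean) and guarantees positive skew
  whenever dispersion is positive.
- **Utilities**: EQ-5D item levels are drawn from a one-factor ordinal
  probit model — a person-level severity factor plus per-dimension
  thresholds — and then *scored*, so the scoring path is exercised
  end-to-end rather than sampling utilities directly. The per-dimension
  level probabilities are scaled by a severity multiplier calibrated at run
  time (1-D quadrature over the person factor plus root finding, seed-free
  and deterministic) so the expected scored utility equals `utility_mean`
  (default 0.8); `utility_sd` maps to the factor loading, giving an emergent
  SD ≈ 0.2 at defaults. The base per-dimension probabilities concentrate
  complaints in pain/discomfort and anxiety/depression, as is typical for a
  middle-aged smoking population.
- **Dropout**: each participant is lost to follow-up with probability
  logistic in age; the intercept is calibrated by root search against the
  realized ages so the marginal rate equals `dropout_rate` (default .442,
  with the reported age direction: default −0.05 log-odds per year).
  Missingness is monotone — a dropout's first missing wave is uniform among
  follow-up waves, and everything measured from that wave on is missing;
  baseline is never missing. The source reports only the 12-month marginal
  rate, so intermediate-wave rates are a free parameter; the uniform choice
  spreads them evenly.

What the generator does **not** emulate: arm-specific quality-of-life
trajectories (utilities are exchangeable across arms), correlation between
cost and smoking status, seasonal or practice-level clustering, item-level
(as opposed to wave-level) missingness, and cotinine validation. Passing
tests on synthetic data therefore demonstrate the correctness of the
pipeline's arithmetic and its statistical properties (parameter recovery,
interval coverage, curve coherence) — not that real-data results would be
re-derived.

## Numerical choices

- **AUC rule**: trapezoid (linear interpolation between waves) by default.
  The verbal description of the QALY calculation is rectangle-like
  (duration × quality weight), but the trapezoid is the standard trial-based
  convention; the rectangle rule is available (`auc_method = "rectangle"`)
  for sensitivity. Both reproduce the worked example — a year at constant
  utility 0.8 is 0.8 QALYs — exactly, since the rules agree on constant
  profiles.
- **Percentiles**: linear-interpolation empirical quantiles (R type 7).
- **Ratio at ΔE = 0**: undefined (NA); the class is then taken from the
  cost sign alone.
- **Chi-square**: uncorrected Pearson statistic (the published statistics
  match the uncorrected form); one-way F from the standard sums of squares.
  Both are cross-checked against independent reference implementations to
  1e-10 in the test suite.
- **Determinism**: one root seed; simulation, missingness, cost-bootstrap
  and CEAC-bootstrap draw from named substreams derived from it, so
  identical config + seed gives identical artifacts byte for byte.
- **Problem sizes in the test suite** (chosen to give tight Monte-Carlo
  error at interactive runtimes): 200 seeds for the retention calibration
  check, 500 simulation repetitions for percentile-interval coverage
  (asserted within ±3% of 95%), and 5,000 participants per arm for
  parameter recovery (ΔC, ΔE within 3 bootstrap SEs of truth).

## Known limitations and documented discrepancies

- The published incremental probability for the MTC–UC abstinence contrast
  (−.02) does not follow from the published arm-level counts, which give
  14/163 − 12/119 = −.015 (→ −.01 at two decimals); the adjustment behind
  the published "adjusted" costs and effects is unstated. The pipeline
  computes unadjusted incrementals, asserts the two reproducible cells
  (.05 and −.07), and records the third as non-reproducing.
- Whether the published acceptability curves used covariate-adjusted costs
  and effects is unknown; no adjustment is applied here.
- No extended-dominance frontier beyond pairwise classes, no lifetime
  extrapolation of QALYs, no multiple imputation, and no productivity-loss
  or informal-care module beyond a configurable price entry — all
  deliberately out of scope.
- The exact vintage of the Dutch tariff in the source is not stated; the
  shipped tariff is the published Dutch time-trade-off value set, and all
  scoring is value-set-agnostic.
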