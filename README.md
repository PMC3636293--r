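# ceatrial

Trial-based cost-effectiveness and cost-utility analysis for multi-arm
randomized controlled trials, built around the economic evaluation of a
three-arm smoking-cessation RCT (internet-based multiple computer tailoring
with and without practice-nurse counselling versus usual care) conducted from
a societal perspective.

It is aimed at health-economics analysts who need a tested, reproducible
pipeline for the standard five steps of a trial-based economic evaluation:
identification, measurement and valuation of costs and effects, calculation
of incremental ratios, and uncertainty analysis.

## What it computes

For arms *i* (intervention) and *c* (comparator) with mean annual costs *C*
and mean effects *E* (probability of prolonged abstinence, or QALYs):

- **ICER / ICUR** = (C_i − C_c) / (E_i − E_c), with dominance classification
  on the cost-effectiveness plane (*dominant*: cheaper and more effective;
  *dominated*: costlier and less effective).
- **Net monetary benefit** at a willingness-to-pay threshold λ:
  NMB = (E_i − E_c) × λ − (C_i − C_c); the package uses €18,000 (the accepted
  Dutch threshold per QALY) as the headline λ.
- **Acceptability curves** (CEAC/CUAC): the probability that each arm has the
  highest NMB as a function of λ, over a stratified nonparametric bootstrap
  (participants resampled with replacement within arms; ties split equally).
- **Percentile bootstrap 95% CIs** for pairwise annual-cost differences.
- **QALYs** by area under the EQ-5D-3L utility curve (Dutch tariff by
  default, trapezoid rule; rectangle rule available), over a 12-month
  follow-up measured at baseline, 6 weeks, 6 months and 12 months.
- **Costing**: resource-use counts from 3-month recall questionnaires valued
  at 2009 Dutch standard prices, CPI-indexed to 2011 (105.38 → 109.02);
  medication by defined daily dose with VAT, prescription charge and
  clawback; fixed programme costs of €57.70 / €7.70 / €0 per participant
  (€141.89 / €82.24 / €0 when patient time and travel are monetised in the
  sensitivity scenario).
- **Intention-to-treat imputation**: interior gaps by the mean of the
  neighbouring waves, otherwise LOCF (NOCB for leading gaps); missing
  abstinence treated as still smoking (negative scenario).
- **Group statistics**: uncorrected Pearson chi-square and one-way ANOVA F
  for baseline comparability and effect comparison.

Because the original participant-level data are not deposited, the package
includes a seeded synthetic-trial generator (`trial_config()`,
`generate_trial()`, `apply_missingness()`) reproducing the study's structure:
arms of 163/132/119, prolonged abstinence ≈ .086/.152/.101, baseline utility
≈ 0.8 (SD 0.2), right-skewed costs, and ≈44% age-dependent monotone loss to
follow-up.

## Worked example

```r
library(ceatrial)

# the published Table-4 inputs: incremental cost €255, incremental
# probability of abstinence .05 for tailoring-only vs usual care
incremental(list(cost = 255, effect = 0.05), list(cost = 0, effect = 0))
#>        label delta_cost delta_effect ratio       class
#>  treat vs ref        255         0.05  5100 tradeoff_NE
```

€5,100 must be paid per additional abstinent participant — the study's
headline ICER. At λ = €18,000 the same contrast yields
`nmb(0.05, 255, 18000)` = €645 of net monetary benefit.

A full synthetic run:

```r
cfg <- trial_config(seed = 7)
path <- tempfile(fileext = ".csv")
simulate_trial_csv(path, cfg)
res <- run_pipeline(path, tempdir(), config = analysis_config(seed = 7))
res$probabilities_at_wtp
#>                outcome   wtp p_MTC  p_MT  p_UC
#>   prolonged_abstinence 18000 0.015 0.615 0.370
#>                   qaly 18000 0.086 0.265 0.649
```

Read: at a willingness to pay of €18,000 per abstinent participant, the
tailoring-only arm has the highest net monetary benefit in 62% of bootstrap
replicates of this synthetic trial, while on the QALY scale usual care is
most likely to be efficient (65%) — the same qualitative ordering as the
study.

A command-line front end over the same functions is installed at
`inst/cli/ceatrial.R` (subcommands `simulate`, `validate`, `evaluate`,
`ceac-plot-data`).

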