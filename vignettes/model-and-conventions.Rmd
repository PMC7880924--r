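---
title: "The decision model, its conventions, and why the defaults are what they are"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The decision model, its conventions, and why the defaults are what they are}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctpcea)
```

## The clinical question and the model

Patients with a previous coronary stent who present with suspected
obstructive coronary artery disease (CAD) or in-stent restenosis (ISR) can
be triaged with coronary CT angiography (CTA), stress myocardial CT
perfusion (CTP), or both. CTA is nearly perfectly sensitive in this
population but — because stent struts blossom into beam-hardening artifact —
badly unspecific (specificity 0.386 here), so it sends many disease-free
patients to an unnecessary invasive coronary angiography (ICA). CTP trades a
little sensitivity (0.914) for much better specificity (0.789). The
combined reading used by the source accuracy study calls every discordant
pair positive, which restores sensitivity 1.000 but crushes specificity to
0.429.

`ctpcea` turns this into a two-stage decision-analytic model:

1. **Decision tree.** For a pre-test probability $p$ of a stenosis requiring
   percutaneous transluminal coronary angioplasty (PTCA) and a test with
   sensitivity $se$ and specificity $sp$, the joint outcome probabilities
   are $TP = p\,se$, $FN = p(1-se)$, $FP = (1-p)(1-sp)$, $TN = (1-p)sp$.
   Acute, time-0, undiscounted costs: imaging for everyone; a timely PTCA
   for true positives; a delayed PTCA, 1.3 times as expensive, for false
   negatives; an unnecessary ICA for false positives; nothing for true
   negatives.
2. **Markov cohort model.** Three states — alive without symptomatic
   stenosis requiring therapy, alive with such a stenosis, dead — in annual
   cycles. Yearly transition risks: new relevant stenosis 0.0264, death with
   stenosis 0.0230, death without 0.0232, other-cause death 0.0126. State
   rewards per year: \$5837.27 / utility 0.75 without stenosis, 1.3 × that
   cost / utility 0.70 with stenosis. Costs and QALYs are discounted at 3%
   per year; the horizon is 10 annual cycles from age 65.

Cost-effectiveness is read off with net monetary benefit
($NMB = \lambda E - C$ at willingness to pay $\lambda$ = \$100{,}000/QALY),
incremental NMB, ICER with dominance categories, and the efficiency
frontier. One-way deterministic sensitivity analysis re-runs the pipeline
across a parameter range; probabilistic sensitivity analysis draws all
distributed parameters (beta for probabilities and utilities, gamma for
costs) and reports the fraction of iterations in which CTP has positive
INMB against CTA, plus the acceptability curve.

## Parameters that matter, with units and defaults

| field | meaning | base value |
|---|---|---|
| `pretest_probability` | prevalence of PTCA-requiring stenosis | 0.6267 |
| `sens_cta`, `spec_cta` | CTA accuracy | 1.000, 0.386 |
| `sens_ctp`, `spec_ctp` | CTP accuracy | 0.914, 0.789 |
| `sens_combo`, `spec_combo` | combined reading (empirical) | 1.000, 0.429 |
| `cost_cta`, `cost_ctp` | acute imaging, USD (2019) | 397.87, 470.31 |
| `cost_ica`, `cost_ptca` | ICA+FFR, timely PTCA, USD | 2810.00, 4678.00 |
| `cost_ptca_delayed` | 1.3 × PTCA while linked | 6081.40 |
| `yearly_cost_no_stenosis` | maintenance cost, USD/year | 5837.27 |
| `yearly_cost_stenosis` | 1.3 × the above while linked | 7588.45 |
| `utility_no_stenosis`, `utility_stenosis` | QALY weights per year | 0.75, 0.70 |
| `p_new_stenosis` | annual new-stenosis risk | 0.0264 |
| `p_death_stenosis`, `p_death_no_stenosis`, `p_death_other` | annual death risks | 0.0230, 0.0232, 0.0126 |
| `wtp`, `discount_rate`, `horizon_cycles`, `start_age` | analysis settings | 100000, 0.03, 10, 65 |

The `linked_assumption` flag (default on) keeps `cost_ptca_delayed` and
`yearly_cost_stenosis` at 1.3 × their partners everywhere — including
deterministic and probabilistic sensitivity analyses — and keeps the
combined strategy's imaging cost at `cost_cta + cost_ctp` (both scans are
performed). Explicitly setting a dependent field decouples it.

## Conventions: the choices the source analysis leaves open

The published description pins down the inputs but not the model's
accounting. Every such choice is a named flag in `cea_conventions()` so any
result can state exactly what produced it.

**Entry convention** (`entry`). The mapping from diagnostic branch to entry
state is not stated. Three policies are provided:

* `"all-treated"` (**default**): everyone enters the well state — positives
  are revascularized at entry (the acute cost already paid), false
  negatives' delayed treatment is likewise an acute cost, true negatives
  are disease-free.
* `"fn-diseased"`: false negatives spend their first year with untreated
  stenosis.
* `"positives-decrement"`: all test positives spend the peri-procedural
  year in the stenosis state, carrying its utility decrement and cost
  premium.

Why the default is `"all-treated"` and not the clinically literal
`"fn-diseased"`: CTA's sensitivity is 1.000, so CTA produces no false
negatives while CTP does — under `"fn-diseased"` CTP necessarily has
*fewer* QALYs than CTA, the opposite of the published ordering, and the
headline dominance result cannot be reproduced. Under `"all-treated"` the
achieved base case is

```{r base-case}
params <- cea_parameters()
res <- run_base_case(params)
results_table(res)
compare(res$CTP, res$CTA, params$wtp)
```

CTP is strictly cheapest with QALYs tied across strategies, so CTP
dominates both alternatives and is the whole efficiency frontier, and the
costs land within 0.4% of the published totals (\$47,013.87 / \$46,758.83 /
\$47,455.63). Under `"positives-decrement"` — the only convention that
reproduces the published *strict* QALY ordering (CTP > CTA+CTP > CTA,
because CTA's false-positive mass is largest) — costs run about 3% above
the published totals:

```{r positives-decrement}
results_table(run_base_case(params,
  cea_conventions(entry = "positives-decrement")))
```

No convention reproduces the published QALY *levels* (6.84–6.93). They are
arithmetically unreachable: 6.84 QALYs at utility ≤ 0.75 requires at least
9.12 discounted person-years, but ten annual cycles discounted at 3% supply
at most 8.53 even with no mortality, while a lifetime horizon supplies
roughly 13 person-years and overshoots both QALYs and costs. The published
costs and QALYs are also mutually inconsistent: solving the two accounting
identities (cost and QALY totals as weighted person-years in the two living
states) for any horizon gives a negative with-stenosis occupancy. We
therefore report the model's own QALYs (≈ 5.51 per strategy at base case)
and treat the published effectiveness levels as not reproducible from the
printed inputs.

**Horizon.** The source states both a "lifetime horizon" and a 10-year
analysis window; we follow the explicit 10-year statement (it is also the
only horizon near the published cost levels). `lifetime_horizon()` switches
to running until age 100.

**Reward accrual.** State membership during cycle $t$ is the occupancy
after $t-1$ transitions; rewards for cycle $t$ are discounted at exponent
$t$ (end-of-cycle). A half-cycle correction (exponent $t - 0.5$) is
available behind `half_cycle` and off by default, since the source does not
mention one.

**Competing risks** (`risk_rule`). Per-cause annual risks are combined
multiplicatively by default, $1 - \prod_i (1 - p_i)$, which cannot exceed 1;
an additive rule is available for replicating spreadsheet-style models and
errors out when a row would exceed 1.

**Stenosis resolution** (`resolution`). The 0.0264 new-stenosis risk is a
yearly revascularization rate, so by default the stenosis state is a
one-year tunnel: its occupants carry the with-stenosis cost and utility for
one cycle and, surviving, return to the well state. A `"persistent"`
alternative keeps them there. Whether an in-model revascularization should
additionally be charged one PTCA is unstated in the source; the
`charge_incident_ptca` flag (default off — the 1.3× yearly cost premium
already represents the revascularization year's expenses; charging PTCA on
top would double-count) adds it for the incident flow only, never for the
entry cohort, whose procedures are acute costs.

**Other-cause mortality** (`mortality`). Default is the constant 0.0126.
An age-specific mode uses the schedule in
`inst/extdata/synthetic_life_table.csv` — a Gompertz–Makeham curve
($q_x = 0.002 + 0.0106\,e^{(\ln 2/8)(x-65)}$) anchored to 0.0126 at age 65
with an eight-year doubling time. It is a constructed, clearly synthetic
stand-in illustrating the age-dependent machinery, not national life-table
data.

## PSA hyperparameters

The source gives each input's distribution *family* (beta or gamma) but no
dispersion. Defaults, stated as assumptions and fully configurable in
`default_distributions()`: beta distributions are moment-matched with an
effective sample size of 150 (the source diagnostic-accuracy cohort) for
prevalence and accuracies and 100 for utilities and transition
probabilities; gamma distributions use a standard error of 20% of the mean
for every cost. Accuracies with base value exactly 1 (CTA and combined
sensitivity) are degenerate and stay fixed. Analysis settings are never
sampled. Each iteration has its own RNG substream keyed by iteration index
under the master seed, so a seed reproduces the sample sequence exactly.
With 30,000 iterations under these defaults, CTP has positive INMB against
CTA at \$100,000/QALY in about 95% of iterations (the source reports 99%
with unstated dispersions; the achieved fraction is recomputed, not
asserted, by `scripts/acceptance.R`).

## What the synthetic generators emulate — and what they do not

`generate_study()` reproduces the *statistical* structure of a prospective
accuracy study (binomial disease count at prevalence 62.67% in n = 150,
binomial test results per margin). It does not emulate reader variability,
stent-level clustering within patients, or verification bias.
`simulate_patients()` realizes the same decision tree and transition
process patient by patient; its agreement with `run_cohort()` (within 3
Monte-Carlo SEs at n = 10^5, tested for every strategy and entry/resolution
combination) validates the cohort engine's accounting, not the model's
clinical realism. Passing tests therefore show internal consistency and
faithfulness to the printed inputs — they cannot show that the three-state
structure, the 1.3× assumptions, or the utilities describe real stented
patients.

## Numerical choices and degenerate inputs

Internal arithmetic is double precision throughout; monetary rounding (2
decimals; QALYs 4, probabilities 6) happens only in the CSV report layer so
golden-file comparisons are stable. DSA grids default to 11 evenly spaced
points; a zero-width range is legal and yields identical points. Ranges
must bracket the base value unless `must_bracket = FALSE`. ICERs are never
printed for dominance quadrants, and a 0/0 comparison is category `"equal"`
rather than a division error. A horizon of 0 cycles returns acute costs and
zero QALYs. `fit_beta_moments()` at mean 0 or 1 degrades to a fixed spec
with a warning rather than an improper beta.

## Problem sizes used in the shipped checks

The test suite runs the microsimulation oracle at 10^5 patients per
strategy for the default-convention equivalence checks (5 × 10^4 for the
optional-flag spot checks) and the PSA at its full 30,000 iterations;
`scripts/acceptance.R` uses 30,000 PSA iterations and the deterministic
base case. These sizes put Monte-Carlo error well below the tolerances
being checked (3 SE at n = 10^5 is about \$60 on a \$47,000 total).

## Known limitations

* The published QALY levels (and hence exact base-case reproduction) are
  unreachable from the printed inputs, as quantified above; only the cost
  levels and the dominance structure are reproduced.
* Radiation-dose QALY adjustments, alternative modalities (CMR, SPECT,
  PET, CT-FFR), ICA procedural complications, and cost inflation machinery
  are out of scope by design.
* Under the default entry convention the three strategies differ only
  through acute costs, so QALY differences are zero by construction; use
  `"positives-decrement"` to explore utility-mediated differences.
* PSA draws are independent across parameters; no correlation structure is
  modeled beyond the deterministic 1.3× links.
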