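---
title: "Banded severity scoring: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Banded severity scoring: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sevband)
```

## The problem

European animal-research law requires licence holders to predict the
severity (pain, suffering, distress or lasting harm) of a procedure, to
keep individual animals below an agreed severity limit via humane
endpoints or intervention points, and to report the severity that actually
occurred. In subacute and chronic experiments (durations of a day or
more), the working assumption of this package is that the degree to which
measurable biological criteria — body temperature, body weight, body
condition, behaviour — deviate from an animal's normal baseline reflects
the impact of the experiment on that animal, without needing to name the
adverse state (pain versus distress versus dystress). `sevband` turns that
assumption into an auditable arithmetic pipeline.

The framework deliberately does **not** cover acute or hyperacute
suffering: intense short-lived states often leave no measurable trace in
criteria such as weight or temperature, and need behavioural assessment
instead. It also does not choose the criteria for you; sign selection is a
scientific decision made per study.

## The model

For each criterion $c$, animal $i$ and timepoint $t$, the deviation from
baseline is

$$
d_{ict} = \begin{cases}
  x_{ict} - b_{ic} & \text{(absolute kind)}\\
  100\,(x_{ict} - b_{ic})/b_{ic} & \text{(percent kind)}
\end{cases}
$$

signed according to the criterion's direction: one-sided schemes
(`increase`, `decrease`) clamp opposite-direction excursions to zero (with
a warning, since direction can genuinely flip with species and context —
small rodents may respond to infection with hypothermia rather than
fever); `either` takes the magnitude. The non-negative deviation is then
assigned to one of five bands delimited by four strictly increasing
boundaries $b_0 < b_1 < b_2 < b_3$:

$$[0, b_0],\; (b_0, b_1],\; (b_1, b_2],\; (b_2, b_3],\; (b_3, \infty)$$

scored $0$ (normal), $1$ (mild), $2$ (moderate), $3$ (severe), $4$ (beyond
severe, which includes death). The three middle bands mirror the legal
severity categories; the outer two are operationally necessary. Band
count is fixed at five for this reason — configurable band counts are out
of scope.

Group statistics at a timepoint, for a group of $N$ scored animals and $K$
criteria with group criterion averages $\bar s_1, \dots, \bar s_K$:

* **criterion average**: $\bar s_c = \tfrac{1}{N} \sum_i s_{ic}$;
* **overall impact score**: $N \cdot \tfrac{1}{K}\sum_c \bar s_c$ (the
  published formula is stated for two criteria; the generalisation divides
  by the number of criteria used, weighting criteria equally — no
  alternative weighting is defined by the framework);
* **per-animal average impact**: overall score $/\,N$, algebraically the
  unweighted mean of the criterion averages;
* **individual animal score**: the mean of one animal's criterion scores,
  the quantity checked against its severity limit.

Verdicts use strict inequality: an individual score of exactly the
limit's ordinal is *at*, not over, the limit, and a per-animal average
exactly equal to the predicted classification's ordinal is `met`, not
`exceeded` (3.1 against a severe prediction of 3 is the canonical
exceedance; 0.9 against mild is `under`).

## Numerical and boundary conventions

* **Boundary membership.** Bands are closed on the right, so a
  temperature rise of exactly 0.2 °C is normal and exactly 1.0 °C is mild.
  The published band tables leave exact boundary values formally
  unassigned (`<0.2` versus `>0.2 to 1`); right-closure matches the prose
  ranges ("0–0.2 °C, i.e., normal") and resolves ties conservatively
  downward.
* **Death.** Death is a criterion in its own right: a dead animal scores 4
  on every criterion at the death timepoint and all later ones, whatever
  was measured. This dominance is enforced in `score_observations()`, not
  left to the data.
* **Removed (withdrawn) animals** are excluded from group denominators
  from withdrawal onward but their rows are retained — scores of animals
  removed after breaching a limit must stay on record.
* **Missing values** for alive animals leave the cell missing and shrink
  that criterion's denominator at that timepoint, with a warning. The
  framework itself never addresses missingness; per-criterion and
  per-animal denominators keep every reported average a true mean of what
  was scored. The identity "per-animal average = mean of criterion
  averages" holds exactly only for complete matrices and is asserted as
  such.
* **Baselines** default to each animal's own pre-treatment value
  (`self_baseline`): what matters is change in the individual, not an
  absolute number. `control_mean` mode instead uses the arithmetic mean of
  a designated control group at the same timepoint — the estimator is a
  package choice; the framework discusses control-group choice but not the
  estimator. Percent criteria require strictly positive baselines.
* **Timepoints** are opaque ordered labels (factor levels if supplied,
  otherwise order of first appearance). No interpolation happens between
  inspections; inspection frequency is an operational matter outside the
  computation.
* Reported numbers are rounded to two decimals in the JSON report, with
  full-precision values kept under `raw`; all comparisons are made at full
  precision.

## Tunable parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| band boundaries | `band_scheme()` | none (scheme-specific) | the scheme *is* the calibration; built-ins: 0.2/1/2/3 °C, 5/10/20/30 % |
| `deviation_kind` | `band_scheme()` | — | absolute for temperature-like criteria, percent for weight-like |
| `direction` | `band_scheme()` | — | one-sided by default in the built-ins; flipping direction is a scheme-configuration decision, not a scoring-time heuristic |
| `baseline_source` | `criterion_scheme()` | `self_baseline` | change in the individual, not an absolute number |
| severity limit / predicted classification | `scheme_set()` | per group | licence-level inputs |
| `cumulative_mode` | `assess_study()` | `max` | regulatory actual-severity convention; `sum` additionally reports a cumulative-load index |
| reuse `policy_threshold` | `reuse_eligibility()` | `moderate` | see below |

Two genuinely open points are resolved as explicit configuration rather
than hard-coded guesses:

* **Reuse threshold.** The framework's own wording on reuse ("no animal
  may be reused if it has experienced suffering of mild or moderate
  severity") contradicts the usual reading of Directive 2010/63/EU
  Art. 16.1(a), under which reuse is permitted when prior actual severity
  was *at most* moderate. The threshold is therefore a parameter, defaulting
  to the Directive reading (`moderate` ⇒ eligible).
* **Cumulative severity** across phases is stated without an aggregation
  rule. Both readings are exposed: `max` (default; the project's actual
  severity is its worst phase) and `sum` (adds the arithmetic total of
  phase per-animal averages as a cumulative-load index). The per-phase
  breakdown is always reported, and phase classifications are derived by
  ceiling the phase's worst per-animal average onto the category scale.

One known tension is left to the user: rodent body weight can vary by up
to 10 % with time of day, yet the built-in weight scheme's normal band is
0–5 %. Schemes are user-configurable precisely because such calibrations
are species- and husbandry-specific; scoring at the same time of day each
day is the operational mitigation.

## The synthetic cohort generator

`generate_cohort()` draws, per animal and criterion, a severity band from
a five-element probability vector, places a deviation inside the drawn
band, and back-transforms it to a raw measurement around a fixed round
baseline (38 units for absolute schemes, 200 for percent). Placement is
`midpoint` by default — band centres make the scored bands invariant to
any boundary-membership convention — while `uniform` draws stress-test
boundary handling. The unbounded top band uses $1.5\,b_3$ as its midpoint
surrogate and $(b_3, 2 b_3]$ for uniform draws: finite, documented,
reproducible. Generation is deterministic given the spec's seed.

What the generator emulates is exactly the band-occupancy structure of a
scoring matrix at one timepoint: independent draws per animal and
criterion. It does **not** emulate longitudinal disease trajectories,
correlation between criteria (real temperature and weight responses are
correlated), inter-animal heterogeneity in baselines, or measurement
noise straddling band boundaries. Passing tests therefore demonstrate the
arithmetic and its invariants, not that any particular animal model is
well described by independent categorical draws.

The built-in worked example, `rat_toxicity_example()`, is a synthetic
reconstruction: the published example prints band assignments, not raw
measurements, so the fixture places measurements at band midpoints such
that scoring reproduces the published matrices cell for cell (low dose:
temperature 0,1,0,1,1 and weight 1,1,1,2,1; high dose: temperature
3,3,4,2,3 and weight 3,4,4,2,3). The high-dose animal in the top
temperature band is represented as a live animal with an extreme
measurement — the published table marks it in a measurement column; the
death override is exercised separately on generated data.

## Problem sizes used in the tests

The test suite runs at desk scale: the ten-animal worked example, 10,000
random deviations against a brute-force interval-scan oracle, fifty
random score matrices for the algebraic identity (tolerance $10^{-12}$), a
1000-animal cohort for the analytic-mean check, and twenty 250-animal
cohorts for the chi-square band-frequency recovery check (α = 0.01,
at most one rejection across the twenty seeds). The whole suite completes
in well under a minute on one CPU.

## Known limitations

* Five fixed bands; no sub-division of the beyond-severe band, whose
  lower bound is the only thing the framework specifies.
* Descriptive arithmetic only — no inferential statistics between dose
  groups, no confidence intervals.
* No statistical sign-selection; criteria are user-chosen.
* No acute/hyperacute behavioural scoring, and no ingestion of
  physiological assays beyond generic numeric criteria.
* Recommended actions (`alert_licence_holder`, `withdraw_or_treat`,
  `humane_kill_candidate`) are advisory labels for score-sheet pipelines;
  the package never removes a breaching animal's data.
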