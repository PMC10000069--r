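# sevband

Banded severity scoring for laboratory-animal welfare assessment.

Animal-research legislation (e.g. Directive 2010/63/EU) requires
scientists to predict the severity of a procedure, to act when an
individual animal crosses its severity limit (humane endpoints,
intervention points), and to report the severity that actually occurred.
`sevband` implements an objective scoring framework for subacute and
chronic experiments built on one assumption: the degree to which
measurable criteria (body temperature, body weight, ...) deviate from an
animal's normal baseline reflects the impact of the experiment on that
animal.

For each criterion, the non-negative deviation from baseline
$d$ is assigned to one of five right-closed bands
$[0,b_0], (b_0,b_1], (b_1,b_2], (b_2,b_3], (b_3,\infty)$ scored
$s \in \{0,1,2,3,4\}$ — normal, mild, moderate, severe, beyond severe or
death. For a group of $N$ animals scored on $K$ criteria with group
criterion averages $\bar s_1,\dots,\bar s_K$:

- overall impact score $= N \cdot \frac{1}{K}\sum_c \bar s_c$
- per-animal average impact $=$ overall $/\,N$
- individual animal score $=$ mean of that animal's criterion scores

An animal **breaches** its severity limit when its individual score
strictly exceeds the limit's ordinal; a group's severity classification is
**exceeded** when its (worst-case) per-animal average strictly exceeds the
predicted category's ordinal. Multi-phase projects get per-phase results,
cumulative severity (max or sum mode) and reuse-eligibility checks.

It is a package for the people who run and oversee in-vivo studies:
named veterinary surgeons, animal-care staff maintaining clinical score
sheets, and licence holders writing retrospective severity returns.

## Worked example

The built-in fixture is a hypothetical rat toxicity study: two dose
groups of five rats, scored at one timepoint on temperature rise
(bands 0.2/1/2/3 °C above baseline) and body-weight loss
(bands 5/10/20/30 %). The low-dose group carries a mild severity limit
and classification, the high-dose group a severe one.

```r
library(sevband)

fx <- rat_toxicity_example()
scores <- score_observations(fx$observations, fx$baselines, fx$scheme)
group_criterion_average(scores)
#> # A tibble: 4 × 6
#>   group_id  timepoint criterion   total_score n_animals average
#>   <chr>     <ord>     <chr>             <int>     <int>   <dbl>
#> 1 high_dose day7      body_weight          16         5     3.2
#> 2 high_dose day7      temperature          15         5     3
#> 3 low_dose  day7      body_weight           6         5     1.2
#> 4 low_dose  day7      temperature           3         5     0.6

assess_study(fx$observations, fx$baselines, fx$scheme)
#> <severity_assessment>
#>   10 animals, 2 criteria, 1 timepoint(s), 2 group(s)
#>   classification verdicts:
#>     high_dose: per-animal average 3.10 vs predicted severe -> exceeded
#>     low_dose: per-animal average 0.90 vs predicted mild -> under
#>   severity-limit breaches: 3 animal-timepoint(s)
```

Reading the output: the low-dose group's criterion averages (0.6 and 1.2)
combine to an overall impact score of 5 × (0.6 + 1.2)/2 = 4.5 and a
per-animal average of 0.9 — below the mild prediction of 1, so the
suffering was less than predicted. The high-dose averages (3.0 and 3.2)
give 15.5 overall and 3.1 per animal — above the severe prediction of 3,
so the classification was exceeded, and the animals whose individual
scores exceed the severe limit (one of them at 4, 4 across both criteria)
are flagged `humane_kill_candidate` / `withdraw_or_treat` on the verdict
sheet while their scores remain on record.

`tidy()` on the assessment returns the per-animal verdict table,
`glance()` the one-row-per-group summary, and `autoplot()` severity
trajectories against the predicted classifications.

## Files and command line

Observations are long CSV
(`study_id,phase_id,group_id,animal_id,timepoint,criterion,value,status`),
baselines `animal_id,criterion,baseline_value`, schemes YAML or JSON
(`read_scheme()` / `write_scheme()`). `run_assessment()` writes a JSON
report plus a flat verdict CSV. A thin CLI wraps the same functions:

```sh
Rscript inst/cli/sevband.R fixture --out demo
Rscript inst/cli/sevband.R assess --scheme demo/scheme.yaml \
    --observations demo/observations.csv --baselines demo/baselines.csv \
    --out demo/report.json
# exit code 0 = no breach, 2 = severity limit breached, 1 = error
```

`simulate` generates synthetic cohorts with chosen band-occupancy
probabilities (see `generate_cohort()`).

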