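# weartime

Wear-time-aware analysis of minute-level consumer-wearable data.

Fitbit-class devices report heart rate and step counts once per minute —
but only while worn, and participants in longitudinal studies wear them
less and less as a study goes on. Estimates built by naively averaging days
(average daily step count, above all) therefore confound behaviour with
device wear. `weartime` is for researchers analysing such cohorts: it makes
wear time an explicit, first-class quantity and quantifies how much the
choice of a "valid day" definition moves the answers.

## What it computes

**Wear time.** The device registers a heart rate every minute it is worn, so

```
wear fraction = (# minutes with a registered heart rate) / (total minutes)
```

with a 24-hour day contributing exactly 1440 minutes.

**Valid-day rules.** Three standard definitions are compared (and custom
ones can be built): `none` (every day valid), `stepcount1000` (registered
steps > 1000), `weartime80` (wear time > 80% of the day, i.e. > 19.2 h).
Per-subject and per-group averages of daily step count and daily heart rate
are computed under each rule, individual differences between rules are
binned on the scale of the standard daily-step activity categories
(sedentary < 5000 steps/day, low active 5000–7500, somewhat active
7500–10,000, highly active ≥ 10,000), and subjects whose activity category
itself changes between rules are flagged.

**Walking heart rate.** Minutes with ≥ 80 steps are walking minutes; their
heart rates are the walking-heart-rate samples. The minimum number of
samples for a confident estimate is found by random subsampling: the mean
standard error `s/√n` must fall below 1 bpm and stay there (a sustained
crossing). Each subject is labelled by which research questions its data can
answer: `both`, `steps_only`, `walking_only`, `neither` — low-compliance
subjects are often `walking_only`, i.e. useless for daily step counts yet
perfectly usable for walking heart rate.

**Compliance comparison and abandonment.** Per-subject wear is compared
across groups with a Kruskal–Wallis omnibus plus Dunn pairwise post hoc
(tie-corrected, Holm-adjusted), and monthly (30-day-block) wear trends
quantify device abandonment.

**Synthetic cohorts.** A minute-level generator with diurnal wear profiles,
geometric monthly abandonment, walking bouts, a resting + elevation + noise
heart-rate model, optional wear–activity coupling, and per-subject ground
truth makes the whole pipeline testable end to end; `study_group_configs()`
bundles six group profiles spanning study-average wear from ≈ 20.8 h/day
down to ≈ 9.8 h/day.

## Worked example

```r
library(weartime)

configs <- study_group_configs(n_subjects = 6)   # six groups, scaled down
sim <- generate_cohort(configs, master_seed = 1)

summaries <- summarize_days(sim$cohort)
population_estimates(summaries, default_rules(c("none", "weartime80")))
```

```
                group       rule n_retained mean_avg_daily_steps mean_avg_daily_hr
       hct_caregivers       none          6                 7138             68.59
       hct_caregivers weartime80          6                 7771             68.53
     ped_onc_patients       none          6                 4243             64.46
     ped_onc_patients weartime80          4                 6903             64.71
             students       none          6                 4458             64.20
             students weartime80          5                 8427             64.27
...
```

Reading this: in the highly compliant caregiver group the two definitions
differ by ~600 steps/day, while in the low-compliance pediatric-oncology and
student groups ignoring wear time (`none`) under-counts daily steps by
2,700–4,000 — and the stricter rule also loses subjects (retention 6 → 4).
Mean daily heart rate barely moves (< 0.3 bpm): it is robust to wear time.

```r
wh <- walking_hr_analysis(sim$cohort, summaries, seed = 1)
table(wh$feasibility)
#>         both   steps_only walking_only      neither
#>           33            0            2            1

wear_group_comparison(summaries)$omnibus
#>        H df      p_value  n
#> 25.43544  5 0.0001147883 36
```

Two subjects have no valid day under the 80%-wear rule yet enough walking
minutes for a converged walking-heart-rate estimate (`walking_only`); group
wear differs significantly (Kruskal–Wallis H = 25.4, p = 1.1e-4; Dunn
pairwise comparisons follow via `$pairwise`).

A thin command-line front end over the same functions lives at
`inst/cli/weartime.R` (subcommands `simulate`, `summarize`, `sensitivity`,
`walking-hr`, `compare`, `all`), and `run_pipeline()` writes every product
as CSV with a manifest of parameters, seed, and output checksums.

## Package layout

- `R/cohort.R`, `R/io.R` — cohort container; minute-record and day-summary
  CSV dialects
- `R/core.R`, `R/rules.R` — wear fraction, day summaries, valid-day rules,
  subject estimates, monthly trend
- `R/sensitivity.R` — population/individual rule sensitivity, difference
  bins, activity-level misclassification
- `R/walking.R` — cadence extraction, SE convergence, days-to-reach,
  feasibility
- `R/group-stats.R` — Kruskal–Wallis wrapper and Dunn post hoc
- `R/simulate.R` — synthetic cohort generator and recovery scoring
- `R/pipeline.R` — end-to-end runner with manifest
- `vignettes/weartime-methods.Rmd` — model, assumptions, parameter
  defaults, design choices, limitations
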