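# temporg

Temporal organization analysis of free recall.

When people freely recall a story or a word list, they tend to recall items
studied close together in time in succession, and mostly in the forward
direction — the *temporal contiguity effect*. `temporg` measures this
organization from recall-order data and compares it across groups and
timepoints, targeting clinical designs such as adults with moderate-severe
traumatic brain injury (TBI) versus non-injured comparison (NC)
participants, tested repeatedly on narrative retelling and wordlist
(AVLT-style) recall.

## What it computes

For each cleaned recall sequence (intrusions dropped, repetitions ignored):

* **Percentile-rank temporal organization score.** Each transition between
  successively recalled items compares the distance actually traversed with
  the distances to every item not yet recalled: distances are
  reverse-ranked (ties share the mean rank) and the transition scores
  (R − 1)/(N − 1). The sequence score is the mean over transitions:
  1.0 = perfect temporal clustering, 0.5 = chance.
* **Lag-CRP.** For each signed lag in −5..+5, the number of times that lag
  transition occurred divided by the number of times it was possible, given
  list length and prior recalls.
* **Inference.** One-sample t tests against the 0.5 chance level; logistic
  recall-accuracy and linear score models (`~ group * timepoint`, optional
  grand-mean-centered percent-recall covariate) with participant-cluster
  bootstrap standard errors; reverse dummy coding to probe interactions;
  and a two-part **zero-inflated beta regression** for CRP magnitudes
  (logistic part for P(y = 0); Beta(μφ, (1−μ)φ) part for positive values,
  with |lag| and direction (±0.5) covariates; values of exactly 1 adjusted
  to 0.999).
* **Synthetic cohorts.** `simulate_cohort()` generates datasets with the
  full study structure from an exponential-in-|lag| transition kernel
  (clustering temperature `tau`, forward bias `phi_fwd`, per-item recall
  probability `p_recall`), so the entire pipeline runs and is testable
  without any participant data.

## Worked example

```r
library(temporg)
s10 <- study_list("story", 10)
round(temporal_organization_score(c(2, 1, 4), s10), 2)
#> [1] 0.9
round(temporal_organization_score(c(1, 5, 9), s10), 2)
#> [1] 0.38
```

Both recalls contain three items, but the first makes short jumps (lags
−1, +3) and clusters tightly (0.90), while the second recalls in order yet
jumps far (+4, +4) and scores near chance (0.38).

A full synthetic analysis:

```r
cfg <- simulation_config(n_per_group = 20, seed = 17)
report <- run_full_analysis(simulate_cohort(cfg), B = 200, seed = 17)
report$models$score_narrative
#> <model_fit> linear model: score ~ group * timepoint
#>   n = 471, logLik = 319.68043, cluster bootstrap B = 200
#>
#>                            term  estimate       se statistic         p ...
#> 1                   (Intercept)  0.869461 0.007158  121.4594 0.000e+00
#> 2                      groupTBI -0.064626 0.018209   -3.5492 3.864e-04
#> 3          timepointShort Delay -0.011564 0.011776   -0.9820 3.261e-01
#> 4           timepointLong Delay -0.092378 0.012740   -7.2510 4.138e-13
#> 5 groupTBI:timepointShort Delay  0.005229 0.026668    0.1961 8.446e-01
#> 6  groupTBI:timepointLong Delay  0.008955 0.025426    0.3522 7.247e-01
```

The intercept is the NC mean score at No Delay (~0.87, far above the 0.5
chance level); the negative `groupTBI` and `timepointLong Delay`
coefficients recover the generator's built-in effects — weaker clustering
with TBI and after a one-week delay — while the 20-minute delay and the
interactions are null, as generated. `report$chance` holds the per-group
and per-timepoint chance tests, `report$pooled_crp` the pooled lag-CRP
curves, and `write_report(report, dir)` writes scores.csv, crp.csv,
crp_pooled.csv, fits.csv and manifest.yaml deterministically.

A thin command-line wrapper with `simulate | score | crp | fit | report`
subcommands is installed at `inst/cli/temporg.R`.

See the vignette (`vignettes/temporal-organization.Rmd`) for the model
details, generator assumptions, and numerical choices.

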