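# adheretraj

Longitudinal medication-adherence analysis for administrative
pharmacy-claims data, built around the use case of biologic therapy in
inflammatory bowel disease (IBD). The package takes raw claims tables —
patient registry, dispensings, diagnosis/exemption events — through a
complete, reproducible pipeline:

1. **New-user cohort construction** with an explicit attrition cascade
   (index-date definition, washout, look-back, follow-up coverage,
   indication), producing a per-step attrition table.
2. **Monthly proportion of days covered (PDC)**: each dispensing of *q*
   DDDs covers `round(q)` days at one defined daily dose per day;
   overlapping coverage counts once; PDC in index-anchored monthly windows
   (28–31 days) is covered days / window length, giving every patient a
   T-month adherence series.
3. **Trajectory clustering** by the nonparametric three-stage procedure:
   24 longitudinal change measures per series, principal-component
   selection of a non-redundant measure subset, and k-means on the
   standardized selected measures with the number of clusters chosen by a
   majority vote of ten cluster-validity indices.
4. **Determinants of adherence**: a multinomial logistic model of cluster
   membership (high-adherence reference) fitted by Newton–Raphson with
   Wald 95% intervals, and optional bidirectional stepwise-AIC covariate
   selection.
5. **Follow-up descriptives**: biologic switching (different substance, or
   originator↔biosimilar) and per-cluster drug-class use.

Because patient-level claims are rarely shareable, the package includes a
**synthetic claims generator** whose defaults encode a realistic study:
three latent adherence-trajectory classes (19/46/35% mixture; constant
~0.95, decline-to-0.70-plateau, decline-to-0.20 shapes),
covariate-dependent class membership with calibrated intercepts (female OR
1.52, older 1.44, biosimilar 0.47, …), switching, and rule-violating
distractor subjects. Every stage of the pipeline is validated against this
known truth.

## Worked example

```r
library(adheretraj)

cfg    <- sim_config(n_subjects = 2000, seed = 42)
sim    <- simulate_population(cfg)
cohort <- identify_new_users(sim$registry, sim$dispensings, sim$events,
                             cfg$rules)
series <- monthly_pdc(coverage_intervals(sim$dispensings, cohort$cohort, 36),
                      cohort$cohort, 36)
model  <- fit_trajectories(series, seed = 7)

print(sim)
#> Synthetic claims database: 2000 subjects, 72230 dispensings, 4844 events
#> Latent classes: high 18.4%, low 35.0%, medium 46.5%

print(cohort$attrition)
#>                                              step n_entering n_excluded n_retained
#> 1:   eligible biologic dispensing in study window       2000          0       2000
#> 2:                    ustekinumab index-date rule       2000          0       2000
#> 3:              sufficient look-back before index       2000         34       1966
#> 4: no biologic in washout before index (new user)       1966         52       1914
#> 5:            registry coverage through follow-up       1914         32       1882
#> 6:                      IBD indication (CD or UC)       1882         48       1834

print(model)
#> Trajectory model: k = 3 (majority vote: 3)
#> Selected measures: m2, m11
#> Cluster shares:
#>     label     N      pct
#> 1: medium   848 46.23773
#> 2:   high   337 18.37514
#> 3:    low   649 35.38713
```

The attrition table shows each selection rule removing exactly the
subjects the generator planted as violators of that rule; the remaining
1,834 new users are clustered into three trajectories whose shares recover
the generating 19/46/35% mixture. The selected measures here are the mean
adherence level (`m2`) and the largest month-to-month increase (`m11`) — a
level dimension and a refill-irregularity dimension.

One call runs everything (cohort → PDC → trajectories → determinants →
follow-up) and writes all stage outputs, a markdown report, and a JSON run
manifest with file digests:

```r
run <- run_pipeline(cfg, out_dir = "out")
run$effects        # odds-ratio table, medium/low vs high adherence
run$followup$use   # per-cluster drug-class use and switch percentages
```

A thin command-line wrapper is installed at
`inst/scripts/adheretraj-pipeline.R`, and
`inst/extdata/default_config.yaml` documents every configurable default.

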