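# gorassoc

Association networks and their demographic predictors in female gorillas.

Adult female gorillas disperse between social groups repeatedly, so they
mostly live among non-kin — yet their within-group spatial associations are
clearly differentiated. **gorassoc** implements the analysis chain used to
ask what predicts that differentiation: are females with a similar state
(both rearing a young infant, similar dominance rank, similar residency
status) more strongly associated, and do association scores track
demographic events in time? It is written for behavioural ecologists working
with focal-animal scan data, and everything runs equally on field tables or
on the bundled synthetic study generator with known injected effects.

## What it computes

* **Proximity networks** from instantaneous scan samples (females within
  5 m of the focal): per window, focal-scan counts `N_a`, joint counts
  `N_ab`, dyadic strength `N_ab / (N_a + N_b)` and node strength (weighted
  degree). Denominators of a dyad count each member's scans over the pair's
  joint residency, so mid-year immigration or emigration does not
  mechanically deflate the index.
* **Dominance**: Elo ratings per group and sex (start 1000, k = 100,
  bottom entry for newcomers), daily scores averaged per calendar year,
  min–max standardized ranks for females (1 = top, 0 = bottom), dyadic
  average rank, and the yearly alpha male.
* **Demographic covariates**: dependent infant (> 6 months of the year with
  an infant under 12 months), new immigrant (first scored year, mid-year
  joiners shift to the next year), last year in group (emigration next
  year), new alpha male, tenure, female number and weaned-adult group size,
  assembled into individual-year and dyad-year model tables.
* **Hierarchical models** of strength: Student-t linear mixed models
  (glmmTMB) with the design's random-intercept structure, 2-SD-standardized
  continuous predictors, a VIF screen, Wald 95% intervals with a
  meaningful-effect flag, and marginal/conditional R².
* **Time-matched event analysis**: networks rebuilt in 365-day windows
  anchored on second births (offsets −2…+2) and immigrations (0…+4), and
  factor-smooth additive models (mgcv) of strength over event time with a
  dyad random intercept and per-condition smooth "sds".
* **A synthetic study generator** emulating the sampling design (multi-year,
  multi-group, focal rotation, 10-min scans, births, transfers, alpha
  turnover) with configurable injected effects, used by the test suite for
  parameter-recovery and null-calibration checks.

## Worked example

```r
library(gorassoc)

scen  <- scenario_config(seed = 11)      # 3 groups x 8 years, field scale
study <- simulate_study(scen)
elo   <- run_elo(study$agonistic, study$demography,
                 start_date = study_start(scen),
                 end_date   = study_end(scen) - 1)
ranks <- rank_table(elo, study$demography)
nets  <- yearly_networks(study$scans, study$demography)
tabs  <- build_model_tables(nets, ranks, study$demography)
fit   <- fit_hierarchical(tabs$dyad, "dyadic")
fit
```

```
<strength_fit> model: dyadic | backend: student | n = 169
                     term estimate      se   ci_low  ci_high meaningful
              (Intercept)  0.17949 0.01829  0.14364  0.21535          *
             rank_average  0.00757 0.00522 -0.00266  0.01780
  dependent_infant_catone -0.00340 0.00298 -0.00924  0.00243
 dependent_infant_catboth  0.06416 0.01355  0.03761  0.09071          *
         new_immigrantyes -0.04530 0.00439 -0.05391 -0.03669          *
            female_number  0.00381 0.00624 -0.00841  0.01604
               group_size -0.00534 0.00691 -0.01888  0.00821
               group_idG2 -0.09623 0.02029 -0.13600 -0.05646          *
               group_idG3 -0.08700 0.01950 -0.12521 -0.04879          *
R2 marginal = 0.524, conditional = 0.938
dropped constant term(s): new_alpha_male
```

This simulation injects a +1 logit proximity boost when both dyad members
have a dependent infant and a −1 logit penalty when either is a recent
immigrant. The fit recovers both: dyads of two mothers score about 0.064
strength units higher than dyads with no infant, dyads containing a new
immigrant about 0.045 lower, both intervals excluding zero ("meaningful");
the rank-homophily slope is positive but not resolved at this study size.
`new_alpha_male` was constant in this replicate and is dropped rather than
fitted. The same objects feed the event analysis
(`find_events()`, `event_strength_series()`, `compile_event_tables()`,
`fit_event_gam()`) and everything is driven end to end by
`run_pipeline(default_config())`, or from a shell via
`inst/exec/gorassoc <simulate|ranks|networks|covariates|eventwindows|fit|all>`.

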