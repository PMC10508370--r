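# pwlmmtree

Piecewise linear mixed-model trees for longitudinal subgroup discovery.

## What problem this solves

Digital back-pain programs collect weekly self-reports (pain intensity,
perceived posture) and usage logs (training minutes) from thousands of
users.  Two features dominate such data: trajectories are **piecewise**
(steep change over the first weeks, then a plateau), and they are
**heterogeneous** — baseline characteristics such as age, gender and
BMI can define subgroups with meaningfully different courses.  This
package is for methodologists and applied analysts who want to model
the piecewise trajectory with per-user random effects *and* discover
moderator-defined subgroups data-adaptively, without pre-specifying
interactions.

## Model

For user *i* in week *t* with a breakpoint at week *c*, define

```
w_pre(t)  = min(t - 1, c - 1)        # weeks elapsed, capped at the break
w_post(t) = max(t - c, 0)            # weeks past the break
```

Within each terminal node *g* of the tree:

```
y_it = beta0_g + beta1_g * w_pre(t) + beta2_g * w_post(t)
       + b0_i + b1_i * w_pre(t) + e_it
```

with a bivariate normal random intercept/early-slope per user, estimated
**globally** across nodes.  The mean trajectory is continuous at the
break; `beta1` is the weekly change before it, `beta2` after it.
Subgroups are found by model-based recursive partitioning: per-node
score-based parameter instability tests (sup-LM for numeric moderators,
chi-squared for binary factors, Bonferroni-corrected, with scores
aggregated to the user level to respect within-user dependence) select
the split variable, and an exhaustive least-squares scan selects the
split point.  Partitioning alternates with a joint `lme4` fit until the
log-likelihood stabilises.  Training duration is modelled on the log
scale, so a slope `b` back-transforms to a weekly percent change of
`(exp(b) - 1) * 100` — e.g. `percent_change(0.108)` is `11.4`%.

Details, tuning parameters and numerical edge cases are documented in
the methods vignette, `vignettes/piecewise-lmm-trees.Rmd`.

## Worked example

Simulate a cohort of 300 users with a planted age subgroup (users over
45 start higher and improve faster early on), then let the tree find it:

```r
library(pwlmmtree)

cfg <- sim_config(300, outcome_kind = "pain",
  subgroup_rule = subgroup_rule("age", breaks = 45, params = list(
    trajectory_params(5.2, -0.20, 0.00),    # age <= 45
    trajectory_params(5.8, -0.60, 0.00))),  # age  > 45
  seed = 42)
cohort <- simulate_cohort(cfg)

fit <- fit_lmm_tree(cohort$table, partitioning_vars = c("age", "gender", "bmi"))
print(fit)
```

```
Piecewise linear mixed-model tree (breakpoint week 3 )
  terminal nodes: 2  alternations: 2  converged: TRUE
  logLik: -3850.041  AIC: 7720.083

[1] n=2400  split: age <= 44.9 (min adj. p=0.00015)
  age <= 44.9
    [2] n=1336  intercept=5.250 w_pre=-0.153 w_post=-0.013
  age > 44.9
    [3] n=1064  intercept=5.936 w_pre=-0.642 w_post=-0.011
```

The planted threshold (45) is recovered at 44.9, neither gender nor BMI
is split on, and the node coefficients track the planted trajectories
(5.2/−0.20 and 5.8/−0.60).  `node_summary(fit)` tabulates the same
nodes with Wald p-values:

```
  node_id    subgroup n_obs intercept slope_pre    p_pre slope_post p_post
1       2 age <= 44.9  1336      5.25    -0.153 1.68e-03    -0.0126  0.472
2       3  age > 44.9  1064      5.94    -0.642 7.10e-32    -0.0105  0.593
```

## Analysis workflow

`analysis/01_simulate_cohort.R` … `analysis/05_report.R` reproduce a
full study-style analysis (simulate cohorts with planted structure and
demonstrate the inclusion screen; select the breakpoint by AIC against
a single-slope comparator; grow depth-tuned trees for pain, posture and
log training duration; evaluate with user-level train/test splits and
5-fold CV; write interpretable reports).  Run them in order from the
package root; all outputs are plain-text files under `results/`.  On
the shipped seeds the breakpoint-at-week-3 model wins for all three
outcomes, the posture tree splits on gender (early slope 0.30
female vs 0.62 male), and the duration tree recovers the planted age-37
rule at age 38, with the older group ramping up +10.5% per week from
483 minutes in week 1.

## License

MIT (see `LICENSE`).
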