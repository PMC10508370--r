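---
title: "Methods: piecewise linear mixed-model trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: piecewise linear mixed-model trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwlmmtree)
```

# The problem

Digital back-pain programs collect weekly self-reports (pain intensity,
perceived posture) and usage logs (training minutes) from large,
heterogeneous user populations.  Two questions drive the methods in this
package:

1. **Trajectory shape.** Week-by-week change is typically not linear:
   there is a steep early phase followed by a plateau.  A two-segment
   ("piecewise") linear trajectory with a single breakpoint captures
   this with three interpretable fixed effects.
2. **Moderated heterogeneity.** Baseline covariates (age, gender, BMI)
   may define subgroups whose trajectories differ.  Rather than
   pre-specifying interactions, the tree searches for subgroups
   data-adaptively while keeping a per-user random trajectory.

# Model

For user $i$ in week $t \in \{1, \dots, T\}$, with breakpoint at week
$c$, define the basis (`piecewise_design()`)

$$w^{\text{pre}}_t = \min(t - 1,\ c - 1), \qquad
  w^{\text{post}}_t = \max(t - c,\ 0),$$

so the mean trajectory is continuous at the breakpoint by construction,
$\beta_1$ is the weekly change before the break and $\beta_2$ after it.
The mixed model fitted in each terminal node $g$ of the tree is

$$y_{it} = \beta_{0g} + \beta_{1g} w^{\text{pre}}_t
  + \beta_{2g} w^{\text{post}}_t + b_{0i} + b_{1i} w^{\text{pre}}_t
  + \varepsilon_{it},$$

with a bivariate normal random intercept/early-slope per user and
independent Gaussian residuals.  The random effects are **global**: they
are estimated once, jointly across all terminal nodes, not separately
per node.  Training duration is modelled on the log scale, so slopes
back-transform to weekly percent change: $(\exp(\beta) - 1) \cdot 100$.

# Estimation procedure

`fit_lmm_tree()` alternates two steps until the joint log-likelihood
changes by less than `tol`:

1. **Partitioning.** Subtract the current predicted random-effect
   contribution from the outcome and grow a model-based recursive
   partition (`grow_mob()`) of the adjusted outcome on the piecewise
   basis.  In each node, per-user-aggregated scores of the node's OLS
   fit are tested for parameter instability along every moderator; the
   moderator with the smallest Bonferroni-adjusted p-value below `alpha`
   is selected, and the split point is chosen by exhaustive
   residual-sum-of-squares minimization (`find_split()`).
2. **Joint mixed fit.** Refit one `lme4::lmer()` model with
   node-specific fixed effects (`outcome ~ 0 + .node + .node:w_pre +
   .node:w_post`) and the global random effects, then update the
   per-user predictions (BLUPs).

Random-effect covariance parameters are warm-started across iterations.
The same alternation with a trivial one-node "tree" reduces to a single
piecewise LMM, which is how `fit_lmm()`, breakpoint selection and the
depth-0 comparisons stay mutually consistent.

## Instability tests

For a numeric moderator, `instability_test()` uses the supremum-LM
statistic over the ordered cumulative score process, with 10% trimming
at both ends.  p-values come from a simulated limiting distribution
(Brownian bridge on a 1000-point grid, 20,000 replicates), computed once
per process dimension with a fixed internal seed and cached for the
session; this keeps p-values deterministic and independent of the
user's RNG state.  Categorical moderators use the corresponding
$\chi^2$ statistic with $k(C-1)$ degrees of freedom.

**Cluster aggregation is essential.**  Scores are summed within user
before testing.  The moderators are user-level constants and the
repeated measures are dependent within user even after subtracting
BLUPs; testing row-level scores treats each week as independent and is
grossly anticonservative (in null simulations it split almost every
cohort).  With user-level aggregation the empirical size of the test is
close to the nominal 5% and null cohorts almost always stay at the root.

## Split search

`find_split()` scans every boundary between distinct sorted moderator
values using cumulative sufficient statistics (prefix sums of
$x x^\top$, $x y$, $y^2$), so the scan is $O(n)$ after sorting rather
than $O(n^2)$.  Singular candidate fits fall back to a pivoted
least-squares solve.  Ties in the objective are resolved toward the
smaller threshold, using a strict-improvement rule with relative
tolerance $10^{-10}$ so floating-point noise cannot flip the choice.
Both children must contain at least `minsplit` rows.  Categorical split
variables must be binary; multi-level factors are rejected with an
informative error rather than silently searching $2^{C-1}$ partitions.

# Tunable parameters

All tree settings live in `tree_control()`:

| parameter | default | rationale |
|---|---|---|
| `alpha` | 0.05 | conventional test level for the instability pre-test |
| `bonferroni` | `TRUE` | corrects for testing several moderators per node |
| `minsplit` | 90 | minimum rows per child; with 8 weekly rows per user this is roughly 11 users, small enough to find minority subgroups but large enough for a stable node model |
| `maxdepth` | 5 | depth cap; in practice selected from a small grid by AIC (`tune_maxdepth()`) |
| `max_iter`, `tol` | 100, 1e-4 | alternation stops on log-likelihood change; 2–4 iterations are typical |
| `trim` | 0.1 | standard trimming fraction for the sup-LM statistic |
| `method` | `"ml"` | maximum likelihood so that AICs are comparable across fixed-effect structures; REML available for variance reporting |

`minsplit` counts **rows**, not users, because node sizes are naturally
expressed in observations and users contribute unequal row counts after
missingness; the default is stated in row units accordingly.

The breakpoint week is a modelling choice, selected by AIC among
candidate values plus a single-slope comparator
(`compare_breakpoints()`).  The comparator uses the same random-effect
structure (random slope on centred week) so the comparison isolates the
mean structure.  AIC counts parameters explicitly: fixed effects plus
two random-effect standard deviations, their correlation, and the
residual standard deviation.

# Synthetic cohorts

`simulate_cohort()` emulates the *included* study sample of a digital
back-pain program: user-level age (truncated normal, location
calibrated by root-finding so the post-truncation mean equals the
configured mean), gender, BMI, then weekly outcomes from the piecewise
model above with planted subgroup rules (`subgroup_rule()`), per-user
random effects, optional bounded-scale clipping, and optional
non-reporting.  `apply_inclusion_filter()` reproduces a typical
screening rule (first pain rating above 4, at least two ratings,
over 360 training minutes in each of the first eight weeks).

What the generator deliberately does **not** emulate: within-week
measurement structure (one row per user-week), informative dropout
(non-reporting is completely at random), time-varying covariates, and
floor/ceiling measurement effects beyond optional clipping.  Screening
on the outcome (first pain > 4) is a selection effect in its own right;
analyses of an included cohort should be read as conditional on
inclusion, which is why the demonstration workflow simulates the
included cohort directly rather than screening a raw cohort that
already has the target structure planted.

# Numerical choices and edge cases

- **Non-convergence.** `fit_lmm()` suppresses lme4's singular-fit
  checks (boundary fits are legitimate here), and retries with the
  Nelder–Mead optimizer when the default optimizer fails to converge.
- **Degenerate noiseless data.** If the outcome is an exact linear
  function of the design, the model is fit by OLS with zero variance
  components (log-likelihood `Inf`, AIC `-Inf`), keeping comparisons
  well-defined instead of crashing inside the optimizer.
- **Collinear designs** raise an error naming the collinear columns;
  fewer than two users raises a degenerate-grouping error.
- **Prediction for unseen users** uses fixed effects only (BLUP 0, the
  random-effect mean) — this is the honest out-of-sample prediction and
  is what `evaluate_tree()` reports as test RMSE, while training RMSE
  includes each training user's BLUP.
- **Untestable moderators** (fewer than two distinct values in a node)
  get p-value 1 rather than an error, so partitioning simply stops.
- **Serialization** (`tree_to_json()`, `lmm_to_json()`) stores numbers
  at full precision in plain JSON; restored trees support prediction
  and reporting.

Quantiles in `descriptive_table()` use the R default (type 7), and the
gender comparison uses a two-sided Wilcoxon rank-sum test, matching
common epidemiological reporting.

# Evaluation

Splitting is always **by user** (`split_by_user()`, `kfold_by_user()`):
rows of one user never appear on both sides, otherwise within-user
correlation leaks and test RMSE is optimistically biased.
`evaluate_tree()` wraps the standard protocol: refit on training users,
report training RMSE (with BLUPs), k-fold cross-validated RMSE, and
held-out test RMSE (fixed effects only).

# Repository shape

The package is organised as a reusable library (`R/`) plus a numbered
analysis workflow (`analysis/01_…` to `analysis/05_…`) that reproduces
a full study-style analysis — simulate, select breakpoint, grow trees,
evaluate, report — writing plain-text artifacts to `results/`.  The
scripts are the command-line interface: each is a small, runnable
`Rscript` that composes the exported functions.

# Known limitations

- Terminal-node p-values are naive Wald tests from the final joint fit;
  they do not account for the tree search that produced the nodes.
  Treat them as descriptive.
- The alternation is monitored by log-likelihood change only; parameter
  trajectories are not checked for cycling (none was observed up to
  `max_iter`).
- The sup-LM null is asymptotic in the number of users per node; in
  very small nodes the test can be conservative.
- Splits on categorical moderators are restricted to binary factors.
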