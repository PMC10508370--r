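#!/usr/bin/env Rscript
# Step 5 — interpretable summaries.
#
# Node summaries (subgroup rules, piecewise coefficients, Wald p-values),
# back-transformation of the log-duration model to minutes and weekly
# percent change, and caterpillar-plot data with 95% intervals.

suppressPackageStartupMessages(library(pwlmmtree))

users <- read_cohort("results/users.csv")
for (oc in c("pain", "posture", "log_duration")) {
  fit <- tree_from_json(file.path("results", paste0("tree_", oc, ".json")))
  fit$outcome <- oc  # node_summary back-transforms log_duration
  write_report(fit, file.path("results", paste0("report_", oc, ".md")),
               profiles = if (oc == "pain") users else NULL)
  ns <- node_summary(fit)
  message("== ", oc, " ==")
  print(ns, digits = 3)
  if (oc == "log_duration") {
    message(sprintf(
      "e.g. node %d: week-1 level %.1f minutes, %+.1f%%/week in weeks 1-3",
      ns$node_id[nrow(ns)], ns$level_week1[nrow(ns)],
      ns$pct_change_pre[nrow(ns)]))
  }
}
message("Reports -> results/report_*.md (+ CSV side files)")
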