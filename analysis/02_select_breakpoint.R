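#!/usr/bin/env Rscript
# Step 2 — pick the trajectory shape by AIC.
#
# For each outcome, fit piecewise mixed models with the break at week 3
# and at week 4, plus the single-slope comparator, all by ML with the
# random intercept + first-segment random slope, and keep the AIC winner.

suppressPackageStartupMessages(library(pwlmmtree))

outcomes <- c(pain = "cohort_pain.csv", posture = "cohort_post.csv",
              log_duration = "cohort_dur.csv")
rows <- list()
for (oc in names(outcomes)) {
  tab <- read_cohort(file.path("results", outcomes[[oc]]))
  cb <- compare_breakpoints(tab, candidate_breakpoints = c(3, 4),
                            include_linear = TRUE)
  message(sprintf("%s: winner = %s", oc, cb$winner))
  at <- cb$aic_table
  at$outcome <- oc
  at$winner <- at$model == cb$winner
  rows[[oc]] <- at
}
aic_tab <- do.call(rbind, rows)
utils::write.csv(aic_tab, "results/breakpoint_aic.csv", row.names = FALSE)
message("AIC comparison table -> results/breakpoint_aic.csv")
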