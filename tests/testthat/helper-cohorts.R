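# cohort builders shared across tests; all randomness is seeded through
# sim_config so suites are deterministic

null_pain_config <- function(seed, n_users = 200) {
  sim_config(n_users = n_users, outcome_kind = "pain", seed = seed)
}

# planted age-40 split: slope_pre differs by 1.0 against residual sd 0.2
# (five residual SDs), the well-separated regime
split40_config <- function(seed, n_users = 500) {
  rule <- subgroup_rule("age", breaks = 40, params = list(
    trajectory_params(5.5, -0.5, 0.02),
    trajectory_params(5.5, 0.5, 0.02)
  ))
  sim_config(n_users = n_users, outcome_kind = "pain",
             subgroup_rule = rule,
             variance = variance_components(1.5, 0.25, 0, 0.2),
             seed = seed)
}

# mean structure with a genuine kink at week 3, moderate noise
break3_config <- function(seed, n_users = 300) {
  sim_config(n_users = n_users, outcome_kind = "pain", seed = seed)
}

# straight-line mean with a random intercept only: no feature of the
# data-generating process distinguishes the weeks around any breakpoint
linear_config <- function(seed, n_users = 300) {
  sim_config(n_users = n_users, outcome_kind = "pain",
             params = trajectory_params(5.5, -0.2, -0.2),
             variance = variance_components(1.5, 0, 0, 1.0),
             seed = seed)
}

# noiseless single-subgroup cohort: outcome an exact function of the basis
noiseless_config <- function(seed, n_users = 30,
                             params = trajectory_params(5, -0.4, 0.1)) {
  sim_config(n_users = n_users, outcome_kind = "pain", params = params,
             variance = variance_components(0, 0, 0, 0), seed = seed)
}

# permutation reference for the instability tests: the distribution of the
# same statistic under random reshuffling of the moderator
perm_pvalue <- function(scores, z, trim = 0.1, B = 199, seed = 1) {
  obs <- instability_test(scores, z, trim = trim)$statistic
  perm <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      instability_test(scores, sample(z), trim = trim)$statistic
    }, numeric(1))
  })
  (1 + sum(perm >= obs)) / (1 + B)
}

# brute-force split search: refit both children with lm() for every
# candidate threshold, no sufficient-statistic shortcuts
brute_force_split <- function(table, variable, minsplit,
                              outcome = "outcome") {
  z <- table[[variable]]
  uz <- sort(unique(z))
  best <- list(objective = Inf, split_point = NA_real_)
  for (i in seq_len(length(uz) - 1)) {
    thr <- (uz[i] + uz[i + 1]) / 2
    left <- z <= thr
    if (sum(left) < minsplit || sum(!left) < minsplit) next
    rssfun <- function(d) {
      sum(stats::resid(stats::lm(stats::reformulate(c("w_pre", "w_post"),
                                                    outcome), data = d))^2)
    }
    obj <- rssfun(table[left, ]) + rssfun(table[!left, ])
    if (obj < best$objective) best <- list(objective = obj, split_point = thr)
  }
  best
}
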