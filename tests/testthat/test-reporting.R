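test_that("percent change matches the published worked example", {
  expect_equal(round(percent_change(0.108), 1), 11.4)
  expect_equal(percent_change(0), 0)
  expect_equal(percent_change(log(2)), 100)
  expect_error(percent_change(Inf), "domain error")
  # strictly increasing in b
  b <- seq(-1, 1, by = 0.05)
  expect_true(all(diff(percent_change(b)) > 0))
})

test_that("intercept back-transformation is exp and round-trips", {
  expect_equal(backtransform_intercept(0), 1)
  expect_equal(backtransform_intercept(log(462.2)), 462.2)
  expect_equal(round(backtransform_intercept(6.152), 1),
               round(exp(6.152), 1))
  grid <- 10^seq(-4, 4, length.out = 25)
  expect_equal(backtransform_intercept(log(grid)), grid, tolerance = 1e-10)
  expect_error(backtransform_intercept(NaN), "domain error")
})

test_that("caterpillar intervals are normal Wald intervals", {
  ch <- simulate_cohort(split40_config(1, n_users = 200))
  tr <- fit_lmm_tree(ch$table, control = tree_control(minsplit = 50,
                                                      maxdepth = 2))
  cd <- caterpillar_data(tr, level = 0.95)
  expect_equal(nrow(cd), 3 * length(tr$leaf_ids))
  z <- qnorm(0.975)
  leaves <- pwlmmtree:::collect_leaves(tr$tree)
  l1 <- leaves[[1]]
  row <- cd[cd$node_id == l1$node_id & cd$parameter == "w_pre", ]
  expect_equal(row$lower, l1$coefficients["w_pre"] - z * l1$se["w_pre"],
               ignore_attr = TRUE)
  # width scales linearly with se and collapses at se = 0
  expect_equal(row$upper - row$lower, 2 * z * l1$se[["w_pre"]])
  expect_equal(qnorm(0.975) * 0.5, (1.98 - 0.02) / 2, tolerance = 0.01)
})

test_that("node summaries describe subgroups and back-transform log slopes", {
  rule <- subgroup_rule("age", breaks = 37, params = list(
    trajectory_params(log(420), 0.02, -0.14),
    trajectory_params(log(470), 0.108, -0.11)))
  cfg <- sim_config(n_users = 300, outcome_kind = "log_duration",
                    subgroup_rule = rule,
                    variance = variance_components(0.5, 0.05, 0, 0.3),
                    seed = 2)
  tr <- fit_lmm_tree(simulate_cohort(cfg)$table, outcome = "outcome",
                     control = tree_control(minsplit = 80, maxdepth = 2))
  ns <- node_summary(tr, log_scale = TRUE)
  expect_equal(nrow(ns), length(tr$leaf_ids))
  expect_true(all(c("subgroup", "level_week1", "pct_change_pre") %in%
                    names(ns)))
  expect_equal(ns$level_week1, exp(ns$intercept))
  expect_equal(ns$pct_change_pre, (exp(ns$slope_pre) - 1) * 100)
})

test_that("descriptive tables use type-7 quantiles and the Wilcoxon test", {
  # quantile convention check on {1,2,3,4}
  profs <- data.frame(
    user_id = sprintf("u%d", 1:8),
    age = c(1, 2, 3, 4, 1, 2, 3, 4),
    gender = factor(rep(c("female", "male"), each = 4),
                    levels = c("female", "male")),
    bmi = c(1, 2, 3, 4, 4, 5, 6, 7))
  tab <- descriptive_table(profs, variables = c("age", "bmi"))
  fem_age <- tab[tab$variable == "age" & tab$group == "female", ]
  expect_equal(fem_age$median, 2.5)
  expect_equal(fem_age$q1, 1.75)
  expect_equal(fem_age$q3, 3.25)
  # identical distributions: two-sided p = 1
  p_age <- tab[tab$variable == "age" & tab$group == "overall", "p_value"]
  expect_equal(p_age, 1)

  # exact enumeration: {1,2,3} vs {4,5,6} has the smallest attainable
  # two-sided p with 3 + 3 observations, 2 * 1/choose(6,3) = 0.1
  profs2 <- data.frame(user_id = sprintf("u%d", 1:6),
                       age = c(1, 2, 3, 4, 5, 6),
                       gender = factor(rep(c("female", "male"), each = 3),
                                       levels = c("female", "male")),
                       bmi = 20)
  tab2 <- descriptive_table(profs2, variables = "age")
  expect_equal(tab2[tab2$group == "overall", "p_value"], 0.1)

  # empty group: summaries emitted, test skipped
  profs3 <- profs[profs$gender == "female", ]
  tab3 <- descriptive_table(profs3, variables = "age")
  expect_true(any(tab3$note != ""))
  expect_true(is.na(tab3[tab3$group == "overall", "p_value"]))
})

test_that("reports are written with node and caterpillar side files", {
  ch <- simulate_cohort(split40_config(3, n_users = 150))
  tr <- fit_lmm_tree(ch$table, control = tree_control(minsplit = 50,
                                                      maxdepth = 2))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "report.md")
  write_report(tr, path, profiles = simulate_cohort(split40_config(3, 150))$users)
  expect_true(file.exists(path))
  expect_true(file.exists(file.path(dir, "report_nodes.csv")))
  expect_true(file.exists(file.path(dir, "report_caterpillar.csv")))
  expect_true(file.exists(file.path(dir, "report_descriptives.csv")))
})
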