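test_that("degenerate configs are rejected and seeds are reproducible", {
  expect_error(sim_config(n_users = 0), "invalid-config")
  expect_error(sim_config(n_users = 10, weeks = 8, breakpoint_week = 8),
               "invalid-config")
  cfg <- sim_config(n_users = 1000, seed = 7)
  expect_identical(simulate_cohort(cfg)$table, simulate_cohort(cfg)$table)
  expect_identical(generate_users(cfg), generate_users(cfg))
})

test_that("moderator marginals match the configured distributions", {
  cfg <- sim_config(n_users = 5000, seed = 11)
  users <- generate_users(cfg)
  # CLT bound: 3 * SD / sqrt(n) on the truncated-normal mean
  expect_lt(abs(mean(users$age) - 43.8), 3 * 15.8 / sqrt(5000))
  expect_lt(abs(mean(users$bmi) - 24.5), 3 * 5.0 / sqrt(5000))
  expect_lt(abs(mean(users$gender == "female") - 0.60),
            3 * 0.5 / sqrt(5000))
  expect_true(all(users$age >= 15 & users$age <= 94))
  expect_true(all(users$bmi > 0))
  expect_false(anyDuplicated(users$user_id) > 0)
})

test_that("the degenerate generator reproduces the planted mean exactly", {
  ch <- simulate_cohort(noiseless_config(1, params = trajectory_params(5, 0, 0)))
  expect_true(all(ch$table$outcome == 5))

  ch2 <- simulate_cohort(noiseless_config(2,
    params = trajectory_params(5, -0.4, 0.1)))
  w1 <- ch2$table$outcome[ch2$table$week == 1]
  w3 <- ch2$table$outcome[ch2$table$week == 3]
  expect_equal(w3 - w1, rep(-0.8, length(w1)))
})

test_that("week-1 variance equals the planted closed form", {
  cfg <- sim_config(n_users = 2000, outcome_kind = "pain",
                    variance = variance_components(1, 0.3, 0, 0.5),
                    seed = 5)
  tab <- simulate_cohort(cfg)$table
  v <- var(tab$outcome[tab$week == 1])
  expect_lt(abs(v - 1.25) / 1.25, 0.10)  # var(u0) + var(eps) = 1 + 0.25
})

test_that("weekly means track the planted piecewise mean function", {
  cfg <- sim_config(n_users = 2000, outcome_kind = "pain",
                    params = trajectory_params(6, -0.5, 0.1), seed = 9)
  tab <- simulate_cohort(cfg)$table
  mu_hat <- tapply(tab$outcome, tab$week, mean)
  b <- piecewise_design(1:8, 3)
  mu <- 6 - 0.5 * b$w_pre + 0.1 * b$w_post
  # marginal SD of a weekly mean over 2000 users
  vc <- cfg$variance
  sdw <- sqrt(vc$sd_intercept^2 + (vc$sd_slope_pre * b$w_pre)^2 +
                vc$sd_residual^2) / sqrt(2000)
  expect_true(all(abs(mu_hat - mu) <= 3 * sdw))
})

test_that("noiseless subgroup output recovers planted trajectories by OLS", {
  rule <- subgroup_rule("age", breaks = 40, params = list(
    trajectory_params(4, -0.6, 0.05), trajectory_params(6, 0.2, -0.1)))
  cfg <- sim_config(n_users = 60, outcome_kind = "pain",
                    subgroup_rule = rule,
                    variance = variance_components(0, 0, 0, 0), seed = 3)
  tab <- simulate_cohort(cfg)$table
  for (grp in list(tab[tab$age <= 40, ], tab[tab$age > 40, ])) {
    co <- coef(lm(outcome ~ w_pre + w_post, grp))
    planted <- if (grp$age[1] <= 40) c(4, -0.6, 0.05) else c(6, 0.2, -0.1)
    expect_equal(unname(co), planted, tolerance = 1e-10)
  }
})

test_that("log-duration tables carry exponentiated minutes", {
  cfg <- sim_config(n_users = 50, outcome_kind = "log_duration", seed = 4)
  tab <- simulate_cohort(cfg)$table
  expect_equal(tab$minutes, exp(tab$outcome))
})

test_that("clipping keeps pain on the 0-10 scale when requested", {
  cfg <- sim_config(n_users = 500, outcome_kind = "pain",
                    params = trajectory_params(9.5, 0.5, 0.5),
                    clip_to_scale = TRUE, seed = 6)
  tab <- simulate_cohort(cfg)$table
  expect_true(all(tab$outcome >= 0 & tab$outcome <= 10))
})

test_that("inclusion filters enforce the strict study thresholds", {
  mk_user <- function(id, pain, minutes) {
    data.frame(user_id = id, week = 1:8, outcome = pain, minutes = minutes)
  }
  tab <- rbind(
    mk_user("border_pain", c(4, rep(5, 7)), rep(400, 8)),     # first pain == 4
    mk_user("ok", c(6, rep(5, 7)), rep(361, 8)),              # all rules pass
    mk_user("border_min", c(6, rep(5, 7)), rep(360, 8)),      # minutes == 360
    mk_user("short", c(6, rep(5, 7)), c(rep(400, 7), 100)),   # 7 of 8 weeks
    mk_user("sparse", c(6, rep(NA, 7)), rep(400, 8))          # one rating
  )
  res <- apply_inclusion_filter(tab)
  expect_identical(unique(res$table$user_id), "ok")
  expect_equal(res$n_users_out, 1)
  expect_gte(res$excluded[["first_pain"]], 1)
  expect_gte(res$excluded[["weekly_minutes"]], 2)
  expect_gte(res$excluded[["min_ratings"]], 1)

  # idempotence
  res2 <- apply_inclusion_filter(res$table)
  expect_equal(res2$table$outcome, res$table$outcome)
  expect_equal(res2$n_users_out, res$n_users_out)

  expect_error(apply_inclusion_filter(tab[, c("user_id", "week", "outcome")]),
               "schema error")
})

test_that("cohorts round-trip through CSV", {
  cfg <- sim_config(n_users = 20, seed = 8)
  tab <- simulate_cohort(cfg)$table
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(tab, path)
  back <- read_cohort(path)
  expect_equal(back$outcome, tab$outcome)
  expect_equal(back$gender, tab$gender)
})

test_that("YAML configs mirror sim_config arguments", {
  skip_if_not_installed("yaml")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_users: 25", "outcome_kind: posture", "seed: 42",
    "params: {intercept: 3.7, slope_pre: 0.4, slope_post: 0.05}",
    "variance: {sd_intercept: 1.2, sd_slope_pre: 0.2, corr_int_slope: 0.0, sd_residual: 0.9}"
  ), path)
  cfg <- sim_config_from_yaml(path)
  expect_equal(cfg$n_users, 25L)
  expect_equal(cfg$params$slope_pre, 0.4)
  expect_equal(cfg$variance$sd_residual, 0.9)
})
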