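test_that("maxdepth = 1 forces the pooled piecewise model", {
  ch <- simulate_cohort(split40_config(1, n_users = 150))
  ctl <- tree_control(minsplit = 20, maxdepth = 1)
  tr <- fit_lmm_tree(ch$table, control = ctl)
  expect_equal(length(tr$leaf_ids), 1L)
  pooled <- fit_lmm(add_piecewise_basis(ch$table, 3),
                    outcome ~ w_pre + w_post)
  expect_equal(unname(tr$tree$coefficients),
               unname(pooled$beta), tolerance = 1e-6)
  expect_equal(predict_tree(tr, ch$table),
               predict_lmm(pooled, add_piecewise_basis(ch$table, 3)),
               tolerance = 1e-6)
})

test_that("growth stops at small nodes and constant moderators", {
  ch <- simulate_cohort(split40_config(2, n_users = 150))
  tab <- add_piecewise_basis(ch$table, 3)
  tab$.ystar <- tab$outcome
  ctl <- tree_control(minsplit = 20, maxdepth = 5)
  small <- grow_mob(tab[1:100, ], c("age", "gender", "bmi"),
                    tree_control(minsplit = 200), outcome = ".ystar")
  expect_null(small$children)
  const <- tab
  const$age <- 50
  const$bmi <- 25
  const$gender <- factor(rep("female", nrow(const)),
                         levels = c("female", "male"))
  expect_null(grow_mob(const, c("age", "gender", "bmi"), ctl,
                       outcome = ".ystar")$children)
})

test_that("a large gender shift splits on gender", {
  rule <- subgroup_rule("gender", params = list(
    trajectory_params(0, 0, 0), trajectory_params(10, 0, 0)))
  cfg <- sim_config(n_users = 120, outcome_kind = "pain",
                    subgroup_rule = rule,
                    variance = variance_components(0, 0, 0, 0.1), seed = 3)
  tr <- fit_lmm_tree(simulate_cohort(cfg)$table,
                     control = tree_control(minsplit = 20, maxdepth = 2))
  expect_identical(tr$tree$split$variable, "gender")
  expect_equal(length(tr$leaf_ids), 2L)
})

test_that("zero variance components reduce to a single pass of grow_mob", {
  rule <- subgroup_rule("age", breaks = 40, params = list(
    trajectory_params(5, -0.5, 0), trajectory_params(5, 0.5, 0)))
  cfg <- sim_config(n_users = 200, outcome_kind = "pain",
                    subgroup_rule = rule,
                    variance = variance_components(0, 0, 0, 0.3), seed = 4)
  tab <- simulate_cohort(cfg)$table
  ctl <- tree_control(minsplit = 50, maxdepth = 2)
  tr <- fit_lmm_tree(tab, control = ctl)
  raw <- grow_mob(add_piecewise_basis(tab, 3), c("age", "gender", "bmi"),
                  ctl)
  expect_identical(tr$tree$split$variable, raw$split$variable)
  expect_equal(tr$tree$split$split_point, raw$split$split_point)
})

test_that("the alternation log-likelihood trace is nondecreasing", {
  ch <- simulate_cohort(split40_config(5, n_users = 300))
  ctl <- tree_control(minsplit = 90, maxdepth = 3)
  tr <- fit_lmm_tree(ch$table, control = ctl)
  expect_true(tr$converged)
  if (length(tr$loglik_trace) > 1) {
    expect_true(all(diff(tr$loglik_trace) >= -10 * ctl$tol))
  }
})

test_that("observations partition exactly across terminal nodes", {
  ch <- simulate_cohort(split40_config(6, n_users = 300))
  tr <- fit_lmm_tree(ch$table, control = tree_control(minsplit = 90,
                                                      maxdepth = 3))
  leaves <- pwlmmtree:::collect_leaves(tr$tree)
  expect_equal(sum(vapply(leaves, `[[`, 0L, "n_obs")), nrow(ch$table))
  leaf_of <- pwlmmtree:::route_rows(tr$tree, add_piecewise_basis(ch$table, 3))
  expect_true(all(leaf_of %in% tr$leaf_ids))
  cnt <- table(leaf_of)
  for (l in leaves) {
    expect_equal(unname(cnt[[as.character(l$node_id)]]), l$n_obs)
  }
})

test_that("moderators varying within user are rejected", {
  ch <- simulate_cohort(null_pain_config(7, n_users = 30))
  tab <- ch$table
  tab$age <- tab$age + tab$week / 10
  expect_error(fit_lmm_tree(tab), "invalid-moderator")
  tab2 <- ch$table
  tab2$gender <- factor(sample(c("a", "b", "c"), nrow(tab2), TRUE))
  tab2$gender <- ave(as.character(tab2$gender), tab2$user_id,
                     FUN = function(x) x[1])
  expect_error(fit_lmm_tree(tab2), "unsupported-moderator")
})

test_that("routing applies printed node intercepts at week 1", {
  # synthetic fixture tree with the published pain-node week-1 levels:
  # age <= 17 -> 5.173, 17 < age <= 56 -> 6.156,
  # 56 < age <= 66 -> 5.383, age > 66 -> 5.260
  leaf <- function(id, b0) {
    n <- pwlmmtree:::new_tree_node(id, 10L, 3L)
    n$coefficients <- c(intercept = b0, w_pre = -0.2, w_post = 0)
    n$se <- c(intercept = 0.1, w_pre = 0.05, w_post = 0.02)
    n$coef_pvalues <- c(intercept = 0, w_pre = 0, w_post = 1)
    n
  }
  inner <- function(id, var, thr, kids, depth) {
    n <- pwlmmtree:::new_tree_node(id, 20L, depth)
    n$split <- list(variable = var, type = "numeric", split_point = thr)
    n$children <- kids
    n$instability_pvalues <- c(age = 1e-5)
    n
  }
  tree <- inner(1, "age", 56,
                list(inner(2, "age", 17, list(leaf(3, 5.173),
                                              leaf(4, 6.156)), 2L),
                     inner(5, "age", 66, list(leaf(6, 5.383),
                                              leaf(7, 5.260)), 2L)), 1L)
  fit <- structure(list(tree = tree,
                        lmm = list(blups = data.frame(
                          user_id = character(0), b_intercept = numeric(0),
                          b_slope = numeric(0))),
                        leaf_ids = c(3L, 4L, 6L, 7L),
                        breakpoint_week = 3, outcome = "outcome"),
                   class = "lmm_tree_fit")
  nd <- data.frame(user_id = "new", week = 1, age = c(10, 40, 60, 80))
  expect_equal(predict_tree(fit, nd), c(5.173, 6.156, 5.383, 5.260))
  expect_equal(predict_tree(fit, nd, include_random = TRUE),
               predict_tree(fit, nd, include_random = FALSE))
  expect_error(predict_tree(fit, data.frame(week = 1)), "schema error")
})

test_that("fitted trees round-trip through JSON", {
  ch <- simulate_cohort(split40_config(8, n_users = 200))
  tr <- fit_lmm_tree(ch$table, control = tree_control(minsplit = 50,
                                                      maxdepth = 2))
  path <- withr::local_tempfile(fileext = ".json")
  tree_to_json(tr, path)
  back <- tree_from_json(path)
  expect_equal(back$leaf_ids, tr$leaf_ids)
  expect_equal(back$aic, tr$aic)
  expect_equal(predict_tree(back, ch$table, include_random = TRUE),
               predict_tree(tr, ch$table, include_random = TRUE))
  expect_output(print(back), "terminal nodes")
})
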