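#' Percent change per week implied by a log-scale slope
#'
#' For models of a log-transformed outcome, a slope `b` on the log scale
#' corresponds to a multiplicative change `exp(b)` per week, i.e.
#' `(exp(b) - 1) * 100` percent.
#'
#' @param b log-scale slope coefficient (finite).
#' @return percent change per week.
#' @examples
#' percent_change(0.108)  # ~11.4% weekly increase
#' @export
percent_change <- function(b) {
  if (any(!is.finite(b))) {
    stop("domain error: 'b' must be finite", call. = FALSE)
  }
  (exp(b) - 1) * 100
}

#' Back-transform a log-scale intercept to original units
#'
#' @param b0 log-scale intercept (finite).
#' @return `exp(b0)`, the week-1 level in original units (e.g. minutes).
#' @export
backtransform_intercept <- function(b0) {
  if (any(!is.finite(b0))) {
    stop("domain error: 'b0' must be finite", call. = FALSE)
  }
  exp(b0)
}

leaf_rule_strings <- function(node, path = character(0)) {
  if (is.null(node$children)) {
    lbl <- if (length(path)) paste(path, collapse = " & ") else "all users"
    return(stats::setNames(list(lbl), as.character(node$node_id)))
  }
  c(leaf_rule_strings(node$children[[1]],
                      c(path, split_label(node$split, 1))),
    leaf_rule_strings(node$children[[2]],
                      c(path, split_label(node$split, 2))))
}

#' Terminal-node summary table
#'
#' One row per terminal node: the subgroup rule along the path from the
#' root, observation count, the piecewise coefficients with naive Wald
#' p-values, and — for log-scale outcomes — the back-transformed week-1
#' level and the percent change per week of each slope.
#'
#' @param fit an `lmm_tree_fit`.
#' @param log_scale back-transform intercepts and slopes?  Defaults to
#'   `TRUE` when the fit's outcome kind is `log_duration`.
#' @return a data.frame, one row per terminal node.
#' @export
node_summary <- function(fit, log_scale = NULL) {
  if (is.null(log_scale)) log_scale <- identical(fit$outcome, "log_duration")
  leaves <- collect_leaves(fit$tree)
  rules <- leaf_rule_strings(fit$tree)
  out <- do.call(rbind, lapply(leaves, function(l) {
    co <- l$coefficients
    pv <- l$coef_pvalues
    row <- data.frame(
      node_id = l$node_id,
      subgroup = rules[[as.character(l$node_id)]],
      n_obs = l$n_obs,
      intercept = co["intercept"],
      slope_pre = co["w_pre"], p_pre = pv["w_pre"],
      slope_post = co["w_post"], p_post = pv["w_post"],
      p_intercept = pv["intercept"],
      row.names = NULL
    )
    if (log_scale) {
      row$level_week1 <- backtransform_intercept(co["intercept"])
      row$pct_change_pre <- percent_change(co["w_pre"])
      row$pct_change_post <- percent_change(co["w_post"])
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' Caterpillar-plot data for node-specific fixed effects
#'
#' One row per (terminal node, parameter) with the estimate and a normal
#' Wald confidence interval, `estimate +/- z(level) * se`.  These are
#' naive (not selection-adjusted) intervals from the joint mixed model.
#'
#' @param fit an `lmm_tree_fit` whose terminal nodes carry standard
#'   errors.
#' @param level confidence level (default 0.95).
#' @return data.frame with columns `node_id`, `parameter`, `estimate`,
#'   `lower`, `upper`.
#' @export
caterpillar_data <- function(fit, level = 0.95) {
  leaves <- collect_leaves(fit$tree)
  if (any(vapply(leaves, function(l) is.null(l$se), logical(1)))) {
    stop("incomplete-fit error: terminal nodes lack standard errors",
         call. = FALSE)
  }
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- do.call(rbind, lapply(leaves, function(l) {
    data.frame(node_id = l$node_id,
               parameter = c("intercept", "w_pre", "w_post"),
               estimate = unname(l$coefficients),
               lower = unname(l$coefficients - zq * l$se),
               upper = unname(l$coefficients + zq * l$se))
  }))
  rownames(out) <- NULL
  out
}

summarise_numeric <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
    min = min(x), max = max(x), mean = mean(x), sd = stats::sd(x))
}

#' Descriptive table of user moderators by gender
#'
#' For each numeric moderator (age, BMI): overall and per-gender N,
#' median, IQR (linear-interpolation quantiles, type 7), range, mean and
#' SD, plus a two-sided Wilcoxon rank-sum p-value comparing the genders
#' (exact for small tie-free samples, normal approximation with
#' continuity and tie correction otherwise — the `stats::wilcox.test`
#' conventions).  With fewer than 2 users in a gender the summaries are
#' still emitted and the test is skipped (`NA` with a note).
#'
#' @param profiles data.frame of user profiles (`age`, `gender`, `bmi`).
#' @param variables moderators to summarise.
#' @return data.frame with one row per (variable, group in
#'   overall/female/male) and a `p_value` column on the overall rows.
#' @export
descriptive_table <- function(profiles, variables = c("bmi", "age")) {
  if (nrow(profiles) < 1) {
    stop("invalid-config error: no profiles", call. = FALSE)
  }
  groups <- list(overall = profiles,
                 female = profiles[profiles$gender == "female", ],
                 male = profiles[profiles$gender == "male", ])
  rows <- list()
  for (v in variables) {
    can_test <- nrow(groups$female) >= 2 && nrow(groups$male) >= 2
    p <- if (can_test) {
      suppressWarnings(stats::wilcox.test(
        groups$female[[v]], groups$male[[v]],
        alternative = "two.sided")$p.value)
    } else NA_real_
    for (g in names(groups)) {
      gd <- groups[[g]]
      if (nrow(gd) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, group = g, n = 0, median = NA, q1 = NA, q3 = NA,
          min = NA, max = NA, mean = NA, sd = NA,
          p_value = NA_real_, note = "empty group; test skipped")
        next
      }
      s <- summarise_numeric(gd[[v]])
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, group = g, n = s["n"], median = s["median"],
        q1 = s["q1"], q3 = s["q3"], min = s["min"], max = s["max"],
        mean = s["mean"], sd = s["sd"],
        p_value = if (g == "overall") p else NA_real_,
        note = if (g == "overall" && !can_test) "test skipped" else "")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a plain-text report of a fitted LMM tree
#'
#' Emits the node-summary table, the caterpillar CSV, and (when profiles
#' are supplied) the descriptive table, as a markdown file plus CSV
#' side-files.
#'
#' @param fit an `lmm_tree_fit`.
#' @param path output markdown path; CSVs are written next to it.
#' @param profiles optional user-profile data.frame for the descriptive
#'   table.
#' @param log_scale passed to [node_summary()].
#' @return invisibly, the markdown path.
#' @export
write_report <- function(fit, path, profiles = NULL, log_scale = NULL) {
  ns <- node_summary(fit, log_scale = log_scale)
  cat_df <- caterpillar_data(fit)
  stem <- sub("\\.md$", "", path)
  utils::write.csv(ns, paste0(stem, "_nodes.csv"), row.names = FALSE)
  utils::write.csv(cat_df, paste0(stem, "_caterpillar.csv"),
                   row.names = FALSE)
  lines <- c("# Piecewise LMM tree report", "",
             sprintf("Terminal nodes: %d; AIC: %.2f; converged: %s",
                     length(fit$leaf_ids), fit$aic, fit$converged), "",
             "## Node summary", "",
             utils::capture.output(print(ns, digits = 4)))
  if (!is.null(profiles)) {
    desc <- descriptive_table(profiles)
    utils::write.csv(desc, paste0(stem, "_descriptives.csv"),
                     row.names = FALSE)
    lines <- c(lines, "", "## Cohort descriptives", "",
               utils::capture.output(print(desc, digits = 4)))
  }
  writeLines(lines, path)
  invisible(path)
}
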