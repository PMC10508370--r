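#' Trajectory parameters for one subgroup
#'
#' Fixed effects of the two-segment weekly trajectory: the expected outcome
#' at week 1 (`intercept`), the per-week slope before the breakpoint
#' (`slope_pre`) and the per-week slope after it (`slope_post`).
#'
#' @param intercept expected outcome at week 1, in outcome units.
#' @param slope_pre slope over the first segment, outcome units per week.
#' @param slope_post slope over the second segment, outcome units per week.
#' @return an object of class `trajectory_params`.
#' @export
trajectory_params <- function(intercept, slope_pre, slope_post) {
  vals <- c(intercept = intercept, slope_pre = slope_pre,
            slope_post = slope_post)
  if (any(!is.finite(vals))) {
    stop("invalid-config error: trajectory parameters must be finite",
         call. = FALSE)
  }
  structure(as.list(vals), class = "trajectory_params")
}

#' Random-effect and residual standard deviations
#'
#' Describes the user-level random intercept, the random slope on the first
#' piecewise segment, their correlation, and the residual noise.
#'
#' @param sd_intercept SD of the user random intercept (outcome units).
#' @param sd_slope_pre SD of the user random slope on `w_pre`
#'   (outcome units per week).
#' @param corr_int_slope correlation between the two random effects,
#'   in \[-1, 1\].
#' @param sd_residual residual SD (outcome units).
#' @return an object of class `variance_components`.
#' @export
variance_components <- function(sd_intercept = 0, sd_slope_pre = 0,
                                corr_int_slope = 0, sd_residual = 0) {
  if (sd_intercept < 0 || sd_slope_pre < 0 || sd_residual < 0) {
    stop("invalid-config error: standard deviations must be >= 0",
         call. = FALSE)
  }
  if (abs(corr_int_slope) > 1) {
    stop("invalid-config error: corr_int_slope must lie in [-1, 1]",
         call. = FALSE)
  }
  structure(list(sd_intercept = sd_intercept, sd_slope_pre = sd_slope_pre,
                 corr_int_slope = corr_int_slope, sd_residual = sd_residual),
            class = "variance_components")
}

#' Planted subgroup rule
#'
#' Assigns each user to one trajectory according to a single moderator.
#' For a numeric moderator (`age`, `bmi`), `breaks` gives interior cut
#' points, so `length(breaks) + 1` branches partition the real line into
#' intervals `(-Inf, b1], (b1, b2], ..., (bk, Inf)`.  For `gender` the
#' branches are the factor levels (`female`, `male`).  Either way the
#' branches are disjoint and exhaustive by construction.
#'
#' @param variable one of `"age"`, `"bmi"`, `"gender"`.
#' @param breaks numeric cut points (numeric moderators only).
#' @param params list of [trajectory_params()], one per branch, ordered by
#'   interval (numeric) or by factor level (gender).
#' @return an object of class `subgroup_rule`.
#' @export
subgroup_rule <- function(variable, breaks = NULL, params) {
  variable <- match.arg(variable, c("age", "bmi", "gender"))
  if (variable == "gender") {
    if (length(params) != 2L) {
      stop("invalid-config error: gender rule needs one trajectory per level",
           call. = FALSE)
    }
  } else {
    if (is.null(breaks) || length(params) != length(breaks) + 1L) {
      stop("invalid-config error: need length(breaks) + 1 trajectories",
           call. = FALSE)
    }
    if (is.unsorted(breaks, strictly = TRUE)) {
      stop("invalid-config error: breaks must be strictly increasing",
           call. = FALSE)
    }
  }
  stopifnot(all(vapply(params, inherits, TRUE, "trajectory_params")))
  structure(list(variable = variable, breaks = breaks, params = params),
            class = "subgroup_rule")
}

default_trajectory <- function(outcome_kind) {
  switch(outcome_kind,
    pain = trajectory_params(5.5, -0.45, 0.02),
    posture = trajectory_params(3.7, 0.45, 0.05),
    log_duration = trajectory_params(6.05, 0.05, -0.12)
  )
}

default_variance <- function(outcome_kind) {
  switch(outcome_kind,
    pain = variance_components(1.5, 0.25, 0, 1.0),
    posture = variance_components(1.4, 0.25, 0, 1.0),
    log_duration = variance_components(0.55, 0.08, 0, 0.45)
  )
}

#' Simulation configuration for a synthetic weekly cohort
#'
#' Bundles everything the generator needs: cohort size, follow-up length,
#' the breakpoint of the planted piecewise mean, the outcome kind, the
#' planted fixed effects (either a single [trajectory_params()] or a
#' [subgroup_rule()] with branch-specific trajectories), variance
#' components, and moderator distributions.  Moderator defaults are
#' truncated normals for age (mean 43.8, SD 15.8, range 15-94) and BMI
#' (mean 24.5, SD 5.0, range 11-55) with 60% women.
#'
#' @param n_users number of users, `>= 1`.
#' @param weeks follow-up length in weeks (default 8).
#' @param breakpoint_week planted breakpoint (default 3); must satisfy
#'   `1 < breakpoint_week < weeks`.
#' @param outcome_kind `"pain"`, `"posture"` or `"log_duration"`.
#' @param params [trajectory_params()] used when no subgroup rule is set.
#' @param subgroup_rule optional [subgroup_rule()] planting heterogeneous
#'   trajectories.
#' @param variance [variance_components()].
#' @param clip_to_scale clip pain/posture outcomes into \[0, 10\]
#'   (default off: clipping distorts the linear model the estimators
#'   assume, so it is opt-in realism).
#' @param selfreport_frac fraction of users who self-report the outcome;
#'   non-reporters keep device columns but have `NA` outcomes
#'   (pain/posture only).
#' @param age_mean,age_sd,age_range,bmi_mean,bmi_sd,bmi_range,p_female
#'   moderator distribution parameters.
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of the config.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_users, weeks = 8, breakpoint_week = 3,
                       outcome_kind = c("pain", "posture", "log_duration"),
                       params = NULL, subgroup_rule = NULL,
                       variance = NULL, clip_to_scale = FALSE,
                       selfreport_frac = 1,
                       age_mean = 43.8, age_sd = 15.8, age_range = c(15, 94),
                       bmi_mean = 24.5, bmi_sd = 5.0, bmi_range = c(11, 55),
                       p_female = 0.60, seed = 1L) {
  outcome_kind <- match.arg(outcome_kind)
  if (!is.numeric(n_users) || length(n_users) != 1 || n_users < 1) {
    stop("invalid-config error: n_users must be >= 1", call. = FALSE)
  }
  if (weeks < 2) {
    stop("invalid-config error: weeks must be >= 2", call. = FALSE)
  }
  if (breakpoint_week <= 1 || breakpoint_week >= weeks) {
    stop("invalid-config error: need 1 < breakpoint_week < weeks",
         call. = FALSE)
  }
  if (selfreport_frac < 0 || selfreport_frac > 1) {
    stop("invalid-config error: selfreport_frac must lie in [0, 1]",
         call. = FALSE)
  }
  if (is.null(params)) params <- default_trajectory(outcome_kind)
  if (is.null(variance)) variance <- default_variance(outcome_kind)
  stopifnot(inherits(params, "trajectory_params"),
            inherits(variance, "variance_components"),
            is.null(subgroup_rule) || inherits(subgroup_rule, "subgroup_rule"))
  structure(list(
    n_users = as.integer(n_users), weeks = as.integer(weeks),
    breakpoint_week = breakpoint_week, outcome_kind = outcome_kind,
    params = params, subgroup_rule = subgroup_rule, variance = variance,
    clip_to_scale = clip_to_scale, selfreport_frac = selfreport_frac,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd, bmi_range = bmi_range,
    p_female = p_female, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [sim_config()]; `params` and
#' `variance` are given as mappings, e.g.
#' `params: {intercept: 5.5, slope_pre: -0.45, slope_post: 0.02}`.
#'
#' @param path path to a YAML file.
#' @return a [sim_config()] object.
#' @export
sim_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$params)) raw$params <- do.call(trajectory_params, raw$params)
  if (!is.null(raw$variance)) {
    raw$variance <- do.call(variance_components, raw$variance)
  }
  do.call(sim_config, raw)
}

truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

# location parameter such that the truncated normal has the target mean
# (asymmetric truncation shifts the mean away from the location)
truncnorm_location <- function(target, sd, lo, hi) {
  stats::uniroot(function(mu) truncnorm_mean(mu, sd, lo, hi) - target,
                 interval = target + c(-3, 3) * sd, tol = 1e-8)$root
}

rtruncnorm <- function(n, target_mean, sd, lo, hi) {
  # inverse-CDF sampler: deterministic given the RNG stream, no rejection
  mu <- truncnorm_location(target_mean, sd, lo, hi)
  plo <- stats::pnorm(lo, mu, sd)
  phi <- stats::pnorm(hi, mu, sd)
  stats::qnorm(stats::runif(n, plo, phi), mu, sd)
}

#' Generate user-level moderator profiles
#'
#' Draws `n_users` profiles with age and BMI from truncated normal
#' distributions and gender from a Bernoulli draw, using the config's seed
#' (the caller's RNG state is left untouched).  The normal's location is
#' calibrated so that the truncated distribution's mean equals the
#' configured mean — asymmetric truncation would otherwise shift it.
#'
#' @param config a [sim_config()].
#' @return a data.frame with columns `user_id`, `age`, `gender` (factor
#'   with levels `female`, `male`), `bmi`.
#' @export
generate_users <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_users
    data.frame(
      user_id = sprintf("u%05d", seq_len(n)),
      age = rtruncnorm(n, config$age_mean, config$age_sd,
                       config$age_range[1], config$age_range[2]),
      gender = factor(ifelse(stats::runif(n) < config$p_female,
                             "female", "male"),
                      levels = c("female", "male")),
      bmi = rtruncnorm(n, config$bmi_mean, config$bmi_sd,
                       config$bmi_range[1], config$bmi_range[2]),
      stringsAsFactors = FALSE
    )
  })
}

#' Map users to their planted subgroup
#'
#' @param users data.frame of user profiles.
#' @param rule a [subgroup_rule()] or `NULL` (everyone in group 1).
#' @return integer branch index per user.
#' @export
assign_subgroup <- function(users, rule) {
  if (is.null(rule)) return(rep(1L, nrow(users)))
  z <- users[[rule$variable]]
  if (rule$variable == "gender") {
    as.integer(factor(z, levels = c("female", "male")))
  } else {
    findInterval(z, rule$breaks, left.open = TRUE) + 1L
  }
}

#' Simulate the weekly outcome table for a set of users
#'
#' Builds one row per user-week.  The outcome follows the planted
#' two-segment mean for the user's subgroup plus a user random intercept,
#' a user random slope on the first segment, and Gaussian residual noise:
#' \deqn{y_{it} = b_0 + b_1 w_{pre} + b_2 w_{post} + u_{0i} + u_{1i} w_{pre}
#'   + \varepsilon_{it}.}
#' For `log_duration` the stored `outcome` column is the log-scale value
#' and a back-transformed `minutes` column is added.
#'
#' @param users data.frame from [generate_users()].
#' @param config a [sim_config()].
#' @return long-format data.frame (`user_id`, `week`, `outcome`, `age`,
#'   `gender`, `bmi`, `w_pre`, `w_post`, and `minutes` for duration), with
#'   the outcome kind in the `"outcome_kind"` attribute.
#' @export
simulate_outcome <- function(users, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(users) == 0) {
    stop("invalid-config error: 'users' must be non-empty", call. = FALSE)
  }
  n <- nrow(users)
  weeks <- seq_len(config$weeks)
  grp <- assign_subgroup(users, config$subgroup_rule)
  par_list <- if (is.null(config$subgroup_rule)) list(config$params) else {
    config$subgroup_rule$params
  }
  beta <- do.call(rbind, lapply(par_list, function(p) {
    c(p$intercept, p$slope_pre, p$slope_post)
  }))

  vc <- config$variance
  Sigma <- matrix(c(vc$sd_intercept^2,
                    vc$corr_int_slope * vc$sd_intercept * vc$sd_slope_pre,
                    vc$corr_int_slope * vc$sd_intercept * vc$sd_slope_pre,
                    vc$sd_slope_pre^2), 2, 2)

  withr::with_seed(config$seed + 1L, {
    # bivariate normal random effects via the (possibly rank-deficient)
    # Cholesky-like square root of Sigma
    ev <- eigen(Sigma, symmetric = TRUE)
    rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors)
    u <- matrix(stats::rnorm(2 * n), n, 2) %*% rt
    eps <- stats::rnorm(n * config$weeks, 0, vc$sd_residual)
    reporter <- stats::runif(n) < config$selfreport_frac

    tab <- data.frame(
      user_id = rep(users$user_id, each = config$weeks),
      week = rep(weeks, times = n),
      stringsAsFactors = FALSE
    )
    tab <- add_piecewise_basis(tab, config$breakpoint_week)
    bi <- beta[grp, , drop = FALSE]
    idx <- rep(seq_len(n), each = config$weeks)
    mu <- bi[idx, 1] + bi[idx, 2] * tab$w_pre + bi[idx, 3] * tab$w_post
    y <- mu + u[idx, 1] + u[idx, 2] * tab$w_pre + eps

    if (config$outcome_kind %in% c("pain", "posture")) {
      if (config$clip_to_scale) y <- pmin(pmax(y, 0), 10)
      y[!reporter[idx]] <- NA_real_
    }
    tab$outcome <- y
    tab$age <- users$age[idx]
    tab$gender <- users$gender[idx]
    tab$bmi <- users$bmi[idx]
    if (config$outcome_kind == "log_duration") tab$minutes <- exp(y)
    attr(tab, "outcome_kind") <- config$outcome_kind
    attr(tab, "breakpoint_week") <- config$breakpoint_week
    tab
  })
}

#' Generate users and their outcome table in one call
#'
#' @param config a [sim_config()].
#' @return list with `users` (profiles) and `table` (long outcome table).
#' @export
simulate_cohort <- function(config) {
  users <- generate_users(config)
  list(users = users, table = simulate_outcome(users, config))
}

#' Apply the study-style inclusion filters to a cohort
#'
#' Retains users who (a) report pain above `first_pain_gt` at their first
#' available assessment, (b) have at least `min_ratings` non-missing
#' outcome ratings, and (c) trained strictly more than
#' `min_weekly_minutes` minutes in each of the first `min_weeks` weeks.
#' Pass `NULL` for a threshold to skip that rule (e.g. the minutes rule
#' when the table carries no `minutes` column).
#'
#' @param table long-format cohort table.
#' @param first_pain_gt strict lower bound on the first assessment
#'   (default 4), or `NULL`.
#' @param min_ratings minimum number of non-missing ratings (default 2),
#'   or `NULL`.
#' @param min_weeks number of initial weeks the minutes rule covers
#'   (default 8).
#' @param min_weekly_minutes strict weekly minutes bound (default 360,
#'   i.e. 6 hours), or `NULL`.
#' @return list with `table` (rows of retained users only), `excluded`
#'   (named per-rule counts of users failing each rule; a user may fail
#'   several), `n_users_in`, `n_users_out`.
#' @export
apply_inclusion_filter <- function(table, first_pain_gt = 4, min_ratings = 2,
                                   min_weeks = 8, min_weekly_minutes = 360) {
  need <- c("user_id", "week")
  if (!is.null(first_pain_gt) || !is.null(min_ratings)) {
    need <- c(need, "outcome")
  }
  if (!is.null(min_weekly_minutes)) need <- c(need, "minutes")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  ids <- unique(table$user_id)
  ok <- rep(TRUE, length(ids))
  names(ok) <- ids
  excluded <- integer(0)

  by_user <- split(seq_len(nrow(table)), table$user_id)
  by_user <- by_user[ids]

  if (!is.null(first_pain_gt)) {
    fail <- vapply(by_user, function(i) {
      rows <- table[i, ]
      rows <- rows[!is.na(rows$outcome), ]
      if (nrow(rows) == 0) return(TRUE)
      first <- rows$outcome[which.min(rows$week)]
      !(first > first_pain_gt)
    }, logical(1))
    excluded["first_pain"] <- sum(fail)
    ok <- ok & !fail
  }
  if (!is.null(min_ratings)) {
    fail <- vapply(by_user, function(i) {
      sum(!is.na(table$outcome[i])) < min_ratings
    }, logical(1))
    excluded["min_ratings"] <- sum(fail)
    ok <- ok & !fail
  }
  if (!is.null(min_weekly_minutes)) {
    fail <- vapply(by_user, function(i) {
      rows <- table[i, ]
      qualifying <- rows$week[!is.na(rows$minutes) &
                                rows$minutes > min_weekly_minutes]
      !all(seq_len(min_weeks) %in% qualifying)
    }, logical(1))
    excluded["weekly_minutes"] <- sum(fail)
    ok <- ok & !fail
  }

  keep <- names(ok)[ok]
  out <- table[table$user_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "outcome_kind") <- attr(table, "outcome_kind")
  attr(out, "breakpoint_week") <- attr(table, "breakpoint_week")
  list(table = out, excluded = excluded,
       n_users_in = length(ids), n_users_out = length(keep))
}

#' Write / read a cohort table as CSV
#'
#' Long format, UTF-8, header row; `gender` round-trips as a factor with
#' levels `female`, `male`.
#'
#' @param table cohort data.frame.
#' @param path file path.
#' @return `read_cohort` returns the data.frame; `write_cohort` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if ("gender" %in% names(tab)) {
    tab$gender <- factor(tab$gender, levels = c("female", "male"))
  }
  tab
}
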