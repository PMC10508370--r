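#' Root mean square error
#'
#' @param observed,predicted equal-length non-empty numeric vectors.
#' @return `sqrt(mean((observed - predicted)^2))`.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) == 0) {
    stop("schema error: observed and predicted must be non-empty and of equal length",
         call. = FALSE)
  }
  sqrt(mean((observed - predicted)^2))
}

#' User-level train/test split
#'
#' Samples `round(test_fraction * n_users)` users into a test set; all of
#' a user's rows go to one side, so the split is user-disjoint.
#'
#' @param table long-format table with `user_id`.
#' @param test_fraction fraction of users held out, in (0, 1).
#' @param seed RNG seed (caller's RNG state untouched).
#' @return list with `train` and `test` data.frames.
#' @export
split_by_user <- function(table, test_fraction = 0.2, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("invalid-config error: test_fraction must lie in (0, 1)",
         call. = FALSE)
  }
  ids <- unique(table$user_id)
  if (length(ids) < 2) {
    stop("cannot-split error: need at least 2 users", call. = FALSE)
  }
  n_test <- round(test_fraction * length(ids))
  test_ids <- withr::with_seed(seed, sample(ids, n_test))
  keep_attrs <- function(x) {
    attr(x, "outcome_kind") <- attr(table, "outcome_kind")
    attr(x, "breakpoint_week") <- attr(table, "breakpoint_week")
    rownames(x) <- NULL
    x
  }
  list(train = keep_attrs(table[!table$user_id %in% test_ids, , drop = FALSE]),
       test = keep_attrs(table[table$user_id %in% test_ids, , drop = FALSE]))
}

#' User-level k-fold partition
#'
#' Shuffles users and deals them into `k` folds whose sizes differ by at
#' most one user; each fold's rows form the validation set and the rest
#' the training set.
#'
#' @param table long-format table with `user_id`.
#' @param k number of folds, `>= 2` and at most the number of users.
#' @param seed RNG seed.
#' @return list of `k` lists, each with `train` and `validation`
#'   data.frames and the fold's `user_ids`.
#' @export
kfold_by_user <- function(table, k = 5, seed = 1L) {
  ids <- unique(table$user_id)
  if (k < 2 || k > length(ids)) {
    stop("invalid-config error: need 2 <= k <= number of users",
         call. = FALSE)
  }
  shuffled <- withr::with_seed(seed, sample(ids))
  fold_of <- rep(seq_len(k), length.out = length(ids))
  lapply(seq_len(k), function(f) {
    val_ids <- shuffled[fold_of == f]
    list(train = table[!table$user_id %in% val_ids, , drop = FALSE],
         validation = table[table$user_id %in% val_ids, , drop = FALSE],
         user_ids = val_ids)
  })
}

#' Compare candidate breakpoints (and the single-slope model) by AIC
#'
#' Fits one piecewise linear mixed model per candidate breakpoint —
#' `outcome ~ w_pre + w_post + (1 + w_pre | user_id)` — plus, optionally,
#' the single-slope model `outcome ~ t + (1 + t | user_id)` (the
#' degenerate basis with the breakpoint beyond the last week), all by
#' maximum likelihood so the AICs are comparable.  Non-convergent
#' candidates are flagged and excluded from the argmin with a warning.
#' Ties go to the model with fewer parameters, then to the first listed.
#'
#' @param table long-format table with `user_id`, `week` and the outcome.
#' @param candidate_breakpoints weeks at which to place the break
#'   (default `c(3, 4)`).
#' @param include_linear also fit the single-slope comparator?
#' @param outcome outcome column name.
#' @return list with `aic_table` (data.frame: model, aic, n_params,
#'   converged), `winner` (`"break_3"`, ... or `"linear"`), and `fits`.
#' @export
compare_breakpoints <- function(table, candidate_breakpoints = c(3, 4),
                                include_linear = TRUE, outcome = "outcome") {
  weeks <- range(table$week)
  if (any(candidate_breakpoints <= weeks[1] |
            candidate_breakpoints >= weeks[2])) {
    stop("invalid-config error: breakpoints must lie strictly inside the observed week range",
         call. = FALSE)
  }
  fits <- list()
  labels <- character(0)
  for (bp in candidate_breakpoints) {
    tab <- add_piecewise_basis(table, bp)
    lab <- paste0("break_", bp)
    fits[[lab]] <- fit_lmm(tab, stats::as.formula(
      paste(outcome, "~ w_pre + w_post")), method = "ml")
    labels <- c(labels, lab)
  }
  if (include_linear) {
    tab <- table
    tab$t_week <- tab$week - 1
    fits[["linear"]] <- fit_lmm(tab, stats::as.formula(
      paste(outcome, "~ t_week")), random_slope_on = "t_week",
      method = "ml")
    labels <- c(labels, "linear")
  }
  aic_table <- data.frame(
    model = labels,
    aic = vapply(fits, `[[`, 0, "aic"),
    n_params = vapply(fits, `[[`, 0L, "n_params"),
    converged = vapply(fits, `[[`, TRUE, "converged"),
    row.names = NULL
  )
  usable <- aic_table$converged
  if (!all(usable)) {
    warning("excluding non-convergent candidate(s): ",
            paste(aic_table$model[!usable], collapse = ", "))
  }
  if (!any(usable)) {
    stop("no candidate model converged", call. = FALSE)
  }
  sub <- aic_table[usable, ]
  best <- sub[order(sub$aic, sub$n_params), ][1, "model"]
  tie <- sum(abs(sub$aic - min(sub$aic)) < 1e-8) > 1
  list(aic_table = aic_table, winner = best, tie = tie, fits = fits)
}

#' Choose the tree depth cap by AIC
#'
#' Fits one LMM tree per depth cap in `grid` and returns the AIC
#' minimizer; non-convergent depths are flagged and excluded (tree
#' convergence failures are expected at high complexity and are handled,
#' not raised).  Ties go to the shallower tree.
#'
#' @param table long-format table.
#' @param grid depth caps to try (default `2:5`).
#' @param control base [tree_control()]; its `maxdepth` is overridden.
#' @param ... passed to [fit_lmm_tree()].
#' @return list with `chosen_maxdepth`, `aic_table`, `fits`.
#' @export
tune_maxdepth <- function(table, grid = 2:5, control = tree_control(), ...) {
  if (!length(grid)) {
    stop("invalid-config error: empty depth grid", call. = FALSE)
  }
  fits <- list()
  for (d in grid) {
    ctl <- control
    ctl$maxdepth <- d
    fits[[as.character(d)]] <- fit_lmm_tree(table, control = ctl, ...)
  }
  aic_table <- data.frame(
    maxdepth = grid,
    aic = vapply(fits, `[[`, 0, "aic"),
    n_leaves = vapply(fits, function(f) length(f$leaf_ids), 0L),
    converged = vapply(fits, `[[`, TRUE, "converged"),
    row.names = NULL
  )
  usable <- aic_table$converged
  if (!all(usable)) {
    warning("excluding non-convergent depth(s): ",
            paste(aic_table$maxdepth[!usable], collapse = ", "))
  }
  if (!any(usable)) stop("no depth converged", call. = FALSE)
  sub <- aic_table[usable, ]
  chosen <- sub[order(sub$aic, sub$maxdepth), ][1, "maxdepth"]
  list(chosen_maxdepth = chosen, aic_table = aic_table, fits = fits)
}

#' Train/test and cross-validated evaluation of an LMM tree
#'
#' Splits users 80/20 (configurable), fits the tree on the training users,
#' and reports training RMSE (predictions including each training user's
#' BLUP) and test RMSE (fixed effects only, since held-out users have no
#' BLUP).  Optionally runs user-level k-fold cross-validation within the
#' training set.
#'
#' @param table long-format table.
#' @param control a [tree_control()].
#' @param test_fraction held-out user fraction.
#' @param k number of CV folds (`0` skips CV).
#' @param seed RNG seed for the splits.
#' @param ... passed to [fit_lmm_tree()].
#' @return an `evaluation_result` list: `rmse_train`, `rmse_test`,
#'   `cv_rmse` (per-fold values and their mean), `fit` (trained tree).
#' @export
evaluate_tree <- function(table, control = tree_control(),
                          test_fraction = 0.2, k = 5, seed = 1L, ...) {
  parts <- split_by_user(table, test_fraction, seed)
  fit <- fit_lmm_tree(parts$train, control = control, ...)
  obs_tr <- parts$train[[fit$outcome]]
  ok_tr <- !is.na(obs_tr)
  pred_tr <- predict_tree(fit, parts$train, include_random = TRUE)
  obs_te <- parts$test[[fit$outcome]]
  ok_te <- !is.na(obs_te)
  pred_te <- predict_tree(fit, parts$test, include_random = FALSE)

  cv <- NULL
  if (k >= 2) {
    folds <- kfold_by_user(parts$train, k, seed + 1L)
    per_fold <- vapply(folds, function(fold) {
      f <- fit_lmm_tree(fold$train, control = control, ...)
      obs <- fold$validation[[f$outcome]]
      ok <- !is.na(obs)
      rmse(obs[ok],
           predict_tree(f, fold$validation, include_random = FALSE)[ok])
    }, numeric(1))
    cv <- list(per_fold = per_fold, mean = mean(per_fold))
  }

  structure(list(
    rmse_train = rmse(obs_tr[ok_tr], pred_tr[ok_tr]),
    rmse_test = rmse(obs_te[ok_te], pred_te[ok_te]),
    cv_rmse = cv, fit = fit,
    n_train_users = length(unique(parts$train$user_id)),
    n_test_users = length(unique(parts$test$user_id))
  ), class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("Evaluation (", x$n_train_users, "train /", x$n_test_users,
      "test users )\n")
  cat(sprintf("  RMSE train: %.4f   RMSE test: %.4f\n",
              x$rmse_train, x$rmse_test))
  if (!is.null(x$cv_rmse)) {
    cat(sprintf("  CV RMSE (k=%d): %.4f  [%s]\n",
                length(x$cv_rmse$per_fold), x$cv_rmse$mean,
                paste(sprintf("%.3f", x$cv_rmse$per_fold), collapse = ", ")))
  }
  invisible(x)
}
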