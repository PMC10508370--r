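#' Control parameters for LMM-tree growth
#'
#' @param alpha significance level of the parameter-instability tests
#'   (default 0.05).
#' @param bonferroni multiply p-values by the number of tested moderators
#'   (default `TRUE`).
#' @param minsplit minimum observations (rows) a node must hold to attempt
#'   a split, and that each child must retain; must be at least twice the
#'   number of node-model parameters (6 here).
#' @param maxdepth maximum root-to-leaf depth (root has depth 1).
#' @param max_iter cap on random-effect / tree alternations.
#' @param tol convergence tolerance on the joint log-likelihood.
#' @param trim trimming fraction of the numeric sup-LM test.
#' @param method `"ml"` or `"reml"` for the joint mixed-model fits.
#' @return an object of class `tree_control`.
#' @export
tree_control <- function(alpha = 0.05, bonferroni = TRUE, minsplit = 90,
                         maxdepth = 5, max_iter = 100, tol = 1e-4,
                         trim = 0.1, method = "ml") {
  if (alpha <= 0 || alpha >= 1) {
    stop("invalid-config error: alpha must lie in (0, 1)", call. = FALSE)
  }
  if (minsplit < 6) {
    stop("invalid-config error: minsplit must be >= 6 (twice the node-model parameters)",
         call. = FALSE)
  }
  if (maxdepth < 1) {
    stop("invalid-config error: maxdepth must be >= 1", call. = FALSE)
  }
  structure(list(alpha = alpha, bonferroni = bonferroni,
                 minsplit = minsplit, maxdepth = maxdepth,
                 max_iter = max_iter, tol = tol, trim = trim,
                 method = method),
            class = "tree_control")
}

new_tree_node <- function(node_id, n_obs, depth) {
  list(node_id = node_id, n_obs = n_obs, depth = depth, split = NULL,
       children = NULL, coefficients = NULL, se = NULL, coef_pvalues = NULL,
       instability_pvalues = NULL)
}

node_model_scores <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  list(coef = fit$coefficients, scores = X * fit$residuals)
}

#' Grow a model-based recursive partition on an adjusted outcome
#'
#' Fits the node model (least squares of the outcome on intercept,
#' `w_pre`, `w_post`), tests its per-observation scores for instability
#' along each partitioning variable, and — when the smallest
#' Bonferroni-adjusted p-value falls below `alpha` and depth allows —
#' splits on that variable at the objective-minimizing point
#' ([find_split()]), recursing into the children.  Nodes smaller than
#' `minsplit`, deeper than `maxdepth`, with no testable moderator, with no
#' admissible split, or with a rank-deficient design become terminal.
#'
#' @param table node data with `w_pre`, `w_post`, the outcome and the
#'   moderators.
#' @param partitioning_vars moderator column names.
#' @param control a [tree_control()].
#' @param outcome outcome column name.
#' @param depth,node_id recursion state (root is depth 1, id 1).
#' @return nested node list (`node_id`, `n_obs`, `split`, `children`,
#'   per-split `instability_pvalues`; growth-time OLS `coefficients`).
#' @export
grow_mob <- function(table, partitioning_vars, control,
                     outcome = "outcome", depth = 1L, node_id = 1L) {
  n <- nrow(table)
  node <- new_tree_node(node_id, n, depth)
  X <- cbind(`(Intercept)` = 1,
             w_pre = table$w_pre, w_post = table$w_post)
  if (qr(X)$rank < ncol(X)) {
    warning("node ", node_id, " design is rank deficient; forcing terminal")
    node$coefficients <- c(intercept = mean(table[[outcome]]),
                           w_pre = 0, w_post = 0)
    return(node)
  }
  nm <- node_model_scores(X, table[[outcome]])
  node$coefficients <- stats::setNames(nm$coef,
                                       c("intercept", "w_pre", "w_post"))

  if (n < control$minsplit || depth >= control$maxdepth) return(node)

  testable <- partitioning_vars[vapply(partitioning_vars, function(v) {
    length(unique(table[[v]][!is.na(table[[v]])])) >= 2
  }, logical(1))]
  if (!length(testable)) return(node)

  cluster <- if ("user_id" %in% names(table)) table$user_id else NULL
  pvals <- vapply(testable, function(v) {
    instability_test(nm$scores, table[[v]], trim = control$trim,
                     cluster = cluster)$p_value
  }, numeric(1))
  adj <- if (control$bonferroni) pmin(pvals * length(testable), 1) else pvals
  node$instability_pvalues <- adj

  if (min(adj) >= control$alpha) return(node)
  best_var <- testable[which.min(adj)]
  sp <- find_split(table, best_var, control$minsplit, outcome = outcome)
  if (!sp$admissible) return(node)

  left_idx <- if (sp$type == "numeric") {
    table[[best_var]] <= sp$split_point
  } else {
    table[[best_var]] %in% sp$split_point
  }
  node$split <- sp[c("variable", "type", "split_point", "objective")]
  node$children <- list(
    grow_mob(table[left_idx, , drop = FALSE], partitioning_vars, control,
             outcome, depth + 1L, 2L * node_id),
    grow_mob(table[!left_idx, , drop = FALSE], partitioning_vars, control,
             outcome, depth + 1L, 2L * node_id + 1L)
  )
  node
}

route_rows <- function(node, table) {
  if (is.null(node$children)) {
    return(rep(node$node_id, nrow(table)))
  }
  sp <- node$split
  left <- if (sp$type == "numeric") {
    table[[sp$variable]] <= sp$split_point
  } else {
    table[[sp$variable]] %in% unlist(sp$split_point)
  }
  out <- integer(nrow(table))
  if (any(left)) {
    out[left] <- route_rows(node$children[[1]], table[left, , drop = FALSE])
  }
  if (any(!left)) {
    out[!left] <- route_rows(node$children[[2]], table[!left, , drop = FALSE])
  }
  out
}

collect_leaves <- function(node) {
  if (is.null(node$children)) return(list(node))
  c(collect_leaves(node$children[[1]]), collect_leaves(node$children[[2]]))
}

tree_depth <- function(node) {
  if (is.null(node$children)) return(1L)
  1L + max(tree_depth(node$children[[1]]), tree_depth(node$children[[2]]))
}

set_leaf_coefs <- function(node, coefs, ses, pvals) {
  if (is.null(node$children)) {
    id <- as.character(node$node_id)
    node$coefficients <- coefs[[id]]
    node$se <- ses[[id]]
    node$coef_pvalues <- pvals[[id]]
    return(node)
  }
  node$children[[1]] <- set_leaf_coefs(node$children[[1]], coefs, ses, pvals)
  node$children[[2]] <- set_leaf_coefs(node$children[[2]], coefs, ses, pvals)
  node
}

#' Fit a piecewise linear mixed-model tree
#'
#' The core estimation routine: alternates between (a) growing a
#' model-based recursive partition ([grow_mob()]) on the outcome adjusted
#' for the current predicted random effects, and (b) fitting the joint
#' linear mixed model whose fixed effects are terminal-node-specific
#' piecewise trajectories — `outcome ~ 0 + node + node:w_pre +
#' node:w_post` — with a global user-level random intercept and random
#' slope on `w_pre`.  Random-effect predictions start at zero and the
#' alternation stops when the joint log-likelihood changes by less than
#' `tol` (or at `max_iter`, reported as non-convergence, not an error).
#' Terminal-node coefficients, standard errors and (naive Wald) p-values
#' come from the final joint fit.
#'
#' @param table long-format data with `user_id`, `week`, the outcome and
#'   the moderators; `w_pre`/`w_post` are derived from `breakpoint_week`
#'   if absent.
#' @param partitioning_vars moderator columns; each must be constant
#'   within user, and categorical ones binary.
#' @param control a [tree_control()].
#' @param breakpoint_week breakpoint used for the piecewise basis
#'   (default: the table's `"breakpoint_week"` attribute, else 3).
#' @param outcome outcome column name.
#' @return an object of class `lmm_tree_fit`: `tree` (root node), `lmm`
#'   (joint `lmm_fit`), `leaf_ids`, `n_alternations`, `loglik_trace`,
#'   `converged`, `aic`, plus metadata for prediction.
#' @export
fit_lmm_tree <- function(table, partitioning_vars = c("age", "gender", "bmi"),
                         control = tree_control(), breakpoint_week = NULL,
                         outcome = "outcome") {
  if (is.null(breakpoint_week)) {
    breakpoint_week <- attr(table, "breakpoint_week")
    if (is.null(breakpoint_week)) breakpoint_week <- 3
  }
  missing_cols <- setdiff(c("user_id", "week", outcome, partitioning_vars),
                          names(table))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  table <- add_piecewise_basis(table, breakpoint_week)
  table <- table[!is.na(table[[outcome]]), , drop = FALSE]

  for (v in partitioning_vars) {
    per_user <- tapply(table[[v]], table$user_id,
                       function(x) length(unique(x)))
    if (any(per_user > 1)) {
      stop("invalid-moderator error: '", v,
           "' varies within user", call. = FALSE)
    }
    if ((is.factor(table[[v]]) || is.character(table[[v]])) &&
        length(unique(stats::na.omit(table[[v]]))) > 2) {
      stop("unsupported-moderator error: categorical moderators must be binary",
           call. = FALSE)
    }
  }

  y <- table[[outcome]]
  re_offset <- rep(0, nrow(table))
  ll_prev <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  theta <- NULL
  tree <- NULL
  joint <- NULL
  iter <- 0L

  while (iter < control$max_iter) {
    iter <- iter + 1L
    table$.ystar <- y - re_offset
    tree <- grow_mob(table, partitioning_vars, control, outcome = ".ystar")
    leaf <- route_rows(tree, table)
    table$.node <- factor(leaf)
    fixed <- if (nlevels(table$.node) == 1) {
      stats::as.formula(paste(outcome, "~ w_pre + w_post"))
    } else {
      stats::as.formula(paste(outcome,
                              "~ 0 + .node + .node:w_pre + .node:w_post"))
    }
    joint <- fit_lmm(table, fixed, random_slope_on = "w_pre",
                     method = control$method, start = theta)
    theta <- joint$theta
    idx <- match(as.character(table$user_id), joint$blups$user_id)
    re_offset <- joint$blups$b_intercept[idx] +
      joint$blups$b_slope[idx] * table$w_pre
    re_offset[is.na(re_offset)] <- 0
    ll_trace <- c(ll_trace, joint$loglik)
    if (abs(joint$loglik - ll_prev) < control$tol) {
      converged <- TRUE
      break
    }
    ll_prev <- joint$loglik
  }

  leaf_ids <- sort(unique(route_rows(tree, table)))
  coefs <- ses <- pvs <- list()
  pname <- function(term, lid) {
    if (nlevels(table$.node) == 1) term else {
      if (term == "(Intercept)") paste0(".node", lid) else {
        paste0(".node", lid, ":", term)
      }
    }
  }
  for (lid in leaf_ids) {
    nm <- c(pname("(Intercept)", lid), pname("w_pre", lid),
            pname("w_post", lid))
    b <- joint$beta[nm]
    s <- joint$se[match(nm, names(joint$beta))]
    coefs[[as.character(lid)]] <- stats::setNames(
      unname(b), c("intercept", "w_pre", "w_post"))
    ses[[as.character(lid)]] <- stats::setNames(
      unname(s), c("intercept", "w_pre", "w_post"))
    pvs[[as.character(lid)]] <- stats::setNames(
      2 * stats::pnorm(-abs(unname(b) / unname(s))),
      c("intercept", "w_pre", "w_post"))
  }
  tree <- set_leaf_coefs(tree, coefs, ses, pvs)

  structure(list(
    tree = tree, lmm = joint, leaf_ids = leaf_ids,
    n_alternations = iter, loglik_trace = ll_trace, converged = converged,
    loglik = joint$loglik, aic = joint$aic,
    breakpoint_week = breakpoint_week,
    partitioning_vars = partitioning_vars, control = control,
    outcome = outcome
  ), class = "lmm_tree_fit")
}

#' Predict from a fitted LMM tree
#'
#' Routes each row to its terminal node via the split rules, evaluates the
#' node's piecewise fixed effects, and optionally adds the global
#' random-effect prediction for users seen during training (unseen users
#' get zero, the population-level prediction).
#'
#' @param fit an `lmm_tree_fit`.
#' @param newdata data.frame with the moderators and `week` (plus
#'   `user_id` when `include_random = TRUE`).
#' @param include_random add per-user BLUP contributions?
#' @return numeric vector of predictions.
#' @export
predict_tree <- function(fit, newdata, include_random = FALSE) {
  used <- tree_split_vars(fit$tree)
  missing_cols <- setdiff(c(used, "week"), names(newdata))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  newdata <- add_piecewise_basis(newdata, fit$breakpoint_week)
  leaf <- route_rows(fit$tree, newdata)
  leaves <- collect_leaves(fit$tree)
  coef_tab <- do.call(rbind, lapply(leaves, function(l) l$coefficients))
  rownames(coef_tab) <- vapply(leaves, function(l) as.character(l$node_id),
                               character(1))
  cc <- coef_tab[as.character(leaf), , drop = FALSE]
  pred <- cc[, "intercept"] + cc[, "w_pre"] * newdata$w_pre +
    cc[, "w_post"] * newdata$w_post
  if (include_random) {
    if (!"user_id" %in% names(newdata)) {
      stop("schema error: missing column(s): user_id", call. = FALSE)
    }
    blups <- fit$lmm$blups
    idx <- match(as.character(newdata$user_id), blups$user_id)
    b0 <- ifelse(is.na(idx), 0, blups$b_intercept[idx])
    b1 <- ifelse(is.na(idx), 0, blups$b_slope[idx])
    pred <- pred + b0 + b1 * newdata$w_pre
  }
  unname(pred)
}

tree_split_vars <- function(node) {
  if (is.null(node$children)) return(character(0))
  unique(c(node$split$variable,
           tree_split_vars(node$children[[1]]),
           tree_split_vars(node$children[[2]])))
}

split_label <- function(sp, side) {
  if (sp$type == "numeric") {
    sprintf("%s %s %.3g", sp$variable, if (side == 1) "<=" else ">",
            sp$split_point)
  } else {
    lv <- unlist(sp$split_point)
    sprintf("%s %s %s", sp$variable, if (side == 1) "in" else "not in",
            paste(lv, collapse = ","))
  }
}

print_node <- function(node, indent = "") {
  if (is.null(node$children)) {
    co <- node$coefficients
    cat(sprintf("%s[%d] n=%d  intercept=%.3f w_pre=%.3f w_post=%.3f\n",
                indent, node$node_id, node$n_obs,
                co["intercept"], co["w_pre"], co["w_post"]))
  } else {
    cat(sprintf("%s[%d] n=%d  split: %s (min adj. p=%.3g)\n",
                indent, node$node_id, node$n_obs,
                split_label(node$split, 1),
                min(node$instability_pvalues)))
    for (side in 1:2) {
      cat(sprintf("%s  %s\n", indent, split_label(node$split, side)))
      print_node(node$children[[side]], paste0(indent, "    "))
    }
  }
}

#' @export
print.lmm_tree_fit <- function(x, ...) {
  cat("Piecewise linear mixed-model tree (breakpoint week",
      x$breakpoint_week, ")\n")
  cat("  terminal nodes:", length(x$leaf_ids),
      " alternations:", x$n_alternations,
      " converged:", x$converged, "\n")
  cat("  logLik:", format(x$loglik), " AIC:", format(x$aic), "\n\n")
  print_node(x$tree)
  invisible(x)
}

node_to_list <- function(node) {
  out <- node[c("node_id", "n_obs", "depth")]
  if (!is.null(node$split)) out$split <- node$split
  if (!is.null(node$instability_pvalues)) {
    out$instability_pvalues <- as.list(node$instability_pvalues)
  }
  if (is.null(node$children)) {
    out$coefficients <- as.list(node$coefficients)
    if (!is.null(node$se)) out$se <- as.list(node$se)
    if (!is.null(node$coef_pvalues)) {
      out$coef_pvalues <- as.list(node$coef_pvalues)
    }
  } else {
    out$children <- list(node_to_list(node$children[[1]]),
                         node_to_list(node$children[[2]]))
  }
  out
}

list_to_node <- function(lst) {
  node <- new_tree_node(lst$node_id, lst$n_obs, lst$depth)
  if (!is.null(lst$split)) node$split <- lst$split
  if (!is.null(lst$instability_pvalues)) {
    node$instability_pvalues <- unlist(lst$instability_pvalues)
  }
  if (!is.null(lst$children)) {
    node$children <- list(list_to_node(lst$children[[1]]),
                          list_to_node(lst$children[[2]]))
  } else {
    node$coefficients <- unlist(lst$coefficients)
    node$se <- unlist(lst$se)
    node$coef_pvalues <- unlist(lst$coef_pvalues)
  }
  node
}

#' Serialize / restore a fitted LMM tree as JSON
#'
#' Nested node structure (split rules, terminal coefficients with SEs and
#' p-values, adjusted instability p-values, node sizes) plus variance
#' components, BLUPs and fit metadata.  The restored object supports
#' [predict_tree()].
#'
#' @param fit an `lmm_tree_fit`.
#' @param path file path.
#' @return `tree_from_json` returns an `lmm_tree_fit`; `tree_to_json`
#'   returns `path` invisibly.
#' @export
tree_to_json <- function(fit, path) {
  obj <- list(
    tree = node_to_list(fit$tree),
    varcomp = unclass(fit$lmm$varcomp),
    blups = fit$lmm$blups,
    loglik = fit$loglik, aic = fit$aic,
    n_alternations = fit$n_alternations,
    loglik_trace = fit$loglik_trace,
    converged = fit$converged,
    breakpoint_week = fit$breakpoint_week,
    partitioning_vars = fit$partitioning_vars,
    outcome = fit$outcome
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname tree_to_json
#' @export
tree_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  tree <- list_to_node(obj$tree)
  blups <- as.data.frame(do.call(rbind, lapply(obj$blups, function(r) r)))
  blups <- data.frame(user_id = vapply(obj$blups, `[[`, "", "user_id"),
                      b_intercept = vapply(obj$blups, `[[`, 0, "b_intercept"),
                      b_slope = vapply(obj$blups, `[[`, 0, "b_slope"),
                      stringsAsFactors = FALSE)
  lmm <- list(varcomp = do.call(variance_components, obj$varcomp),
              blups = blups, loglik = obj$loglik, aic = obj$aic)
  leaves <- collect_leaves(tree)
  structure(list(
    tree = tree, lmm = lmm,
    leaf_ids = sort(vapply(leaves, `[[`, 1L, "node_id")),
    n_alternations = obj$n_alternations,
    loglik_trace = obj$loglik_trace, converged = obj$converged,
    loglik = obj$loglik, aic = obj$aic,
    breakpoint_week = obj$breakpoint_week,
    partitioning_vars = obj$partitioning_vars, outcome = obj$outcome
  ), class = "lmm_tree_fit")
}
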