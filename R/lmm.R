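#' Fit a linear mixed model with user-level random intercept and slope
#'
#' Fits the Gaussian mixed model defined by an arbitrary fixed-effect
#' formula together with a user-level random intercept and, optionally, a
#' random slope on one column (by default `w_pre`, the first piecewise
#' segment), i.e. the `(1 + w_pre | user_id)` structure.  The
#' random-effects covariance is unstructured (free correlation).
#' Estimation is by maximum likelihood by default so that AIC values are
#' comparable across fixed-effect structures; REML is available for
#' variance-component reporting.
#'
#' If the outcome is an exact linear function of the fixed design (zero
#' residual variance), the likelihood surface is degenerate; the fit then
#' collapses to the ordinary least-squares solution with all variance
#' components reported as zero.
#'
#' @param table long-format data.frame containing the outcome, design and
#'   `user_id` columns.
#' @param fixed one-sided or two-sided formula for the fixed effects, e.g.
#'   `outcome ~ w_pre + w_post`.
#' @param random_slope_on column name carrying the random slope, or
#'   `"none"` for a random intercept only.
#' @param method `"ml"` (default) or `"reml"`.
#' @param group column identifying users (default `"user_id"`).
#' @param start optional `theta` start values passed to the optimizer
#'   (speeds up refits with an unchanged random structure).
#' @return an object of class `lmm_fit` with elements `beta`, `se`,
#'   `varcomp` ([variance_components()]), `blups` (per-user intercept and
#'   slope deviations), `loglik`, `aic`, `n_obs`, `n_params`, `converged`,
#'   plus the terms and factor levels needed for prediction.
#' @export
fit_lmm <- function(table, fixed, random_slope_on = "w_pre",
                    method = c("ml", "reml"), group = "user_id",
                    start = NULL) {
  method <- match.arg(method)
  vars <- all.vars(fixed)
  missing_cols <- setdiff(c(vars, group), names(table))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  use <- stats::complete.cases(table[, vars, drop = FALSE])
  dat <- table[use, , drop = FALSE]
  mf <- stats::model.frame(fixed, dat, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  ids <- dat[[group]]
  if (length(unique(ids)) < 2) {
    stop("degenerate-grouping error: at least 2 users are required",
         call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular-design error: collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  xlev <- stats::.getXlevels(attr(mf, "terms"), mf)
  has_slope <- !identical(random_slope_on, "none")

  # degenerate noiseless path: exact linear dependence on the fixed design
  ols <- stats::lm.fit(X, y)
  rss <- sum(ols$residuals^2)
  if (rss / length(y) < 1e-16) {
    beta <- ols$coefficients
    p <- length(beta)
    npar <- p + 1 + if (has_slope) 3 else 1
    blups <- unique_blup_frame(unique(ids))
    fit <- list(beta = beta, se = rep(0, p),
                varcomp = variance_components(0, 0, 0, 0),
                blups = blups, loglik = Inf, aic = -Inf,
                n_obs = length(y), n_params = npar, converged = TRUE,
                method = method, fixed = fixed,
                terms = stats::delete.response(attr(mf, "terms")),
                xlev = xlev, group = group,
                random_slope_on = random_slope_on, degenerate = TRUE,
                theta = NULL)
    class(fit) <- "lmm_fit"
    return(fit)
  }

  re_term <- if (has_slope) {
    sprintf("(1 + %s | %s)", random_slope_on, group)
  } else {
    sprintf("(1 | %s)", group)
  }
  full_formula <- stats::as.formula(
    paste(deparse(fixed[[2]]), "~",
          paste(deparse(fixed[[3]], width.cutoff = 500), collapse = ""),
          "+", re_term)
  )
  environment(full_formula) <- environment()

  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  warn <- character(0)
  fit_once <- function(control, st) {
    withCallingHandlers(
      lme4::lmer(full_formula, data = dat, REML = (method == "reml"),
                 control = control, start = st),
      warning = function(w) {
        warn <<- c(warn, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
  }
  mod <- fit_once(ctrl, start)
  conv_ok <- function(m) {
    isTRUE(m@optinfo$conv$opt == 0) &&
      length(m@optinfo$conv$lme4$messages) == 0
  }
  if (!conv_ok(mod)) {
    # one derivative-free restart before reporting non-convergence
    ctrl2 <- lme4::lmerControl(optimizer = "Nelder_Mead",
                               calc.derivs = FALSE,
                               check.conv.singular = "ignore")
    mod2 <- tryCatch(fit_once(ctrl2, NULL), error = function(e) NULL)
    if (!is.null(mod2) && conv_ok(mod2)) mod <- mod2
  }

  beta <- lme4::fixef(mod)
  se <- sqrt(diag(as.matrix(stats::vcov(mod))))
  vc <- lme4::VarCorr(mod)[[group]]
  sd_int <- sqrt(vc[1, 1])
  if (has_slope) {
    sd_slope <- sqrt(vc[2, 2])
    corr <- if (sd_int > 0 && sd_slope > 0) {
      vc[1, 2] / (sd_int * sd_slope)
    } else 0
  } else {
    sd_slope <- 0
    corr <- 0
  }
  varcomp <- variance_components(sd_int, sd_slope,
                                 max(-1, min(1, corr)),
                                 stats::sigma(mod))

  re <- lme4::ranef(mod)[[group]]
  blups <- data.frame(user_id = rownames(re),
                      b_intercept = re[[1]],
                      b_slope = if (has_slope) re[[2]] else 0,
                      stringsAsFactors = FALSE)

  ll <- as.numeric(stats::logLik(mod))
  npar <- attr(stats::logLik(mod), "df")
  fit <- list(beta = beta, se = se, varcomp = varcomp, blups = blups,
              loglik = ll, aic = -2 * ll + 2 * npar,
              n_obs = stats::nobs(mod), n_params = npar,
              converged = conv_ok(mod), warnings = warn,
              method = method, fixed = fixed,
              terms = stats::delete.response(attr(mf, "terms")),
              xlev = xlev, group = group,
              random_slope_on = random_slope_on, degenerate = FALSE,
              theta = lme4::getME(mod, "theta"))
  class(fit) <- "lmm_fit"
  fit
}

unique_blup_frame <- function(ids) {
  data.frame(user_id = as.character(ids), b_intercept = 0, b_slope = 0,
             stringsAsFactors = FALSE)
}

#' Predict from a fitted linear mixed model
#'
#' Fixed-effect predictions `X beta`, optionally adding each user's
#' predicted random intercept and slope (BLUPs).  Users absent from the
#' training data contribute zero random effect (the population-level
#' prediction), which is the convention used for test-set RMSE.
#'
#' @param fit an `lmm_fit`.
#' @param table data.frame with the design and grouping columns.
#' @param include_random add the per-user BLUP contribution?
#' @return numeric vector of predictions, one per row of `table`.
#' @export
predict_lmm <- function(fit, table, include_random = FALSE) {
  needed <- all.vars(fit$terms)
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- stats::model.matrix(fit$terms, table, xlev = fit$xlev)
  pred <- drop(X %*% fit$beta[colnames(X)])
  if (include_random) {
    idx <- match(as.character(table[[fit$group]]), fit$blups$user_id)
    b0 <- ifelse(is.na(idx), 0, fit$blups$b_intercept[idx])
    b1 <- ifelse(is.na(idx), 0, fit$blups$b_slope[idx])
    z <- if (identical(fit$random_slope_on, "none")) 0 else {
      table[[fit$random_slope_on]]
    }
    pred <- pred + b0 + b1 * z
  }
  unname(pred)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model (", toupper(x$method), ")\n", sep = "")
  cat("  observations:", x$n_obs, " parameters:", x$n_params, "\n")
  cat("  logLik:", format(x$loglik), " AIC:", format(x$aic), "\n")
  cat("  converged:", x$converged, "\n\nFixed effects:\n")
  print(data.frame(estimate = x$beta, se = x$se))
  cat("\nRandom effects (user level):\n")
  v <- x$varcomp
  cat(sprintf("  sd(intercept) = %.4g  sd(slope) = %.4g  corr = %.3f  sd(resid) = %.4g\n",
              v$sd_intercept, v$sd_slope_pre, v$corr_int_slope,
              v$sd_residual))
  invisible(x)
}

#' Serialize / restore a fitted LMM as JSON
#'
#' Stores coefficients, standard errors, variance components, per-user
#' BLUPs and convergence metadata in plain JSON.  The restored object
#' predicts but does not carry the original model frame.
#'
#' @param fit an `lmm_fit`.
#' @param path file path.
#' @return `lmm_from_json` returns an `lmm_fit`; `lmm_to_json` returns
#'   `path` invisibly.
#' @export
lmm_to_json <- function(fit, path) {
  obj <- list(
    beta = as.list(fit$beta), se = as.list(stats::setNames(fit$se, names(fit$beta))),
    varcomp = unclass(fit$varcomp), blups = fit$blups,
    loglik = fit$loglik, aic = fit$aic, n_obs = fit$n_obs,
    n_params = fit$n_params, converged = fit$converged,
    method = fit$method, fixed = deparse(fit$fixed),
    random_slope_on = fit$random_slope_on, group = fit$group
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname lmm_to_json
#' @export
lmm_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fixed <- stats::as.formula(paste(obj$fixed, collapse = ""))
  mf_terms <- stats::delete.response(stats::terms(fixed))
  fit <- list(
    beta = unlist(obj$beta), se = unlist(obj$se),
    varcomp = do.call(variance_components, obj$varcomp),
    blups = as.data.frame(obj$blups), loglik = obj$loglik, aic = obj$aic,
    n_obs = obj$n_obs, n_params = obj$n_params, converged = obj$converged,
    method = obj$method, fixed = fixed, terms = mf_terms,
    xlev = list(), group = obj$group,
    random_slope_on = obj$random_slope_on, degenerate = FALSE, theta = NULL
  )
  class(fit) <- "lmm_fit"
  fit
}
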