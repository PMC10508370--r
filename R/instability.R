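# Score-based parameter-instability tests used by the model-based
# recursive partitioning step.  The node model is least squares of the
# (random-effect-adjusted) outcome on (1, w_pre, w_post); its estimating
# equations contribute one k-vector score per observation,
# U_i = x_i * r_i, which sum to zero at the estimate.  Parameter
# instability along a moderator z shows up as systematic drift in the
# cumulative sum of scores ordered by z.

.supLM_cache <- new.env(parent = emptyenv())

#' Null distribution of the trimmed sup-LM statistic
#'
#' The limiting process of the standardized cumulative score sum is a
#' k-dimensional Brownian bridge; the sup-LM statistic is the supremum of
#' its squared norm scaled by t(1-t) over the trimmed interval.  The null
#' distribution has no convenient closed form, so it is simulated once per
#' (k, trim) pair on a fine grid and cached for the session.  A fixed
#' internal seed makes p-values reproducible; the caller's RNG state is
#' untouched.
#'
#' @param k number of model parameters (score dimension).
#' @param trim trimming fraction at each end of the ordering.
#' @param nrep,ngrid Monte-Carlo replicates and grid resolution.
#' @return sorted numeric vector of simulated null statistics.
#' @keywords internal
supLM_null <- function(k, trim = 0.1, nrep = 20000L, ngrid = 1000L) {
  key <- sprintf("k%d_t%0.3f", k, trim)
  if (!is.null(.supLM_cache[[key]])) return(.supLM_cache[[key]])
  stats_null <- withr::with_seed(271828L + k, {
    tt <- seq_len(ngrid) / ngrid
    lo <- which(tt >= trim)[1]
    hi <- max(which(tt <= 1 - trim))
    denom <- tt[lo:hi] * (1 - tt[lo:hi])
    vapply(seq_len(nrep), function(r) {
      z <- matrix(stats::rnorm(ngrid * k), ngrid, k)
      cs <- apply(z, 2, cumsum) / sqrt(ngrid)
      bridge <- cs - tcrossprod(tt, cs[ngrid, ])
      max(rowSums(bridge[lo:hi, , drop = FALSE]^2) / denom)
    }, numeric(1))
  })
  .supLM_cache[[key]] <- sort(stats_null)
  .supLM_cache[[key]]
}

#' Test parameter stability of node-model scores along a moderator
#'
#' For a numeric moderator, observations are ordered by `z` and the
#' statistic is the supremum, over candidate cut fractions t in
#' `[trim, 1 - trim]` (evaluated only at boundaries between distinct `z`
#' values), of `||W(t)||^2 / (t (1 - t))` where `W` is the cumulative sum
#' of the decorrelated scores scaled by `1/sqrt(n)`.  The p-value comes
#' from the simulated Brownian-bridge null distribution.
#'
#' For a categorical moderator the statistic aggregates the within-category
#' score sums, `sum_c ||Delta W_c||^2 / (n_c / n)`, which is asymptotically
#' chi-square with `k * (C - 1)` degrees of freedom because the category
#' sums are constrained to total zero.
#'
#' Because the moderators are user-level and repeated measures within a
#' user stay dependent even after adjusting for predicted random effects,
#' the test can (and, inside the tree, does) aggregate scores within
#' clusters before forming the cumulative process: pass `cluster` to sum
#' each user's score contributions into a single row, which makes the
#' score covariance estimate cluster-robust.
#'
#' @param scores n x k matrix of per-observation score contributions
#'   (columns sum to ~0 at the node estimate).
#' @param z moderator vector, numeric or factor, length n.
#' @param trim trimming fraction for the numeric sup-LM (default 0.1).
#' @param cluster optional cluster id vector of length n; `z` must be
#'   constant within cluster.
#' @return list with `statistic`, `p_value`, and `type`
#'   (`"supLM"` or `"chisq"`).  Fewer than 2 distinct `z` values gives
#'   `p_value = 1` (untestable).
#' @export
instability_test <- function(scores, z, trim = 0.1, cluster = NULL) {
  scores <- as.matrix(scores)
  if (length(z) != nrow(scores)) {
    stop("schema error: 'z' must match the score rows", call. = FALSE)
  }
  if (!is.null(cluster)) {
    if (length(cluster) != nrow(scores)) {
      stop("schema error: 'cluster' must match the score rows",
           call. = FALSE)
    }
    cl <- as.character(cluster)
    if (any(tapply(z, cl, function(v) length(unique(v))) > 1)) {
      stop("invalid-moderator error: 'z' varies within cluster",
           call. = FALSE)
    }
    first <- !duplicated(cl)
    zc <- z[first]
    names(zc) <- cl[first]
    scores <- rowsum(scores, cl)
    z <- zc[rownames(scores)]
  }
  n <- nrow(scores)
  if (length(unique(z[!is.na(z)])) < 2) {
    return(list(statistic = 0, p_value = 1, type = "untestable"))
  }
  k <- ncol(scores)
  J <- crossprod(scores) / n
  R <- tryCatch(chol(J), error = function(e) NULL)
  if (is.null(R)) {
    # numerically singular score covariance: treat as untestable
    return(list(statistic = 0, p_value = 1, type = "untestable"))
  }
  S <- scores %*% backsolve(R, diag(k))  # decorrelated scores

  if (is.factor(z) || is.character(z)) {
    zf <- droplevels(factor(z))
    sums <- rowsum(S, zf) / sqrt(n)
    prop <- as.numeric(table(zf)) / n
    stat <- sum(rowSums(sums^2) / prop)
    df <- k * (nlevels(zf) - 1)
    list(statistic = stat, p_value = stats::pchisq(stat, df, lower.tail = FALSE),
         type = "chisq")
  } else {
    ord <- order(z)
    W <- apply(S[ord, , drop = FALSE], 2, cumsum) / sqrt(n)
    zo <- z[ord]
    # evaluate only where the moderator actually changes value
    boundary <- which(zo[-n] < zo[-1])
    tt <- boundary / n
    ok <- tt >= trim & tt <= 1 - trim
    if (!any(ok)) {
      return(list(statistic = 0, p_value = 1, type = "untestable"))
    }
    idx <- boundary[ok]
    stat <- max(rowSums(W[idx, , drop = FALSE]^2) /
                  (tt[ok] * (1 - tt[ok])))
    null_dist <- supLM_null(k, trim)
    p <- (sum(null_dist >= stat) + 1) / (length(null_dist) + 1)
    list(statistic = stat, p_value = p, type = "supLM")
  }
}
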