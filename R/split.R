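#' Exhaustive split-point search for one moderator
#'
#' Scans candidate binary splits of a node on one moderator and returns
#' the split minimizing the summed residual sum of squares of the two
#' children's node models (least squares of the outcome on intercept,
#' `w_pre`, `w_post`).  Numeric moderators are scanned over midpoints of
#' adjacent observed unique values; a binary categorical moderator has the
#' single level-vs-level split.  Both children must contain at least
#' `minsplit` observations (rows); ties in the objective keep the smaller
#' threshold.
#'
#' @param table node data with `w_pre`, `w_post`, the outcome and the
#'   moderator.
#' @param variable moderator column name.
#' @param minsplit minimum observations required in each child.
#' @param outcome outcome column name (default `"outcome"`).
#' @param design_cols design columns of the node model.
#' @return list with `variable`, `type` (`"numeric"` or `"categorical"`),
#'   `split_point` (numeric threshold, or character vector of left-branch
#'   levels), `objective` (summed child RSS) and `admissible`.  When no
#'   split satisfies `minsplit`, `admissible` is `FALSE`.
#' @export
find_split <- function(table, variable, minsplit, outcome = "outcome",
                       design_cols = c("w_pre", "w_post")) {
  z <- table[[variable]]
  y <- table[[outcome]]
  X <- cbind(`(Intercept)` = 1, as.matrix(table[, design_cols, drop = FALSE]))
  if (is.factor(z) || is.character(z)) {
    find_split_categorical(X, y, z, minsplit, variable)
  } else {
    find_split_numeric(X, y, z, minsplit, variable)
  }
}

rss_from_stats <- function(Sxx, Sxy, Syy, X = NULL, y = NULL) {
  b <- tryCatch(solve(Sxx, Sxy), error = function(e) NULL)
  if (is.null(b)) {
    if (is.null(X)) return(NA_real_)
    return(sum(stats::lm.fit(X, y)$residuals^2))  # rank-deficient fallback
  }
  max(Syy - sum(b * Sxy), 0)
}

find_split_numeric <- function(X, y, z, minsplit, variable) {
  n <- length(y)
  ord <- order(z)
  Xo <- X[ord, , drop = FALSE]
  yo <- y[ord]
  zo <- z[ord]
  k <- ncol(X)

  # prefix sufficient statistics: RSS of any child is Syy - b'Sxy with
  # b = Sxx^{-1} Sxy, all obtainable from cumulative sums
  pair_idx <- expand.grid(i = seq_len(k), j = seq_len(k))
  P <- Xo[, pair_idx$i, drop = FALSE] * Xo[, pair_idx$j, drop = FALSE]
  cumP <- apply(P, 2, cumsum)
  cumXy <- apply(Xo * yo, 2, cumsum)
  cumYy <- cumsum(yo^2)

  boundaries <- which(zo[-n] < zo[-1])
  boundaries <- boundaries[boundaries >= minsplit &
                             (n - boundaries) >= minsplit]
  if (!length(boundaries)) {
    return(list(variable = variable, type = "numeric", split_point = NA_real_,
                objective = NA_real_, admissible = FALSE))
  }
  tot_P <- cumP[n, ]
  tot_Xy <- cumXy[n, ]
  tot_Yy <- cumYy[n]

  best_obj <- Inf
  best_i <- NA_integer_
  for (i in boundaries) {
    SxxL <- matrix(cumP[i, ], k, k)
    SxyL <- cumXy[i, ]
    rssL <- rss_from_stats(SxxL, SxyL, cumYy[i],
                           Xo[seq_len(i), , drop = FALSE], yo[seq_len(i)])
    SxxR <- matrix(tot_P - cumP[i, ], k, k)
    SxyR <- tot_Xy - cumXy[i, ]
    rssR <- rss_from_stats(SxxR, SxyR, tot_Yy - cumYy[i],
                           Xo[(i + 1):n, , drop = FALSE], yo[(i + 1):n])
    obj <- rssL + rssR
    # strict improvement beyond float noise keeps the smaller threshold
    # when two candidate splits tie in the objective
    if (is.finite(obj) && obj < best_obj - 1e-10 * max(1, abs(obj))) {
      best_obj <- obj
      best_i <- i
    }
  }
  if (!is.finite(best_obj)) {
    return(list(variable = variable, type = "numeric", split_point = NA_real_,
                objective = NA_real_, admissible = FALSE))
  }
  list(variable = variable, type = "numeric",
       split_point = (zo[best_i] + zo[best_i + 1]) / 2,
       objective = best_obj, admissible = TRUE)
}

find_split_categorical <- function(X, y, z, minsplit, variable) {
  zf <- droplevels(factor(z))
  if (nlevels(zf) != 2) {
    stop("unsupported-moderator error: categorical moderators must be binary",
         call. = FALSE)
  }
  left <- zf == levels(zf)[1]
  if (sum(left) < minsplit || sum(!left) < minsplit) {
    return(list(variable = variable, type = "categorical",
                split_point = NA_character_, objective = NA_real_,
                admissible = FALSE))
  }
  rss <- function(idx) sum(stats::lm.fit(X[idx, , drop = FALSE],
                                         y[idx])$residuals^2)
  list(variable = variable, type = "categorical",
       split_point = levels(zf)[1], objective = rss(left) + rss(!left),
       admissible = TRUE)
}
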