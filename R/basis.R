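#' Piecewise time basis for a two-segment weekly trajectory
#'
#' Encodes week indices as two joined linear covariates: `w_pre`, the weeks
#' elapsed before the breakpoint, and `w_post`, the weeks elapsed after it.
#' The time origin sits at week 1, so an intercept in a model using this
#' basis is the expected outcome at the first week.  With `t = week - 1` and
#' `c = breakpoint_week - 1`:
#' \deqn{w_{pre} = \min(t, c), \quad w_{post} = \max(t - c, 0)}
#' so that `w_pre + w_post = week - 1` and any coefficient pair implies a
#' trajectory continuous at the breakpoint.
#'
#' A breakpoint beyond the last observed week degenerates gracefully:
#' `w_post` is identically zero and the model collapses to a single linear
#' slope, which is how the single-slope comparator model is expressed.
#'
#' @param week integer vector of week indices, all `>= 1`.
#' @param breakpoint_week week at which the slope is allowed to change;
#'   must be `> 1`.
#' @return a data.frame with numeric columns `w_pre` and `w_post`, one row
#'   per input week.
#' @examples
#' piecewise_design(1:8, breakpoint_week = 3)
#' @export
piecewise_design <- function(week, breakpoint_week) {
  if (any(!is.finite(week)) || any(week < 1)) {
    stop("domain error: 'week' must be >= 1", call. = FALSE)
  }
  if (!is.finite(breakpoint_week) || breakpoint_week <= 1) {
    stop("domain error: 'breakpoint_week' must be > 1", call. = FALSE)
  }
  t <- week - 1
  c0 <- breakpoint_week - 1
  data.frame(w_pre = pmin(t, c0), w_post = pmax(t - c0, 0))
}

#' Append piecewise basis columns to a long table
#'
#' @param table data.frame with a `week` column.
#' @param breakpoint_week breakpoint week passed to [piecewise_design()].
#' @return `table` with `w_pre` and `w_post` columns added (overwritten if
#'   already present), and the breakpoint recorded in the
#'   `"breakpoint_week"` attribute.
#' @export
add_piecewise_basis <- function(table, breakpoint_week) {
  if (!"week" %in% names(table)) {
    stop("schema error: column 'week' is required", call. = FALSE)
  }
  basis <- piecewise_design(table$week, breakpoint_week)
  table$w_pre <- basis$w_pre
  table$w_post <- basis$w_post
  attr(table, "breakpoint_week") <- breakpoint_week
  table
}
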