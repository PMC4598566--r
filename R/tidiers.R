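# broom-style tidy()/glance() methods for the package's result objects.

#' Tidy a polarity summary
#'
#' @param x A `polarity_summary`.
#' @param ... Unused.
#' @return Per-group tibble: `condition`, `group_id`, `n_vectors`,
#'   `csd_deg`.
#' @export
tidy.polarity_summary <- function(x, ...) x$groups

#' Condition-level glance at a polarity summary
#'
#' @param x A `polarity_summary`.
#' @param ... Unused.
#' @return One row per condition with mean/sd CSD and, when two conditions
#'   were compared, the Mann–Whitney U and p-value.
#' @export
glance.polarity_summary <- function(x, ...) {
  out <- x$conditions
  if (!is.null(x$test)) {
    out$mw_U <- x$test$U
    out$mw_p_value <- x$test$p_value
  }
  out
}

#' Tidy a cilia time course
#'
#' @param x A `cilia_timecourse`.
#' @param ... Unused.
#' @return Tibble of per-condition/timepoint means and s.e.m.
#' @export
tidy.cilia_timecourse <- function(x, ...) x$points

#' Glance at a cilia time course
#'
#' @param x A `cilia_timecourse`.
#' @param ... Unused.
#' @return Tibble of Welch tests vs the control condition.
#' @export
glance.cilia_timecourse <- function(x, ...) x$tests

#' Tidy a flow summary
#'
#' @param x A `flow_summary`.
#' @param ... Unused.
#' @return Per-track velocity/tortuosity tibble.
#' @export
tidy.flow_summary <- function(x, ...) x$tracks

#' Glance at a flow summary
#'
#' @param x A `flow_summary`.
#' @param ... Unused.
#' @return Per-condition tibble with relative-to-control ratios.
#' @export
glance.flow_summary <- function(x, ...) x$conditions
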