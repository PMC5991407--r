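#' Cohort effectiveness rates
#'
#' Counts and rates of effective projects per indicator (and, when
#' present, per improvement type), optionally grouped. Rates are percent,
#' rounded half away from zero to 2 decimals at presentation; counts stay
#' exact.
#'
#' @param flags data.frame with the four `effective_*` columns (and
#'   optionally the seven type membership columns from
#'   [assign_types_cohort()]).
#' @param group_by optional name of a grouping column in `flags` (e.g.
#'   `period` or a province/group code); `NULL` pools everything.
#' @return data.frame with one row per group: `group`, `n_projects`, then
#'   `count_*` and `rate_*` per indicator/type column found.
#' @export
effectiveness_rates <- function(flags, group_by = NULL) {
  stat_cols <- intersect(c(paste0("effective_", c("pl", "pv", "pp", "mi")),
                           improvement_types()), names(flags))
  if (length(stat_cols) == 0) stop("no effectiveness/type columns found")
  groups <- if (is.null(group_by)) list(all = flags)
            else split(flags, flags[[group_by]])
  rows <- lapply(names(groups), function(gname) {
    g <- groups[[gname]]
    if (nrow(g) == 0) {
      message("group '", gname, "' is empty; omitted")
      return(NULL)
    }
    row <- data.frame(group = gname, n_projects = nrow(g))
    for (col in stat_cols) {
      cnt <- sum(g[[col]])
      row[[paste0("count_", col)]] <- cnt
      row[[paste0("rate_", col)]] <- round_half_up(100 * cnt / nrow(g), 2)
    }
    row
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Pool per-cohort rates into an overall rate
#'
#' Size-weighted mean of sub-cohort percentages, `sum(n_i r_i) / sum(n_i)`,
#' rounded half away from zero to 2 decimals — the arithmetic that turns
#' per-period effectiveness rates into the all-projects rate.
#'
#' @param counts integer cohort sizes.
#' @param rates percentages, same length.
#' @return pooled percentage (2 decimals).
#' @export
pooled_rate <- function(counts, rates) {
  if (length(counts) != length(rates)) stop("`counts` and `rates` lengths differ")
  if (sum(counts) == 0) stop("total count is zero")
  round_half_up(sum(counts * rates) / sum(counts), 2)
}

#' Difference between two rates, in percentage points
#'
#' @param later,former percentages in `[0, 100]`.
#' @return `later - former`, rounded to 2 decimals.
#' @export
rate_difference <- function(later, former) {
  round_half_up(later - former, 2)
}

#' Recover a project count from a cohort rate
#'
#' @param n cohort size.
#' @param rate percentage in `[0, 100]`.
#' @return integer count, `n * rate / 100` rounded half away from zero.
#' @export
count_from_rate <- function(n, rate) {
  as.integer(round_half_up(n * rate / 100, 0))
}

#' Published per-period effectiveness rates of the reference study
#'
#' The per-period effectiveness rates (percent) and cohort sizes reported
#' by the reference national evaluation: 4442 former projects (completed
#' 2006-2010, indicator-evaluated) and 3063 later projects (completed
#' 2011-2013, SVM-predicted). These are the inputs to the pooled-rate
#' arithmetic of [pooled_rate()] and [rate_difference()].
#'
#' @return data.frame with columns `period`, `n_projects`, `pl`, `pv`,
#'   `pp`, `mi`.
#' @export
study_cohort_rates <- function() {
  data.frame(period = c("former", "later"),
             n_projects = c(4442L, 3063L),
             pl = c(62.02, 88.18),
             pv = c(55.02, 66.41),
             pp = c(53.53, 81.55),
             mi = c(33.30, 3.59))
}
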