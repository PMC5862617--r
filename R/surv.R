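#' Split a survival table at the median expression value
#'
#' Dichotomizes subjects into high- and low-expression groups at the
#' median: `high` holds expression strictly above the median, `low`
#' holds expression at or below it, so ties at the median land
#' deterministically in `low`.
#'
#' @param tbl a survival table (see [as_survival_table()]).
#' @return Named list of two survival tables, `high` and `low`.
#' @export
median_split <- function(tbl) {
  tbl <- as_survival_table(as.data.frame(tbl))
  if (nrow(tbl) < 2) stop("need >= 2 subjects")
  med <- stats::median(tbl$expression)
  hi <- tbl$expression > med
  if (!any(hi)) stop("all expression values identical; no bifurcation possible")
  list(high = tbl[hi, , drop = FALSE], low = tbl[!hi, , drop = FALSE])
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-censored product-limit survival estimate, computed with
#' [survival::survfit()]. The curve starts at 1, is nonincreasing, and
#' steps only at observed event times.
#'
#' @param tbl a survival table.
#' @return Object of class `km_curve`: data frame with one row per
#'   distinct event time (`time`, `n_risk`, `n_event`, `survival`).
#'   A warning is raised (and the curve stays flat at 1) when no events
#'   are observed.
#' @export
km_estimate <- function(tbl) {
  tbl <- as_survival_table(as.data.frame(tbl))
  if (nrow(tbl) < 1) stop("empty survival table")
  if (!any(tbl$event)) warning("no events observed; survival curve is flat at 1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = tbl)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, survival = fit$surv)
  out <- out[out$n_event > 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("km_curve", class(out))
  out
}

#' Log-rank comparison of two survival groups
#'
#' Standard log-rank chi-square test (1 degree of freedom) between two
#' groups, via [survival::survdiff()].
#'
#' @param high,low survival tables for the two groups (e.g. from
#'   [median_split()]).
#' @return List with `chi_square` and `p_value`.
#' @export
logrank_test <- function(high, low) {
  high <- as_survival_table(as.data.frame(high))
  low <- as_survival_table(as.data.frame(low))
  if (nrow(high) == 0 || nrow(low) == 0) stop("both groups must be nonempty")
  df <- rbind(cbind(high, .grp = "high"), cbind(low, .grp = "low"))
  if (!any(df$event)) stop("no events observed; log-rank test undefined")
  sd <- survival::survdiff(survival::Surv(time, event) ~ .grp, data = df)
  chisq <- unname(sd$chisq)
  list(chi_square = chisq,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Median-split survival analysis of an expression biomarker
#'
#' Convenience wrapper: median expression split, per-group Kaplan-Meier
#' curves, and the log-rank test.
#'
#' @param tbl a survival table with an `expression` column.
#' @return List with `split` (the two tables), `km` (list of two
#'   `km_curve`s) and `logrank` (list with chi_square, p_value).
#' @export
survival_by_expression <- function(tbl) {
  sp <- median_split(tbl)
  list(split = sp,
       km = list(high = km_estimate(sp$high), low = km_estimate(sp$low)),
       logrank = logrank_test(sp$high, sp$low))
}
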