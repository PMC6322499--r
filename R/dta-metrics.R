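#' Two-by-two tables and diagnostic accuracy metrics
#'
#' Index-test calls are compared against the dual-adjudicated reference
#' standard by cross-tabulating into a confusion table, from which
#' sensitivity, specificity, PPV and NPV are estimated with exact
#' (Clopper-Pearson) binomial confidence intervals.
#'
#' @name dta_metrics
NULL

#' Build a confusion table from calls and reference labels
#'
#' @param calls data.frame with `record_id` and a logical `positive` column
#'   (binary matcher output), or a named logical vector.
#' @param truth data.frame with `record_id` and logical `truth` column, or a
#'   named logical vector.
#' @return object of class `confusion_table` with integer fields `tp`, `fp`,
#'   `fn`, `tn`. The four counts always partition the records.
#' @export
build_confusion <- function(calls, truth) {
  if (is.data.frame(calls)) {
    call_ids <- as.character(calls$record_id); call_pos <- as.logical(calls$positive)
  } else {
    call_ids <- names(calls); call_pos <- as.logical(calls)
  }
  if (is.data.frame(truth)) {
    truth_ids <- as.character(truth$record_id); truth_pos <- as.logical(truth$truth)
  } else {
    truth_ids <- names(truth); truth_pos <- as.logical(truth)
  }
  if (length(call_ids) == 0L || length(truth_ids) == 0L) {
    cm_alignment_error("calls and truth must be non-empty")
  }
  only_calls <- setdiff(call_ids, truth_ids)
  only_truth <- setdiff(truth_ids, call_ids)
  if (length(only_calls) || length(only_truth) ||
      anyDuplicated(call_ids) || anyDuplicated(truth_ids)) {
    cm_alignment_error(
      paste0("calls and truth do not align 1:1; ",
             length(only_calls), " call-only and ",
             length(only_truth), " truth-only record(s)"),
      ids = c(only_calls, only_truth))
  }
  y <- truth_pos[match(call_ids, truth_ids)]
  confusion_table(
    tp = sum(call_pos & y), fp = sum(call_pos & !y),
    fn = sum(!call_pos & y), tn = sum(!call_pos & !y))
}

#' @rdname build_confusion
#' @param tp,fp,fn,tn nonnegative integer counts (total must be positive).
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    cm_validation_error("confusion counts must be nonnegative integers")
  }
  if (sum(counts) == 0) cm_validation_error("confusion table is empty")
  structure(as.list(as.integer(counts)) |> setNames(names(counts)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("test +", "test -"), c("truth +", "truth -")))
  cat("<confusion_table> n =", x$tp + x$fp + x$fn + x$tn, "\n")
  print(m)
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The equal-tailed exact interval via beta quantiles; `x = 0` pins the lower
#' limit to 0 and `x = n` pins the upper limit to 1.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param alpha significance level (default 0.05 for a 95 percent interval).
#' @return numeric vector `c(low, high)`.
#' @export
clopper_pearson <- function(x, n, alpha = 0.05) {
  if (n <= 0 || x < 0 || x > n) cm_validation_error("need 0 <= x <= n, n > 0")
  low <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  high <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(low = low, high = high)
}

.metric_xn <- function(table, which) {
  switch(which,
    sensitivity = c(x = table$tp, n = table$tp + table$fn),
    specificity = c(x = table$tn, n = table$tn + table$fp),
    ppv         = c(x = table$tp, n = table$tp + table$fp),
    npv         = c(x = table$tn, n = table$tn + table$fn),
    cm_config_error(paste0("unknown metric: ", which))
  )
}

#' Diagnostic accuracy metric with exact confidence interval
#'
#' @param table a `confusion_table`.
#' @param which one of `"sensitivity"`, `"specificity"`, `"ppv"`, `"npv"`.
#' @param alpha significance level (default 0.05).
#' @return object of class `metric_estimate`: `metric`, `point`, `ci_low`,
#'   `ci_high` (all proportions), `x`, `n`, `alpha`.
#'
#'   A zero denominator (e.g. PPV of a test that never calls positive)
#'   raises a condition of class `carematch_undefined_metric`; such cells
#'   are conventionally printed as "-".
#' @export
dta_metric <- function(table, which = c("sensitivity", "specificity", "ppv", "npv"),
                       alpha = 0.05) {
  which <- match.arg(which)
  xn <- .metric_xn(table, which)
  if (xn["n"] == 0) {
    cm_stop(paste0(which, " is undefined: zero denominator"),
            "carematch_undefined_metric")
  }
  ci <- clopper_pearson(xn["x"], xn["n"], alpha)
  structure(
    list(metric = which, point = unname(xn["x"] / xn["n"]),
         ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
         x = unname(xn["x"]), n = unname(xn["n"]), alpha = alpha),
    class = "metric_estimate"
  )
}

#' @export
print.metric_estimate <- function(x, ...) {
  cat(sprintf("%s %s (%s-%s)  [%d/%d]\n", x$metric,
              pct1(x$point), pct1(x$ci_low), pct1(x$ci_high), x$x, x$n))
  invisible(x)
}

# 1-decimal-place percentage string, the table reporting convention
pct1 <- function(p) sprintf("%.1f%%", 100 * p)

#' All four metrics for a confusion table
#'
#' @inheritParams dta_metric
#' @return data.frame with one row per metric: point, exact CI, x, n.
#'   Undefined metrics (zero denominator) appear as `NA`.
#' @export
dta_metrics <- function(table, alpha = 0.05) {
  rows <- lapply(c("sensitivity", "specificity", "ppv", "npv"), function(w) {
    est <- tryCatch(dta_metric(table, w, alpha),
                    carematch_undefined_metric = function(e) NULL)
    if (is.null(est)) {
      data.frame(metric = w, point = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, x = NA_integer_, n = NA_integer_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(metric = w, point = est$point, ci_low = est$ci_low,
                 ci_high = est$ci_high, x = est$x, n = est$n,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Prevalence of reference-standard positives
#'
#' @param positives count of positive records.
#' @param total total record count (`> 0`).
#' @return proportion `positives / total`.
#' @export
prevalence <- function(positives, total) {
  if (total <= 0) cm_validation_error("total must be > 0")
  if (positives < 0 || positives > total) {
    cm_validation_error("need 0 <= positives <= total")
  }
  positives / total
}

#' Sample size for estimating sensitivity at a given precision
#'
#' Buderer-style formula for diagnostic sensitivity studies:
#' \deqn{n = \mathrm{round}\!\left(\frac{z_{1-\alpha/2}^2\, S(1-S)}
#'   {d^2\, \mathrm{prev}}\right)}
#' where `S` is the anticipated sensitivity, `d` the marginal error and
#' `prev` the anticipated prevalence (the factor that inflates the binomial
#' sample size because only prevalent cases inform sensitivity). Rounding is
#' to the nearest integer.
#'
#' @param S anticipated sensitivity, in (0, 1).
#' @param d marginal error, `> 0`.
#' @param prev anticipated prevalence, in (0, 1].
#' @param alpha significance level (default 0.05, so `z = 1.96`).
#' @return integer sample size.
#' @examples
#' sample_size_sensitivity(S = 0.85, d = 0.05, prev = 0.04)  # 4898
#' @export
sample_size_sensitivity <- function(S, d, prev, alpha = 0.05) {
  if (S <= 0 || S >= 1) cm_validation_error("S must be in (0, 1)")
  if (d <= 0) cm_validation_error("d must be > 0")
  if (prev <= 0 || prev > 1) cm_validation_error("prev must be in (0, 1]")
  z <- qnorm(1 - alpha / 2)
  as.integer(round(z^2 * S * (1 - S) / (d^2 * prev)))
}

#' Merge two independent adjudications into a consensus label set
#'
#' Agreeing records receive the common label; disagreements are returned
#' unresolved so they can be settled externally (by discussion) and fed back
#' through `resolutions`.
#'
#' @param labels_a,labels_b data.frames with `record_id` and logical `truth`
#'   columns covering the same records.
#' @param resolutions optional data.frame with `record_id` and `truth` for
#'   (a subset of) the disagreeing records.
#' @return list with `consensus` (data.frame `record_id`, `truth`; `NA`
#'   truth where still unresolved) and `disagreements` (character vector of
#'   record ids that disagreed, before resolution).
#' @export
merge_adjudications <- function(labels_a, labels_b, resolutions = NULL) {
  ids_a <- as.character(labels_a$record_id)
  ids_b <- as.character(labels_b$record_id)
  if (length(setdiff(ids_a, ids_b)) || length(setdiff(ids_b, ids_a)) ||
      anyDuplicated(ids_a) || anyDuplicated(ids_b)) {
    cm_alignment_error("adjudication sets must cover identical record ids",
                       ids = c(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a)))
  }
  a <- as.logical(labels_a$truth)
  b <- as.logical(labels_b$truth)[match(ids_a, ids_b)]
  agree <- a == b
  out <- data.frame(record_id = ids_a,
                    truth = ifelse(agree, a, NA), stringsAsFactors = FALSE)
  disagreements <- ids_a[!agree]
  if (!is.null(resolutions) && length(disagreements)) {
    i <- match(out$record_id, as.character(resolutions$record_id))
    use <- !is.na(i) & is.na(out$truth)
    out$truth[use] <- as.logical(resolutions$truth)[i[use]]
  }
  list(consensus = out, disagreements = disagreements)
}
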