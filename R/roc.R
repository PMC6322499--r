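#' ROC curves, AUROC and cut-off selection for the score methods
#'
#' A score method calls a record positive when its score is at or above a
#' threshold (`score >= t`, matching the "cut-off >= x" reporting
#' convention). The ROC curve evaluates every distinct observed score as a
#' threshold plus one sentinel above the maximum (the all-negative corner),
#' carrying the full confusion table at each threshold so that cut-off rules
#' can constrain on PPV as well as sensitivity/specificity.
#'
#' @name roc
NULL

.extract_scores_truth <- function(scores, truth) {
  if (is.data.frame(scores)) {
    ids <- as.character(scores$record_id); sc <- as.numeric(scores$score)
  } else {
    ids <- names(scores); sc <- as.numeric(scores)
  }
  if (is.data.frame(truth)) {
    tids <- as.character(truth$record_id); y <- as.logical(truth$truth)
    if (is.null(ids)) cm_alignment_error("scores must carry record ids")
    i <- match(ids, tids)
    if (anyNA(i) || length(setdiff(tids, ids))) {
      cm_alignment_error("scores and truth do not align 1:1",
                         ids = c(ids[is.na(i)], setdiff(tids, ids)))
    }
    y <- y[i]
  } else {
    y <- as.logical(truth)
    if (length(y) != length(sc)) {
      cm_alignment_error("scores and truth lengths differ")
    }
  }
  if (!any(y) || all(y)) {
    cm_validation_error("ROC analysis needs at least one positive and one negative")
  }
  list(score = sc, truth = y)
}

#' Compute the ROC curve over all observed thresholds
#'
#' @param scores data.frame with `record_id` and `score` (output of
#'   [score_phonics()] / [score_markov()]), or a plain numeric vector.
#' @param truth data.frame with `record_id` and logical `truth`, or a
#'   logical vector aligned with `scores`.
#' @return object of class `roc_curve`: a data.frame with one row per
#'   threshold (ascending; last row is the sentinel above the maximum) and
#'   columns `threshold`, `tp`, `fp`, `fn`, `tn`, `tpr`, `fpr`. `tpr` and
#'   `fpr` are non-increasing in the threshold; the curve always contains
#'   the (0,0) and (1,1) corners in (fpr, tpr) space.
#' @export
roc_curve <- function(scores, truth) {
  st <- .extract_scores_truth(scores, truth)
  s <- st$score; y <- st$truth
  npos <- sum(y); nneg <- sum(!y)
  thr <- sort(unique(s))
  thr <- c(thr, max(thr) + 1)  # sentinel above the maximum: all-negative corner
  # cumulative counts: predicted positive <=> score >= t
  tp <- vapply(thr, function(t) sum(y & s >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(!y & s >= t), numeric(1))
  out <- data.frame(threshold = thr, tp = tp, fp = fp,
                    fn = npos - tp, tn = nneg - fp,
                    tpr = tp / npos, fpr = fp / nneg)
  structure(out, class = c("roc_curve", "data.frame"))
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> ", nrow(x), " thresholds\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' AUROC with Wald confidence limits
#'
#' The area equals the probability that a random positive scores above a
#' random negative, ties counted one half (the Mann-Whitney statistic),
#' computed exactly via mid-ranks. The standard error is Hanley-McNeil by
#' default, or the DeLong empirical (placement-value) variance; the interval
#' is `auc +/- z * se`, clipped to `[0, 1]`.
#'
#' @inheritParams roc_curve
#' @param alpha significance level (default 0.05).
#' @param se_method `"hanley"` (default) or `"delong"`.
#' @return object of class `auroc_estimate`: `auc`, `se`, `ci_low`,
#'   `ci_high`, `n_pos`, `n_neg`, `se_method`.
#' @export
auroc <- function(scores, truth, alpha = 0.05,
                  se_method = c("hanley", "delong")) {
  se_method <- match.arg(se_method)
  st <- .extract_scores_truth(scores, truth)
  s <- st$score; y <- st$truth
  npos <- sum(y); nneg <- sum(!y)
  r <- rank(s)  # mid-ranks handle ties as 1/2
  auc <- (sum(r[y]) - npos * (npos + 1) / 2) / (npos * nneg)
  if (se_method == "hanley") {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (npos - 1) * (q1 - auc^2) +
                  (nneg - 1) * (q2 - auc^2)) / (npos * nneg))
  } else {
    sp <- s[y]; sn <- s[!y]
    v10 <- vapply(sp, function(x) mean((x > sn) + 0.5 * (x == sn)), numeric(1))
    v01 <- vapply(sn, function(x) mean((sp > x) + 0.5 * (sp == x)), numeric(1))
    se <- sqrt(var(v10) / npos + var(v01) / nneg)
  }
  z <- qnorm(1 - alpha / 2)
  structure(
    list(auc = auc, se = se,
         ci_low = max(0, auc - z * se), ci_high = min(1, auc + z * se),
         n_pos = npos, n_neg = nneg, se_method = se_method, alpha = alpha),
    class = "auroc_estimate"
  )
}

#' @export
print.auroc_estimate <- function(x, ...) {
  cat(sprintf("AUROC %.3f (%.3f-%.3f), se %.4f [%s], %d pos / %d neg\n",
              x$auc, x$ci_low, x$ci_high, x$se, x$se_method,
              x$n_pos, x$n_neg))
  invisible(x)
}

.curve_metrics <- function(curve) {
  sens <- curve$tpr
  spec <- 1 - curve$fpr
  called <- curve$tp + curve$fp
  ppv <- ifelse(called > 0, curve$tp / called, NA_real_)
  data.frame(threshold = curve$threshold, sens = sens, spec = spec,
             ppv = ppv)
}

.cutoff_result <- function(rule, curve, i, extra = list()) {
  if (is.na(i)) {
    sel <- list(rule = rule, threshold = NA_real_, j = NA_real_,
                metrics = NULL)
  } else {
    tab <- confusion_table(curve$tp[i], curve$fp[i], curve$fn[i], curve$tn[i])
    sel <- list(rule = rule, threshold = curve$threshold[i],
                j = curve$tpr[i] - curve$fpr[i],
                metrics = dta_metrics(tab), table = tab)
  }
  structure(c(sel, extra), class = "cutoff_selection")
}

#' @export
print.cutoff_selection <- function(x, ...) {
  cat("<cutoff_selection> rule ", x$rule, ": ", sep = "")
  if (is.na(x$threshold)) {
    cat("no admissible threshold\n")
  } else {
    cat("cut-off >= ", x$threshold, " (J = ", round(x$j, 3), ")\n", sep = "")
    print.data.frame(x$metrics, row.names = FALSE)
  }
  if (!is.null(x$constraint_met) && !x$constraint_met) {
    cat("  note: PPV floor not attainable; max-PPV threshold reported\n")
  }
  invisible(x)
}

#' Researcher-defined cut-off: maximize sensitivity under a PPV floor
#'
#' Among thresholds whose PPV exceeds `min_ppv`, choose the one with the
#' greatest sensitivity (ties: lowest threshold). If no threshold clears the
#' floor, the maximum-PPV threshold is returned with `constraint_met =
#' FALSE`. Thresholds at which the test calls nobody positive (undefined
#' PPV) are not admissible.
#'
#' @param curve a [roc_curve()].
#' @param min_ppv PPV floor (default 0.90).
#' @param target_sens aspirational sensitivity recorded in the result
#'   (default 0.80); it does not constrain the search.
#' @return object of class `cutoff_selection`.
#' @export
select_cutoff_constrained <- function(curve, min_ppv = 0.90,
                                      target_sens = 0.80) {
  m <- .curve_metrics(curve)
  ok <- !is.na(m$ppv) & m$ppv > min_ppv
  if (any(ok)) {
    cand <- which(ok)
    i <- cand[order(-m$sens[cand], m$threshold[cand])][1]
    met <- TRUE
  } else {
    cand <- which(!is.na(m$ppv))
    i <- if (length(cand)) cand[order(-m$ppv[cand], m$threshold[cand])][1] else NA
    met <- FALSE
  }
  .cutoff_result("constrained", curve, i,
                 list(min_ppv = min_ppv, target_sens = target_sens,
                      constraint_met = met))
}

#' Youden-index cut-off
#'
#' Maximizes J = sensitivity + specificity - 1 = tpr - fpr over the curve's
#' thresholds; ties broken by the lowest threshold.
#'
#' @param curve a [roc_curve()].
#' @return object of class `cutoff_selection` (with the achieved `j`).
#' @export
select_cutoff_youden <- function(curve) {
  j <- curve$tpr - curve$fpr
  i <- order(-j, curve$threshold)[1]
  .cutoff_result("youden", curve, i)
}

#' Sensitivity-equals-specificity cut-off
#'
#' Chooses the threshold minimizing |sensitivity - specificity|; when even
#' the best gap exceeds `tolerance` no crossing exists (typical of coarse
#' score lattices) and the threshold is reported as `NA`.
#'
#' @param curve a [roc_curve()].
#' @param tolerance largest acceptable |sens - spec| gap (default 0.02).
#' @return object of class `cutoff_selection`; `threshold` is `NA` when no
#'   crossing exists within tolerance.
#' @export
select_cutoff_sens_eq_spec <- function(curve, tolerance = 0.02) {
  gap <- abs(curve$tpr - (1 - curve$fpr))
  i <- order(gap, curve$threshold)[1]
  if (gap[i] > tolerance) i <- NA
  .cutoff_result("sens_eq_spec", curve, i, list(tolerance = tolerance))
}

#' Trapezoidal area under a computed ROC curve
#'
#' Numerically integrates the curve in (fpr, tpr) space. With the mid-rank
#' tie convention this equals [auroc()]'s Mann-Whitney area exactly; it is
#' exposed mainly as a cross-check.
#'
#' @param curve a [roc_curve()].
#' @return numeric area.
#' @export
roc_trapezoid_auc <- function(curve) {
  o <- order(curve$fpr, curve$tpr)
  x <- curve$fpr[o]; y <- curve$tpr[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Write ROC points to CSV
#' @param curve a [roc_curve()].
#' @param path output path.
#' @export
write_roc_csv <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE)
}
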