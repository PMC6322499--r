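test_that("build_confusion partitions records and detects misalignment", {
  calls <- data.frame(record_id = c("a", "b", "c", "d"),
                      positive = c(TRUE, TRUE, FALSE, FALSE))
  truth <- data.frame(record_id = c("a", "b", "c", "d"),
                      truth = c(TRUE, FALSE, TRUE, FALSE))
  tab <- build_confusion(calls, truth)
  expect_equal(unclass(tab)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  all_right <- build_confusion(truth |> transform(positive = truth), truth)
  expect_equal(all_right$fp + all_right$fn, 0L)
  # conservation over random instances
  set.seed(3)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    ids <- sprintf("r%02d", 1:n)
    tab <- build_confusion(
      data.frame(record_id = ids, positive = runif(n) < 0.4),
      data.frame(record_id = sample(ids), truth = runif(n) < 0.3))
    expect_equal(tab$tp + tab$fp + tab$fn + tab$tn, n)
  }
  expect_error(build_confusion(calls[0, ], truth),
               class = "carematch_alignment_error")
  err <- tryCatch(
    build_confusion(calls, data.frame(record_id = c("a", "b", "c", "e"),
                                      truth = TRUE)),
    carematch_alignment_error = function(e) e)
  expect_setequal(err$ids, c("d", "e"))
})

test_that("dta_metric gives exact Clopper-Pearson intervals and boundaries", {
  # flag table reconstructed from printed study margins (see acceptance)
  tab <- confusion_table(tp = 385, fp = 9, fn = 46, tn = 4560)
  sens <- dta_metric(tab, "sensitivity")
  expect_equal(round(100 * sens$point, 1), 89.3)
  expect_equal(sens$n, 431)
  # closed form at x = 0: upper limit 1 - (alpha/2)^(1/n)
  ci0 <- clopper_pearson(0, 10, 0.05)
  expect_equal(unname(ci0["low"]), 0)
  expect_equal(unname(ci0["high"]), 1 - 0.025^(1 / 10), tolerance = 1e-10)
  # x = n pins the upper limit to 1
  cin <- clopper_pearson(7, 7)
  expect_equal(unname(cin["high"]), 1)
  est <- dta_metric(confusion_table(7, 0, 0, 3), "sensitivity")
  expect_equal(est$point, 1)
  expect_equal(est$ci_high, 1)
  # ordering invariant ci_low <= point <= ci_high on random tables
  set.seed(9)
  for (i in 1:20) {
    x <- sample(0:30, 1); n <- x + sample(0:30, 1)
    if (n == 0) next
    ci <- clopper_pearson(x, n)
    expect_lte(ci["low"], x / n + 1e-12)
    expect_gte(ci["high"], x / n - 1e-12)
  }
  # undefined metric signals rather than dividing by zero
  none <- confusion_table(tp = 0, fp = 0, fn = 5, tn = 5)
  expect_error(dta_metric(none, "ppv"), class = "carematch_undefined_metric")
  expect_true(is.na(dta_metrics(none)$point[3]))
})

test_that("clopper-pearson interval width shrinks with n at fixed p", {
  w <- function(n) diff(clopper_pearson(round(0.9 * n), n))
  expect_gt(w(20), w(80))
  expect_gt(w(80), w(320))
})

test_that("roc_curve sweeps observed thresholds with the sentinel corner", {
  sc <- c(90, 80, 10); y <- c(TRUE, TRUE, FALSE)
  curve <- roc_curve(sc, y)
  expect_equal(curve$threshold, c(10, 80, 90, 91))
  at80 <- curve[curve$threshold == 80, ]
  expect_equal(at80$tpr, 1); expect_equal(at80$fpr, 0)
  # endpoints contain both corners
  expect_true(any(curve$fpr == 0 & curve$tpr == 0))
  expect_true(any(curve$fpr == 1 & curve$tpr == 1))
  # all-identical scores collapse to the two corners
  flat <- roc_curve(rep(5, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(nrow(flat), 2)
  expect_setequal(flat$tpr, c(0, 1))
  # monotone in threshold; matches brute-force sweep with ties
  set.seed(4)
  for (i in 1:10) {
    n <- sample(6:40, 1)
    s <- sample(0:5, n, replace = TRUE)
    y <- runif(n) < 0.5
    if (!any(y) || all(y)) next
    curve <- roc_curve(s, y)
    expect_true(all(diff(curve$tpr) <= 0))
    expect_true(all(diff(curve$fpr) <= 0))
    for (j in seq_len(nrow(curve))) {
      t <- curve$threshold[j]
      expect_equal(curve$tp[j], sum(y & s >= t))
      expect_equal(curve$fp[j], sum(!y & s >= t))
    }
  }
  expect_error(roc_curve(c(1, 2), c(TRUE, TRUE)),
               class = "carematch_validation_error")
})

test_that("auroc equals the exhaustive pairwise count and trapezoid area", {
  expect_equal(auroc(c(9, 8, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  # spec worked example: positives {13,25,0}, negatives {0,0,13}
  sc <- c(13, 25, 0, 0, 0, 13); y <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(auroc(sc, y)$auc, 6.5 / 9)
  set.seed(5)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    s <- sample(0:8, n, replace = TRUE)
    y <- runif(n) < 0.5
    if (!any(y) || all(y)) next
    a <- auroc(s, y)
    expect_equal(a$auc, auc_pairwise(s, y))
    expect_equal(a$auc, roc_trapezoid_auc(roc_curve(s, y)))
    # invariance under strictly increasing transforms
    expect_equal(auroc(exp(s / 3) + 2, y)$auc, a$auc)
    expect_true(a$ci_low <= a$auc && a$auc <= a$ci_high)
  }
})

test_that("auroc standard errors: hanley-mcneil formula, delong option", {
  sc <- c(13, 25, 0, 0, 0, 13); y <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  a <- auroc(sc, y)
  A <- 6.5 / 9; q1 <- A / (2 - A); q2 <- 2 * A^2 / (1 + A)
  se <- sqrt((A * (1 - A) + 2 * (q1 - A^2) + 2 * (q2 - A^2)) / 9)
  expect_equal(a$se, se)
  d <- auroc(sc, y, se_method = "delong")
  expect_equal(d$auc, a$auc)
  expect_gt(d$se, 0)
  # near-chance scores give auc about 0.5 at large n
  set.seed(6)
  s <- runif(4000); y2 <- runif(4000) < 0.3
  expect_equal(auroc(s, y2)$auc, 0.5, tolerance = 0.05)
})

test_that("youden and sens=spec selections match exhaustive search", {
  set.seed(12)
  for (i in 1:25) {
    n <- sample(8:50, 1)
    s <- sample(0:6, n, replace = TRUE)
    y <- runif(n) < 0.4
    if (!any(y) || all(y)) next
    curve <- roc_curve(s, y)
    # exhaustive over the curve's thresholds
    j <- curve$tpr - curve$fpr
    best <- min(curve$threshold[j == max(j)])
    sel <- select_cutoff_youden(curve)
    expect_equal(sel$threshold, best)
    expect_equal(sel$j, max(j))
    gap <- abs(curve$tpr - (1 - curve$fpr))
    ses <- select_cutoff_sens_eq_spec(curve, tolerance = 1)
    expect_equal(ses$threshold, min(curve$threshold[gap == min(gap)]))
  }
  # perfect test: J = 1 at the separating threshold
  perfect <- roc_curve(c(9, 9, 1, 1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(select_cutoff_youden(perfect)$j, 1)
  expect_equal(select_cutoff_youden(perfect)$threshold, 9)
  # useless test: J = 0
  flat <- roc_curve(rep(3, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(select_cutoff_youden(flat)$j, 0)
})

test_that("sens=spec reports no threshold on coarse lattices", {
  # 3-value score with a large minimum |sens - spec| gap
  s <- c(0, 0, 0, 0, 0, 0, 100, 100, 100, 50)
  y <- c(rep(FALSE, 7), TRUE, TRUE, TRUE)
  curve <- roc_curve(s, y)
  gap <- min(abs(curve$tpr - (1 - curve$fpr)))
  expect_gt(gap, 0.05)
  expect_true(is.na(select_cutoff_sens_eq_spec(curve, 0.05)$threshold))
  expect_false(is.na(select_cutoff_sens_eq_spec(curve, 1)$threshold))
})

test_that("constrained rule maximizes sensitivity under the PPV floor", {
  fake <- function(tp, fp, fn, tn, thr) {
    structure(data.frame(threshold = thr, tp = tp, fp = fp, fn = fn, tn = tn,
                         tpr = tp / (tp + fn), fpr = fp / (fp + tn)),
              class = c("roc_curve", "data.frame"))
  }
  # threshold 1: PPV .95 sens .85; threshold 2: PPV .91 sens .90 -> pick 2
  curve <- fake(tp = c(85, 90), fp = c(5, 9), fn = c(15, 10),
                tn = c(95, 91), thr = c(1, 2))
  sel <- select_cutoff_constrained(curve, min_ppv = 0.90)
  expect_equal(sel$threshold, 2)
  expect_true(sel$constraint_met)
  # no threshold clears the floor -> max-PPV fallback, flagged
  weak <- fake(tp = c(50, 30), fp = c(50, 20), fn = c(0, 20),
               tn = c(0, 30), thr = c(1, 2))
  sel2 <- select_cutoff_constrained(weak, min_ppv = 0.90)
  expect_false(sel2$constraint_met)
  expect_equal(sel2$threshold, 2)  # PPV .6 beats .5
  # single-threshold curve returns that threshold
  one <- fake(10, 1, 0, 9, thr = 5)
  expect_equal(select_cutoff_constrained(one)$threshold, 5)
  # metrics at the cut-off are the four standard estimates
  expect_setequal(sel$metrics$metric, c("sensitivity", "specificity",
                                        "ppv", "npv"))
})

test_that("sample size and prevalence reproduce the worked examples", {
  expect_equal(sample_size_sensitivity(S = 0.85, d = 0.05, prev = 0.04), 4898L)
  expect_equal(sample_size_sensitivity(S = 0.85, d = 0.05, prev = 1), 196L)
  # S = 0.5 maximizes n at fixed d, prev
  ns <- vapply(c(0.2, 0.35, 0.5, 0.65, 0.8),
               function(S) sample_size_sensitivity(S, 0.05, 0.1), integer(1))
  expect_equal(which.max(ns), 3L)
  expect_error(sample_size_sensitivity(0.85, 0.05, 0),
               class = "carematch_validation_error")

  expect_equal(prevalence(1455, 20000), 0.07275)
  expect_equal(round(100 * prevalence(1455, 20000), 1), 7.3)
  expect_equal(prevalence(0, 10), 0)
  expect_equal(prevalence(10, 10), 1)
  expect_error(prevalence(1, 0), class = "carematch_validation_error")
})

test_that("merge_adjudications resolves agreement and lists conflicts", {
  a <- data.frame(record_id = c("x", "y", "z"), truth = c(TRUE, FALSE, TRUE))
  b <- data.frame(record_id = c("x", "y", "z"), truth = c(TRUE, TRUE, TRUE))
  m <- merge_adjudications(a, b)
  expect_equal(m$disagreements, "y")
  expect_true(is.na(m$consensus$truth[m$consensus$record_id == "y"]))
  expect_equal(m$consensus$truth[m$consensus$record_id == "x"], TRUE)
  # full agreement: empty disagreement list
  m2 <- merge_adjudications(a, a)
  expect_length(m2$disagreements, 0)
  # resolution table completes the consensus
  m3 <- merge_adjudications(a, b,
                            resolutions = data.frame(record_id = "y",
                                                     truth = TRUE))
  expect_equal(m3$consensus$truth[m3$consensus$record_id == "y"], TRUE)
  expect_equal(m3$disagreements, "y")
  expect_error(merge_adjudications(a, b[1:2, ]),
               class = "carematch_alignment_error")
})
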