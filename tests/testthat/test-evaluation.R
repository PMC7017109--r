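test_that("outcome classification follows the response/duration rule", {
  expect_equal(classify_outcome("PR", 11), "successful")
  expect_equal(classify_outcome("SD", 8), "unsuccessful")
  expect_equal(classify_outcome("SD", 12), "successful")  # boundary inclusive
  expect_equal(classify_outcome("CR", NA), "successful")
  expect_equal(classify_outcome("PD", 20), "unsuccessful")
  expect_error(classify_outcome("XX", 1), "unknown response")
  expect_error(classify_outcome("SD", NA), "requires ttf_months")
})

test_that("cohort summaries aggregate categories into outcome labels", {
  records <- data.frame(
    response = c(rep("CR", 23), rep("PR", 40), rep("SD", 7 + 53), rep("PD", 79)),
    ttf_months = c(rep(20, 23), rep(10, 40), rep(14, 7), rep(8, 53), rep(2, 79)),
    stringsAsFactors = FALSE)
  s <- summarize_outcomes(records)
  expect_equal(s$n, 202)
  expect_equal(sum(s$categories), 202)
  expect_equal(unname(s$categories),
               c(23, 47, 53, 79))
  expect_equal(unname(s$labels), c(70, 132))
  empty <- summarize_outcomes(records[0, ])
  expect_true(all(empty$categories == 0) && all(empty$labels == 0))
  one <- summarize_outcomes(data.frame(response = "CR", ttf_months = 5))
  expect_equal(unname(one$labels), c(1, 0))
})

test_that("confusion matrices use the strict greater-than rule and conserve totals", {
  cm <- confusion_at_threshold(c(30, 10), c("successful", "unsuccessful"), 25)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(1, 0, 0, 1))
  cm0 <- confusion_at_threshold(rep(0, 5),
                                c("successful", rep("unsuccessful", 4)), 25)
  expect_equal(cm0$tp + cm0$fp, 0)
  # a score equal to the threshold is not predicted favorable
  cm25 <- confusion_at_threshold(25, "successful", 25)
  expect_equal(cm25$fn, 1)
  expect_equal(confusion_at_threshold(25, "successful", 25, strict = FALSE)$tp, 1)
  # hand-verified six-record set, totals conserved at every threshold
  scores <- c(0, 17, 25, 42, 60, 80)
  labels <- c("unsuccessful", "unsuccessful", "successful", "unsuccessful",
              "successful", "successful")
  for (t in c(-1, 0, 20, 25, 50, 100)) {
    cm <- confusion_at_threshold(scores, labels, t)
    expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, 6)
    expect_equal(cm$tp, sum(scores > t & labels == "successful"))
    expect_equal(cm$fp, sum(scores > t & labels == "unsuccessful"))
  }
  expect_error(confusion_at_threshold(1:3, c("successful", "unsuccessful"), 25),
               "same length")
})

test_that("performance indices and exact binomial CIs reproduce the published table", {
  pm <- performance_metrics(confusion_matrix(tp = 59, fp = 30, fn = 11, tn = 102))
  expect_equal(pm$sensitivity$percent, 84L)
  expect_equal(pm$specificity$percent, 77L)
  expect_equal(pm$ppv$percent, 66L)
  expect_equal(pm$npv$percent, 90L)
  expect_equal(c(pm$sensitivity$ci_lower_percent, pm$sensitivity$ci_upper_percent),
               c(74L, 92L))
  expect_equal(c(pm$specificity$ci_lower_percent, pm$specificity$ci_upper_percent),
               c(69L, 84L))
})

test_that("degenerate confusion matrices give flagged, not NaN, metrics", {
  perfect <- performance_metrics(confusion_matrix(10, 0, 0, 10))
  for (m in c("sensitivity", "specificity", "ppv", "npv"))
    expect_equal(perfect[[m]]$percent, 100L)
  even <- performance_metrics(confusion_matrix(1, 1, 1, 1))
  for (m in c("sensitivity", "specificity", "ppv", "npv"))
    expect_equal(even[[m]]$percent, 50L)
  nopos <- performance_metrics(confusion_matrix(0, 0, 0, 5))
  expect_false(nopos$sensitivity$defined)
  expect_true(nopos$specificity$defined)
})

test_that("rank-based AUC equals trapezoidal ROC integration and flips with labels", {
  expect_equal(roc_and_auc(c(60, 80, 10, 20, 30),
                           c("successful", "successful", rep("unsuccessful", 3))
                           )$auc, 1)
  expect_equal(roc_and_auc(c(30, 10, 50),
                           c("successful", "unsuccessful", "unsuccessful")
                           )$auc, 0.5)
  set.seed(7)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    scores <- sample(seq(0, 100, by = 5), n, replace = TRUE)  # ties likely
    labels <- ifelse(runif(n) < 0.4, "successful", "unsuccessful")
    if (length(unique(labels)) < 2) next
    r <- roc_and_auc(scores, labels)
    expect_equal(r$auc, oracle_trapezoid_auc(scores, labels))
    flipped <- ifelse(labels == "successful", "unsuccessful", "successful")
    expect_equal(r$auc + roc_and_auc(scores, flipped)$auc, 1)
    expect_true(all(diff(r$roc$tpr) >= 0) && all(diff(r$roc$fpr) >= 0))
    expect_equal(r$roc$tpr[1] + r$roc$fpr[1], 0)
    expect_equal(r$roc$tpr[nrow(r$roc)], 1)
  }
  expect_error(roc_and_auc(1:3, rep("successful", 3)), "at least one")
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(11)
  scores <- sample(0:100, 40, replace = TRUE)
  labels <- ifelse(runif(40) < 0.35, "successful", "unsuccessful")
  got <- roc_and_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("unsuccessful", "successful"),
    direction = "<", quiet = TRUE)))
  expect_equal(got, ref)
})

test_that("Youden threshold selection matches an exhaustive scan", {
  # perfectly separated groups: lowest optimal candidate wins
  expect_equal(youden_threshold(c(60, 80, 10, 20),
                                c("successful", "successful",
                                  "unsuccessful", "unsuccessful")), 20)
  hand <- list(scores = c(0, 0, 10, 25, 25, 40, 60, 90),
               labels = c("unsuccessful", "unsuccessful", "successful",
                          "unsuccessful", "successful", "successful",
                          "unsuccessful", "successful"))
  expect_equal(youden_threshold(hand$scores, hand$labels),
               oracle_youden(hand$scores, hand$labels))
  set.seed(3)
  for (i in 1:15) {
    n <- sample(8:25, 1)
    scores <- sample(seq(0, 100, 5), n, replace = TRUE)
    labels <- ifelse(runif(n) < 0.4, "successful", "unsuccessful")
    if (length(unique(labels)) < 2) next
    expect_equal(youden_threshold(scores, labels),
                 oracle_youden(scores, labels))
  }
  expect_error(youden_threshold(1:3, rep("unsuccessful", 3)), "at least one")
})

test_that("Mann-Whitney U handles ties, matches pair counting and wilcox.test", {
  tied <- mann_whitney(c(5, 5), c(5, 5))
  expect_equal(tied$U, 2)        # n1*n2/2 under complete tying
  expect_equal(tied$p, 1)
  sep <- mann_whitney(c(3, 4), c(1, 2))
  expect_equal(sep$U_less, 0)    # no unsuccessful > successful pair
  expect_equal(sep$U, 0)
  set.seed(21)
  for (i in 1:15) {
    x <- sample(0:10, sample(3:8, 1), replace = TRUE)
    y <- sample(0:10, sample(3:8, 1), replace = TRUE)
    mw <- mann_whitney(x, y)
    expect_equal(mw$U_greater, oracle_u_pairs(x, y))
    expect_equal(mw$U_less, oracle_u_pairs(y, x))
    expect_equal(mw$U_greater,
                 unname(suppressWarnings(wilcox.test(x, y)$statistic)))
  }
})

test_that("the normal approximation tracks the exact permutation p-value", {
  set.seed(31)
  rel_err <- c()
  for (i in 1:10) {
    x <- sample(0:40, 6, replace = TRUE)
    y <- sample(0:40, 6, replace = TRUE)
    exact <- mann_whitney(x, y, exact_limit = 100)
    expect_equal(exact$method, "exact enumeration")
    approx <- mann_whitney(x, y, exact_limit = 0)
    if (exact$p > 0.05) {
      rel_err <- c(rel_err, abs(approx$p - exact$p) / exact$p)
      # the discrete exact distribution limits per-draw agreement
      expect_lt(abs(approx$p - exact$p) / exact$p, 0.25)
    }
    # untied data: our normal p equals wilcox.test with continuity correction
    if (!anyDuplicated(c(x, y)))
      expect_equal(approx$p,
                   wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  }
  expect_lt(mean(rel_err), 0.10)  # within 10% of exact on average
})

test_that("cohort evaluation assembles a coherent report and can fill in scores", {
  g <- generate_cohort(cohort_spec(n_patients = 25, seed = 4))
  rep1 <- evaluate_cohort(g$records, threshold = 25)
  expect_equal(rep1$cm$tp + rep1$cm$fp + rep1$cm$fn + rep1$cm$tn, rep1$n)
  expect_equal(rep1$threshold, 25)
  expect_true(rep1$auc >= 0 && rep1$auc <= 1)
  # recomputing scores from kb + profiles reproduces the stored column
  blank <- g$records
  blank$score_percent <- NULL
  rep2 <- evaluate_cohort(blank, threshold = 25, kb = calibration_kb(),
                          profiles = g$profiles)
  expect_equal(c(rep2$cm$tp, rep2$cm$fp, rep2$cm$fn, rep2$cm$tn),
               c(rep1$cm$tp, rep1$cm$fp, rep1$cm$fn, rep1$cm$tn))
  expect_error(evaluate_cohort(blank, threshold = 25), "supply kb")
  # omitted threshold falls back to the Youden optimum
  rep3 <- evaluate_cohort(g$records)
  lab <- classify_outcome(g$records)
  expect_equal(rep3$threshold, youden_threshold(g$records$score_percent, lab))
})

test_that("cohort TSV round-trips through load_cohort", {
  g <- generate_cohort(cohort_spec(n_patients = 10, seed = 9))
  dir <- file.path(tempdir(), "cohort-rt")
  write_cohort(g, dir)
  rec <- load_cohort(file.path(dir, "cohort.tsv"))
  expect_equal(nrow(rec), nrow(g$records))
  expect_equal(rec$score_percent, g$records$score_percent)
  profs <- load_profiles(file.path(dir, "profiles.tsv"),
                         patients_path = file.path(dir, "patients.tsv"))
  expect_equal(length(profs), 10)
  expect_equal(profs[[1]]$alterations, g$profiles[[1]]$alterations)
})
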