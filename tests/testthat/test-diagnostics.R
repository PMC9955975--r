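test_that("dichotomization is strict at the cutoff and Inf is long", {
  expect_identical(as.character(dichotomize(27.28)), "short")
  expect_identical(as.character(dichotomize(54.6)), "long")
  expect_identical(as.character(dichotomize(48)), "long")   # boundary
  expect_identical(as.character(dichotomize(Inf)), "long")
  expect_identical(as.character(dichotomize(47.999, cutoff_h = 48)), "short")
  expect_error(dichotomize(-3), "positive")
  expect_error(dichotomize(10, cutoff_h = 0), "cutoff")
})

test_that("confusion matrix counts partition the cohort", {
  pred <- c(rep("short", 36), rep("long", 27))
  obs <- c(rep("complete", 34), rep("incomplete", 2),
           rep("complete", 9), rep("incomplete", 18))
  cm <- build_confusion(pred, obs)
  expect_equal(cm$tp, 34)
  expect_equal(cm$fp, 2)
  expect_equal(cm$fn, 9)
  expect_equal(cm$tn, 18)
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, 63)

  cm2 <- build_confusion(rep("short", 5), rep("complete", 5))
  expect_equal(unlist(cm2[c("tp", "fp", "fn", "tn")]),
               c(tp = 5, fp = 0, fn = 0, tn = 0))

  expect_error(build_confusion(character(0), character(0)), "empty")
  expect_error(build_confusion("short", c("complete", "complete")), "length")
  expect_error(build_confusion("tall", "complete"), "short")
})

test_that("diagnostic metrics match hand-computed proportions", {
  m <- diagnostic_metrics(confusion_matrix(34, 2, 9, 18))
  est <- setNames(m$estimate, m$metric)
  expect_equal(round(est[["sensitivity"]], 3), 0.791)
  expect_equal(round(est[["specificity"]], 3), 0.900)
  expect_equal(round(est[["accuracy"]], 3), 0.825)
  expect_equal(round(est[["ppv"]], 3), 0.944)
  expect_equal(round(est[["npv"]], 3), 0.667)
  # Wilson interval for 34/43, frozen from the closed form
  expect_equal(m$ci_low[m$metric == "sensitivity"], 0.647944, tolerance = 1e-5)
  expect_equal(m$ci_high[m$metric == "sensitivity"], 0.885772, tolerance = 1e-5)
  expect_true(all(m$ci_low <= m$estimate & m$estimate <= m$ci_high))

  perfect <- diagnostic_metrics(confusion_matrix(10, 0, 0, 10))
  expect_true(all(perfect$estimate == 1))
  symmetric <- diagnostic_metrics(confusion_matrix(1, 1, 1, 1))
  expect_true(all(symmetric$estimate == 0.5))
})

test_that("metrics with zero denominators are undefined, not zero", {
  m <- diagnostic_metrics(confusion_matrix(0, 0, 0, 5))
  est <- setNames(m$estimate, m$metric)
  expect_true(is.na(est[["sensitivity"]]))   # no condition-positives
  expect_true(is.na(est[["ppv"]]))           # no test-positives
  expect_equal(est[["specificity"]], 1)
  expect_error(diagnostic_metrics(confusion_matrix(0, 0, 0, 0)), "empty")
})

test_that("ppv is Bayes-consistent with sensitivity, specificity, prevalence", {
  set.seed(11)
  for (i in 1:20) {
    cm <- confusion_matrix(sample(1:30, 1), sample(1:30, 1),
                           sample(1:30, 1), sample(1:30, 1))
    m <- diagnostic_metrics(cm)
    est <- setNames(m$estimate, m$metric)
    total <- cm$tp + cm$fp + cm$fn + cm$tn
    prev <- (cm$tp + cm$fn) / total
    ppv_bayes <- est[["sensitivity"]] * prev /
      (est[["sensitivity"]] * prev + (1 - est[["specificity"]]) * (1 - prev))
    expect_equal(unname(est[["ppv"]]), unname(ppv_bayes), tolerance = 1e-12)
  }
})

test_that("ROC reproduces worked examples and brute-force AUC", {
  r <- roc_analysis(c(20, 30, 90, 100),
                    c("complete", "complete", "incomplete", "incomplete"))
  expect_equal(r$auc, 1)
  expect_equal(r$optimal_cutoff_h, 60)   # midpoint of 30 and 90
  expect_equal(r$youden_j, 1)

  # order of cases is irrelevant
  r2 <- roc_analysis(c(20, 90, 30, 100),
                     c("complete", "incomplete", "complete", "incomplete"))
  expect_equal(r2$auc, 1)

  # interleaved case, oracle value 0.75 from pairwise comparison
  r3 <- roc_analysis(c(10, 30, 20, 40),
                     c("complete", "complete", "incomplete", "incomplete"))
  expect_equal(r3$auc, 0.75)
  expect_equal(r3$auc, brute_force_auc(c(10, 30, 20, 40),
                                       c("complete", "complete",
                                         "incomplete", "incomplete")))

  expect_error(roc_analysis(c(10, 20), c("complete", "complete")), "one")
})

test_that("AUC is invariant to monotone transforms and flips with labels", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    hl <- sample(c(runif(n, 10, 200), Inf), n)
    lab <- sample(c("complete", "incomplete"), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- c("complete", "incomplete")
    a <- roc_analysis(hl, lab)$auc
    # strictly monotone transform of the half-lives
    a_t <- roc_analysis(hl^3 + 1, lab)$auc
    expect_equal(a, a_t)
    # swapping class labels maps AUC to 1 - AUC
    flipped <- ifelse(lab == "complete", "incomplete", "complete")
    expect_equal(roc_analysis(hl, flipped)$auc, 1 - a)
  }
})

test_that("ROC operating points equal dichotomize + build_confusion", {
  set.seed(31)
  for (i in 1:8) {
    n <- sample(6:15, 1)
    hl <- round(runif(n, 10, 120), 1)
    hl[sample(n, 1)] <- Inf
    lab <- sample(c("complete", "incomplete"), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- c("complete", "incomplete")
    r <- roc_analysis(hl, lab)
    for (j in seq_len(nrow(r$table))) {
      cut <- r$table$cutoff_h[j]
      if (!is.finite(cut)) next
      cm <- build_confusion(dichotomize(hl, cut), lab)
      expect_equal(r$table$sensitivity[j], cm$tp / (cm$tp + cm$fn))
      expect_equal(r$table$specificity[j], cm$tn / (cm$tn + cm$fp))
    }
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(47)
  for (i in 1:5) {
    n <- 40
    hl <- c(rlnorm(n / 2, log(30), 0.4), rlnorm(n / 2, log(90), 0.4))
    lab <- rep(c("complete", "incomplete"), each = n / 2)
    ours <- roc_analysis(hl, lab)$auc
    ref <- suppressMessages(
      as.numeric(pROC::auc(pROC::roc(lab, -hl, levels = c("incomplete", "complete"),
                                     direction = "<"))))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})
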