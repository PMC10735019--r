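test_that("confusion counts and metrics match the published tables", {
  # perfect classifier
  cm0 <- confusion(c("Accepted", "Rejected"), c(1, 0), 0.5)
  expect_equal(c(cm0$fp, cm0$fn), c(0, 0))
  expect_equal(accuracy(cm0), 1)

  # SVM cross-validation table: accuracy (7687 + 7745) / 16571
  svm_cm <- confusion_matrix(tp = 7745, fp = 595, fn = 544, tn = 7687)
  expect_equal(accuracy(svm_cm), (7687 + 7745) / 16571, tolerance = 1e-12)
  expect_equal(round(accuracy(svm_cm), 2), 0.93)

  # NN validation table: precision 1539 / (1539 + 81)
  nn_cm <- confusion_matrix(tp = 1539, fp = 81, fn = 116, tn = 1579)
  expect_equal(precision(nn_cm), 1539 / 1620, tolerance = 1e-12)
  expect_equal(round(precision(nn_cm), 2), 0.95)

  # worked 50-image example
  wk <- confusion_matrix(tp = 39, fp = 1, fn = 6, tn = 4)
  expect_equal(precision(wk), 0.975)
  expect_equal(recall(wk), 39 / 45)
  expect_equal(round(recall(wk), 2), 0.87)

  # undefined metrics return the NA marker, never a number
  empty_pos <- confusion_matrix(tp = 0, fp = 0, fn = 3, tn = 5)
  expect_true(is.na(precision(empty_pos)))
  expect_true(is.na(recall(confusion_matrix(0, 2, 0, 5))))

  expect_error(confusion(c("Accepted"), c(0.5, 0.2)), "equal length")
})

test_that("confusion agrees with brute-force recomputation at any threshold", {
  set.seed(14)
  labels <- sample(c("Accepted", "Rejected"), 200, replace = TRUE)
  prob <- round(runif(200), 2)  # plenty of ties
  for (thr in c(0, 0.25, 0.5, 0.76, 1)) {
    cm <- confusion(labels, prob, thr)
    want <- confusion_oracle(labels, prob, thr)
    expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), unname(want))
  }
})

test_that("the ROC curve matches the pairwise-comparison oracle", {
  # perfectly separating scores
  r <- roc_curve(rep(c("Accepted", "Rejected"), each = 5),
                 c(6:10, 1:5) / 10)
  expect_equal(attr(r, "auc"), 1)

  # threshold below the minimum score: everything predicted positive
  expect_equal(r$tpr[nrow(r)], 1)
  expect_equal(r$fpr[nrow(r)], 1)

  # labels independent of scores
  set.seed(3)
  lab <- sample(c("Accepted", "Rejected"), 10000, replace = TRUE)
  sc <- runif(10000)
  expect_equal(attr(roc_curve(lab, sc), "auc"), 0.5, tolerance = 0.02)

  # exhaustive pairwise oracle on small instances, with ties
  set.seed(4)
  for (i in 1:25) {
    n <- sample(8:50, 1)
    lab <- sample(c("Accepted", "Rejected"), n, replace = TRUE,
                  prob = c(0.6, 0.4))
    if (length(unique(lab)) < 2) next
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    expect_equal(attr(roc_curve(lab, sc), "auc"), auc_oracle(lab, sc),
                 tolerance = 1e-12)
  }

  expect_error(roc_curve(rep("Accepted", 4), runif(4)), "both classes")
})

test_that("the precision-recall curve enumerates distinct thresholds", {
  lab <- rep(c("Accepted", "Rejected"), each = 4)
  perfect <- pr_curve(lab, c(0.9, 0.8, 0.85, 0.95, 0.1, 0.2, 0.15, 0.05))
  expect_true(any(perfect$recall == 1 & perfect$precision == 1))

  # all-positive endpoint: precision equals prevalence
  expect_equal(perfect$precision[nrow(perfect)], 0.5)
  expect_equal(perfect$threshold[nrow(perfect)], -Inf)

  # hand enumeration on a 6-point score list with a tie: each operating
  # point is labelled with the smallest threshold realizing it under the
  # strict p > threshold rule
  lab6 <- c("Accepted", "Accepted", "Rejected", "Accepted", "Rejected", "Rejected")
  sc6 <- c(0.9, 0.7, 0.7, 0.5, 0.3, 0.1)
  pc <- pr_curve(lab6, sc6)
  expect_equal(pc$threshold, c(0.7, 0.5, 0.3, 0.1, -Inf))
  expect_equal(pc$recall, c(1 / 3, 2 / 3, 1, 1, 1))
  expect_equal(pc$precision, c(1, 2 / 3, 3 / 4, 3 / 5, 1 / 2))
  # brute-force cross-check at each listed threshold
  for (i in seq_len(nrow(pc))) {
    cts <- confusion_oracle(lab6, sc6, pc$threshold[i])
    expect_equal(pc$recall[i], unname(cts["tp"] / (cts["tp"] + cts["fn"])))
    expect_equal(pc$precision[i], unname(cts["tp"] / (cts["tp"] + cts["fp"])))
  }
})

test_that("threshold selection reaches the precision target with best recall", {
  # perfect scores: target met at full recall
  lab <- rep(c("Accepted", "Rejected"), each = 10)
  sc <- c(seq(0.8, 0.99, length.out = 10), seq(0.01, 0.2, length.out = 10))
  op <- select_threshold_for_precision(lab, sc, 0.97)
  expect_equal(op$recall, 1)
  expect_gte(op$precision, 0.97)

  # the returned threshold is minimal: brute-force over a fine grid
  # (scores informative about the labels so the target is achievable)
  set.seed(9)
  lab2 <- sample(c("Accepted", "Rejected"), 120, replace = TRUE)
  sc2 <- round(ifelse(lab2 == "Accepted", rbeta(120, 3, 1), rbeta(120, 1, 3)), 2)
  op2 <- select_threshold_for_precision(lab2, sc2, 0.8)
  expect_gte(op2$precision, 0.8)
  grid <- seq(0, op2$threshold - 1e-9, 0.005)
  for (thr in grid) {
    cts <- confusion_oracle(lab2, sc2, thr)
    p <- if (cts["tp"] + cts["fp"] > 0) cts["tp"] / (cts["tp"] + cts["fp"]) else NA
    expect_false(isTRUE(unname(p) >= 0.8))
  }
  # and its recall is the brute-force best subject to the constraint
  best_recall <- 0
  for (thr in unique(sc2)) {
    cts <- confusion_oracle(lab2, sc2, thr)
    if (cts["tp"] + cts["fp"] > 0 &&
        cts["tp"] / (cts["tp"] + cts["fp"]) >= 0.8) {
      best_recall <- max(best_recall, cts["tp"] / (cts["tp"] + cts["fn"]))
    }
  }
  expect_equal(op2$recall, best_recall)

  expect_error(
    select_threshold_for_precision(c("Accepted", "Rejected"), c(0.4, 0.6), 0.9),
    "unachievable")
})

test_that("precision stratified by track count matches per-bin computation", {
  lab <- rep("Accepted", 8)
  prob <- rep(1, 8)
  counts <- c(10, 20, 30, 40, 200, 300, 400, 500)
  sp <- stratified_precision(lab, prob, counts, breaks = c(0, 100, 600), 0.5)
  expect_equal(sp$precision, c(1, 1))

  # a single bin equals the global precision
  set.seed(2)
  lab2 <- sample(c("Accepted", "Rejected"), 60, replace = TRUE)
  pr2 <- runif(60)
  sp1 <- stratified_precision(lab2, pr2, rep(50, 60), breaks = c(0, 100), 0.5)
  expect_equal(sp1$precision, precision(confusion(lab2, pr2, 0.5)))

  # two bins with hand-assigned memberships
  lab3 <- c("Accepted", "Rejected", "Accepted", "Accepted", "Rejected")
  pr3 <- c(0.9, 0.8, 0.3, 0.95, 0.2)
  n3 <- c(10, 20, 150, 160, 170)
  sp3 <- stratified_precision(lab3, pr3, n3, breaks = c(0, 100, 200), 0.5)
  expect_equal(sp3$precision, c(1 / 2, 1))
  expect_equal(sp3$n, c(2, 3))

  expect_error(stratified_precision(lab3, pr3, n3, breaks = c(0, 100), 0.5),
               "cover")
})

test_that("projected confusion reproduces the 50-image worked example", {
  cm <- project_confusion(0.97, 0.87, 45, 5)
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(39, 6, 1, 4))

  cm2 <- project_confusion(1, 1, 12, 7)
  expect_equal(c(cm2$tp, cm2$fn, cm2$fp, cm2$tn), c(12, 0, 0, 7))

  cm3 <- project_confusion(0.5, 0.5, 10, 10)
  expect_equal(c(cm3$tp, cm3$fn, cm3$fp, cm3$tn), c(5, 5, 5, 5))

  expect_error(project_confusion(0.5, 1, 100, 2), "inconsistent")
})

test_that("prediction histograms partition each class", {
  lab <- rep(c("Accepted", "Rejected"), c(30, 20))
  set.seed(5)
  prob <- runif(50)
  h <- prediction_histogram(lab, prob)
  expect_equal(sum(h$accepted), 30)
  expect_equal(sum(h$rejected), 20)

  h1 <- prediction_histogram(rep("Accepted", 5), rep(1, 5))
  expect_equal(sum(h1$accepted > 0), 1)
  expect_equal(h1$accepted[length(h1$accepted)], 5)
})
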