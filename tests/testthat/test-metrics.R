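# Evaluation protocol: confusion matrices, one-vs-rest class metrics, macro
# averaging, PR/ROC curves. Reference values come from independent oracles
# (caret/pROC and brute-force recounting), never from the code under test.

test_that("confusion matrices count exactly", {
  true <- rep(0:5, each = 200)
  cm <- confusion_matrix(true, true, 6)
  expect_equal(diag(cm), rep(200L, 6))          # perfect predictor
  expect_equal(sum(cm), 1200)

  all0 <- confusion_matrix(true, rep(0L, 1200), 6)
  expect_equal(all0[, 1], rep(200L, 6))         # everything lands in column 0
  expect_true(all(all0[, -1] == 0))

  set.seed(30)
  t2 <- sample(0:5, 400, replace = TRUE)
  p2 <- sample(0:5, 400, replace = TRUE)
  cm2 <- confusion_matrix(t2, p2, 6)
  expect_equal(rowSums(cm2), as.numeric(table(factor(t2, levels = 0:5))))
  expect_equal(colSums(cm2), as.numeric(table(factor(p2, levels = 0:5))))
  expect_error(confusion_matrix(c(0, 6), c(0, 0), 6), "range")
})

test_that("per-class metrics satisfy their internal identities", {
  set.seed(31)
  for (rep in 1:25) {
    K <- sample(2:7, 1)
    cm <- matrix(rpois(K * K, 8), K, K)
    total <- sum(cm)
    for (k in 0:(K - 1)) {
      m <- class_metrics(cm, k)
      expect_equal(m$tp + m$fn, sum(cm[k + 1, ]))
      expect_equal(m$tp + m$fp, sum(cm[, k + 1]))
      expect_equal(m$tp + m$tn + m$fp + m$fn, total)
      expect_equal(m$fpr + m$specificity, 100, tolerance = 1e-9)
      if (m$precision + m$recall > 0)
        expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall),
                     tolerance = 1e-9)
    }
    # micro accuracy is the trace over the total
    rep_all <- metric_report(
      rep(0:(K - 1), times = rowSums(cm))[order(rep(seq_len(K), times = rowSums(cm)))],
      unlist(lapply(seq_len(K), function(i) rep(0:(K - 1), times = cm[i, ]))),
      class_names = paste0("c", 1:K))
    expect_equal(rep_all$micro_accuracy, 100 * sum(diag(cm)) / total,
                 tolerance = 1e-9)
  }
})

test_that("empty classes are flagged rather than dividing by zero", {
  cm <- matrix(0L, 3, 3); cm[1, 1] <- 5; cm[2, 2] <- 3
  m <- class_metrics(cm, 2)
  expect_true(m$degenerate)
  expect_equal(m$precision, 0)
  expect_equal(m$recall, 0)
  expect_equal(m$f1, 0)
})

test_that("class metrics agree with an independent reference on random matrices", {
  skip_if_not_installed("caret")
  set.seed(33)
  for (rep in 1:1000) {
    K <- sample(2:6, 1)
    cm <- matrix(rpois(K * K, sample(1:20, 1)), K, K)
    if (sum(cm) == 0) next
    # rebuild label vectors realizing the matrix, then recount independently
    true <- unlist(lapply(seq_len(K), function(i) rep(i, sum(cm[i, ]))))
    pred <- unlist(lapply(seq_len(K), function(i)
      rep(seq_len(K), times = cm[i, ])))
    k <- sample(K, 1)
    m <- class_metrics(cm, k - 1L)
    tp <- sum(true == k & pred == k); fp <- sum(true != k & pred == k)
    fn <- sum(true == k & pred != k); tn <- sum(true != k & pred != k)
    expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(tp, fp, fn, tn))
    if (rep <= 50 && !(K == 2 && k == 2)) {  # cross-check a subsample against caret
      # (caret reports the binary case for its positive class only)
      cc <- caret::confusionMatrix(factor(pred, levels = seq_len(K)),
                                   factor(true, levels = seq_len(K)))
      ref <- cc$byClass
      if (K == 2) ref <- matrix(ref, 1, dimnames = list("Class: 1", names(ref)))
      expect_equal(m$recall, 100 * unname(ref[k, "Sensitivity"]),
                   tolerance = 1e-9)
      expect_equal(m$specificity, 100 * unname(ref[k, "Specificity"]),
                   tolerance = 1e-9)
      if (!is.na(ref[k, "Precision"]))
        expect_equal(m$precision, 100 * unname(ref[k, "Precision"]),
                     tolerance = 1e-9)
    }
  }
})

test_that("macro averaging reproduces a published-style summary table", {
  # per-class rows of a six-behavior evaluation (percent)
  tab <- data.frame(
    accuracy    = c(98.75, 98.83, 98.67, 99.67, 99.75, 99.33),
    precision   = c(96.50, 93.00, 98.50, 99.50, 99.00, 98.50),
    recall      = c(96.00, 100.00, 93.80, 98.50, 99.50, 97.50),
    specificity = c(99.30, 98.80, 99.70, 99.90, 99.80, 99.70),
    f1          = c(96.20, 96.37, 96.10, 99.00, 99.20, 98.00))
  tab$tpr <- tab$recall; tab$fpr <- 100 - tab$specificity
  avg <- macro_average(tab)
  expect_equal(round_half_up(avg$accuracy, 2), 99.17)
  expect_equal(round_half_up(avg$precision, 2), 97.50)   # the mAP
  expect_equal(round_half_up(avg$recall, 2), 97.55)
  expect_equal(round_half_up(avg$specificity, 2), 99.53)
  expect_equal(round_half_up(avg$f1, 2), 97.48)
  # identical per-class rows average to themselves
  same <- tab[rep(2, 4), ]
  expect_equal(macro_average(same)$precision, 93.00)
})

test_that("the F1 harmonic mean reproduces known precision/recall pairs", {
  f1 <- function(p, r) 2 * p * r / (p + r)
  expect_equal(round_half_up(f1(93.00, 100.00), 2), 96.37)
  expect_equal(round_half_up(f1(98.50, 97.50), 2), 98.00)
})

test_that("PR curves match brute-force threshold enumeration", {
  scores <- c(0.9, 0.8, 0.7, 0.45, 0.3, 0.1)
  labels <- c(1, 1, 0, 1, 0, 0)
  cv <- pr_curve(scores, labels)
  # oracle: enumerate every threshold by hand
  for (i in seq_along(cv$points$threshold)) {
    th <- cv$points$threshold[i]
    pred <- scores >= th
    tp <- sum(pred & labels == 1)
    expect_equal(cv$points$precision[i], tp / sum(pred))
    expect_equal(cv$points$recall[i], tp / sum(labels == 1))
  }
  # perfectly separated scores balance at precision = recall = 1
  sep <- pr_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(sep$bep, 1)
  expect_equal(sep$f1_at_bep, sep$bep)   # F1 of equal P and R is that value
  expect_warning(deg <- pr_curve(c(0.5, 0.6), c(1, 1)), "single class")
  expect_true(deg$degenerate)
})

test_that("ROC curves and AUC behave like the standard definition", {
  skip_if_not_installed("pROC")
  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$points$fpr[1], 0)
  expect_equal(perfect$points$tpr[nrow(perfect$points)], 1)

  set.seed(35)
  scores <- rnorm(300)
  labels <- rbinom(300, 1, 0.4)
  ours <- roc_curve(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-9)
  # reversing the score sign mirrors the AUC
  expect_equal(roc_curve(-scores, labels)$auc, 1 - ours, tolerance = 1e-9)
})

test_that("label-independent scores give AUC 1/2 at n = 10^4", {
  set.seed(36)
  n <- 1e4
  scores <- runif(n)
  labels <- rbinom(n, 1, 0.5)
  expect_lt(abs(roc_curve(scores, labels)$auc - 0.5), 0.02)
})

test_that("macro and micro ROC averaging track the per-class curves", {
  set.seed(37)
  K <- 4; n <- 400
  labels <- sample(0:(K - 1), n, replace = TRUE)
  # well-separated synthetic scores
  raw <- matrix(rnorm(K * n), K, n) + 2.5 * (rep(0:(K - 1), n) ==
                                               rep(labels, each = K))
  scores <- apply(raw, 2, softmax)
  mc <- roc_multiclass(scores, labels)
  aucs <- vapply(mc$per_class, function(cv) cv$auc, 0)
  expect_true(all(aucs > 0.9))
  expect_equal(mc$macro$auc, mean(aucs), tolerance = 0.02)
  expect_gt(mc$micro$auc, 0.9)
  expect_lte(mc$macro$auc, 1)
  # degenerate scores: identical for every class -> AUC near 1/2
  flat <- matrix(1 / K, K, n)
  mc2 <- roc_multiclass(flat + matrix(rnorm(K * n, sd = 1e-3), K, n), labels)
  expect_lt(abs(mc2$micro$auc - 0.5), 0.05)
})

test_that("reports are internally consistent and land on disk", {
  set.seed(38)
  true <- sample(0:5, 300, replace = TRUE)
  pred <- ifelse(runif(300) < 0.8, true, sample(0:5, 300, replace = TRUE))
  rep1 <- metric_report(true, pred)
  expect_equal(sum(rep1$confusion), 300)
  expect_equal(rep1$macro$precision, mean(rep1$per_class$precision))
  dir <- withr::local_tempdir()
  paths <- write_report(rep1, dir)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths["json"])
  expect_equal(js$mAP, round_half_up(rep1$macro$precision, 2))
})
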