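# Multiclass evaluation: confusion matrices, one-vs-rest per-class metrics,
# macro averaging, PR curves with balance point, ROC curves with macro/micro
# averaging and AUC.

#' Confusion matrix from label vectors
#'
#' @param true,predicted integer class ids in `0..K-1`, equal length.
#' @param n_classes K.
#' @param class_names optional dimnames.
#' @return K x K integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(true, predicted, n_classes,
                             class_names = NULL) {
  true <- as.integer(true); predicted <- as.integer(predicted)
  if (length(true) != length(predicted))
    stopf("label vectors differ in length (%d vs %d)", length(true), length(predicted))
  bad <- which(true < 0L | true >= n_classes | predicted < 0L | predicted >= n_classes)
  if (length(bad))
    stopf("label out of range 0..%d at index %d", n_classes - 1L, bad[1])
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(true))
    cm[true[i] + 1L, predicted[i] + 1L] <- cm[true[i] + 1L, predicted[i] + 1L] + 1L
  if (!is.null(class_names)) dimnames(cm) <- list(true = class_names,
                                                  predicted = class_names)
  cm
}

#' Per-class one-vs-rest metrics
#'
#' Reduces the confusion matrix to the class-k binary problem (Tp = diagonal
#' cell, Fn = rest of the row, Fp = rest of the column, Tn = everything else,
#' Sumd = total) and evaluates, as percentages: accuracy (Tp+Tn)/Sumd, recall
#' (true-positive rate) Tp/(Tp+Fn), precision Tp/(Tp+Fp), false-positive rate
#' Fp/(Fp+Tn), specificity Tn/(Fp+Tn), and F1 = 2PR/(P+R). Zero-denominator
#' cases yield 0 with `degenerate = TRUE`.
#'
#' @param cm confusion matrix (rows = true).
#' @param k class index, 0-based.
#' @return one-row data frame with the metric columns, the raw counts, and a
#'   `degenerate` flag.
#' @export
class_metrics <- function(cm, k) {
  K <- nrow(cm)
  if (k < 0L || k >= K) stopf("class index %d out of range 0..%d", k, K - 1L)
  i <- k + 1L
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  total <- sum(cm)
  tn <- total - tp - fn - fp
  safe <- function(num, den) if (den > 0) 100 * num / den else 0
  degenerate <- (tp + fn) == 0 || (fp + tn) == 0 || (tp + fp) == 0
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  data.frame(class = k,
             accuracy = safe(tp + tn, total),
             precision = precision,
             recall = recall,
             tpr = recall,
             fpr = safe(fp, fp + tn),
             specificity = safe(tn, fp + tn),
             f1 = f1,
             tp = tp, tn = tn, fp = fp, fn = fn, sumd = total,
             degenerate = degenerate)
}

#' Macro average of per-class metrics
#'
#' Arithmetic mean of each metric column across classes. The macro-averaged
#' precision at argmax decisions is what this evaluation protocol reports as
#' mAP.
#'
#' @param per_class data frame of [class_metrics()] rows.
#' @return one-row data frame of averaged metrics.
#' @export
macro_average <- function(per_class) {
  cols <- c("accuracy", "precision", "recall", "tpr", "fpr", "specificity", "f1")
  out <- as.data.frame(as.list(colMeans(per_class[, cols, drop = FALSE])))
  out
}

#' Full evaluation report
#'
#' @param true,predicted 0-based label vectors.
#' @param class_names class names in label order.
#' @return list of class `pbatn_report`: `confusion` (K x K), `per_class`
#'   data frame, `macro` (one row; its `precision` is the mAP), and
#'   `micro_accuracy` (trace / total, in percent).
#' @export
metric_report <- function(true, predicted, class_names = behavior_classes()) {
  K <- length(class_names)
  cm <- confusion_matrix(true, predicted, K, class_names)
  per_class <- do.call(rbind, lapply(0:(K - 1L), function(k) class_metrics(cm, k)))
  per_class$class_name <- class_names
  structure(list(confusion = cm,
                 per_class = per_class,
                 macro = macro_average(per_class),
                 micro_accuracy = 100 * sum(diag(cm)) / sum(cm),
                 n = sum(cm)),
            class = "pbatn_report")
}

#' @export
print.pbatn_report <- function(x, ...) {
  cat(sprintf("<evaluation of %d clips>\n", x$n))
  cols <- c("class_name", "accuracy", "precision", "recall", "specificity", "f1")
  tab <- x$per_class[, cols]
  tab[-1] <- lapply(tab[-1], round_half_up, 2)
  print(tab, row.names = FALSE)
  m <- round_half_up(unlist(x$macro[c("accuracy", "precision", "recall",
                                      "specificity", "f1")]), 2)
  cat(sprintf("macro: accuracy %.2f  precision (mAP) %.2f  recall %.2f  specificity %.2f  F1 %.2f\n",
              m[1], m[2], m[3], m[4], m[5]))
  cat(sprintf("micro accuracy: %.2f\n", round_half_up(x$micro_accuracy, 2)))
  invisible(x)
}

## ---- threshold curves ------------------------------------------------------

binary_counts <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- as.integer(labels[ord])
  # unique descending thresholds; counts at ">= threshold"
  dup <- rev(duplicated(rev(s)))
  tp <- cumsum(y)[!dup]
  n_pred <- seq_along(y)[!dup]
  list(thr = s[!dup], tp = tp, fp = n_pred - tp,
       pos = sum(y), neg = length(y) - sum(y))
}

#' Precision-recall curve with balance point
#'
#' Sweeps every distinct score as a decision threshold (predict positive at
#' `score >= threshold`), records (recall, precision) points, and locates the
#' balance point (BEP) where precision equals recall, interpolating linearly
#' between the bracketing thresholds. At the BEP the F1 score equals the
#' common precision = recall value.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (0/1 or logical).
#' @return list of class `pbatn_curve`: `points` data frame (threshold,
#'   recall, precision), `bep`, `f1_at_bep`, `auc` (trapezoidal area under
#'   precision over recall), `degenerate` flag.
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (!all(is.finite(scores))) stopf("scores must be finite")
  if (length(unique(labels)) < 2L) {
    warnf("labels contain a single class; PR curve is degenerate")
    return(structure(list(points = NULL, bep = NA_real_, f1_at_bep = NA_real_,
                          auc = NA_real_, degenerate = TRUE),
                     class = "pbatn_curve"))
  }
  b <- binary_counts(scores, labels)
  precision <- b$tp / pmax(b$tp + b$fp, 1L)
  recall <- b$tp / b$pos
  pts <- data.frame(threshold = b$thr, recall = recall, precision = precision)
  d <- precision - recall
  bep <- if (any(d == 0)) {
    precision[which(d == 0)[1]]
  } else {
    cross <- which(d[-1] * d[-length(d)] < 0)
    if (!length(cross)) {
      i <- which.min(abs(d)); precision[i]
    } else {
      i <- cross[1]
      w <- d[i] / (d[i] - d[i + 1])
      (1 - w) * precision[i] + w * precision[i + 1]
    }
  }
  auc <- trapezoid(recall, precision)
  structure(list(points = pts, bep = bep, f1_at_bep = bep, auc = auc,
                 degenerate = FALSE),
            class = "pbatn_curve")
}

trapezoid <- function(x, y) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' ROC curve and AUC
#'
#' Sweeps thresholds over the scores, recording (false-positive rate,
#' true-positive rate) points anchored at (0,0) and (1,1), with trapezoidal
#' area under the curve.
#'
#' @inheritParams pr_curve
#' @return list of class `pbatn_curve` with `points` (threshold, fpr, tpr)
#'   and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (!all(is.finite(scores))) stopf("scores must be finite")
  if (length(unique(labels)) < 2L) {
    warnf("labels contain a single class; ROC curve is degenerate")
    return(structure(list(points = NULL, auc = NA_real_, degenerate = TRUE),
                     class = "pbatn_curve"))
  }
  b <- binary_counts(scores, labels)
  pts <- data.frame(threshold = c(Inf, b$thr),
                    fpr = c(0, b$fp / b$neg),
                    tpr = c(0, b$tp / b$pos))
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1)
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  structure(list(points = pts, auc = trapezoid(pts$fpr, pts$tpr),
                 degenerate = FALSE),
            class = "pbatn_curve")
}

#' Multiclass ROC with macro and micro averaging
#'
#' One-vs-rest ROC per class, a macro-averaged curve (per-class true-positive
#' rates linearly interpolated onto the union grid of false-positive rates,
#' then averaged), and a micro-averaged curve (all one-vs-rest decisions
#' pooled into one binary problem).
#'
#' @param scores K x n matrix of class scores (columns = clips).
#' @param labels 0-based true labels, length n.
#' @return list with `per_class` (list of [roc_curve()]s), `macro` (points +
#'   auc) and `micro` ([roc_curve()]).
#' @export
roc_multiclass <- function(scores, labels) {
  K <- nrow(scores)
  per_class <- lapply(0:(K - 1L), function(k)
    roc_curve(scores[k + 1L, ], labels == k))
  grid <- sort(unique(unlist(lapply(per_class, function(cv)
    if (!cv$degenerate) cv$points$fpr))))
  tprs <- vapply(per_class, function(cv) {
    if (cv$degenerate) return(rep(NA_real_, length(grid)))
    approx(cv$points$fpr, cv$points$tpr, xout = grid, ties = max,
           rule = 2)$y
  }, numeric(length(grid)))
  macro_tpr <- rowMeans(tprs, na.rm = TRUE)
  onehot <- as.integer(rep(0:(K - 1L), times = length(labels)) ==
                         rep(labels, each = K))
  micro <- roc_curve(as.numeric(scores), onehot)
  list(per_class = per_class,
       macro = list(points = data.frame(fpr = grid, tpr = macro_tpr),
                    auc = trapezoid(grid, macro_tpr)),
       micro = micro)
}

## ---- report writers --------------------------------------------------------

#' Write an evaluation report to CSV and JSON
#'
#' @param report a [metric_report()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cols <- c("class_name", "accuracy", "precision", "recall", "fpr",
            "specificity", "f1", "tp", "tn", "fp", "fn")
  tab <- report$per_class[, cols]
  num <- vapply(tab, is.numeric, TRUE) & names(tab) %in%
    c("accuracy", "precision", "recall", "fpr", "specificity", "f1")
  tab[num] <- lapply(tab[num], round_half_up, 2)
  macro <- cbind(class_name = "macro_average",
                 as.data.frame(lapply(report$macro[c("accuracy", "precision",
                   "recall", "fpr", "specificity", "f1")], round_half_up, 2)),
                 tp = NA, tn = NA, fp = NA, fn = NA)
  csv <- file.path(dir, "metrics.csv")
  write.csv(rbind(tab, macro), csv, row.names = FALSE)
  js <- file.path(dir, "metrics.json")
  jsonlite::write_json(
    list(per_class = tab, macro = macro[-1],
         micro_accuracy = round_half_up(report$micro_accuracy, 2),
         mAP = round_half_up(report$macro$precision, 2),
         confusion = report$confusion, n = report$n),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv = csv, json = js))
}

#' Plot helpers for curves and confusion matrices
#'
#' @param curves output of [roc_multiclass()] or a list of per-class
#'   [pr_curve()]s; `cm` a confusion matrix.
#' @param class_names class names for the legend.
#' @return a ggplot object.
#' @export
plot_roc_curves <- function(curves, class_names = behavior_classes()) {
  dfs <- lapply(seq_along(curves$per_class), function(i) {
    cv <- curves$per_class[[i]]
    if (cv$degenerate) return(NULL)
    cbind(cv$points[, c("fpr", "tpr")], class = class_names[i])
  })
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   color = .data$class)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey") +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = "One-vs-rest ROC curves") +
    ggplot2::theme_minimal()
}

#' @rdname plot_roc_curves
#' @export
plot_pr_curves <- function(curves, class_names = behavior_classes()) {
  dfs <- lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    if (cv$degenerate) return(NULL)
    cbind(cv$points[, c("recall", "precision")], class = class_names[i])
  })
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision,
                                   color = .data$class)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "Recall", y = "Precision", title = "PR curves") +
    ggplot2::theme_minimal()
}

#' @rdname plot_roc_curves
#' @param cm confusion matrix.
#' @export
plot_confusion <- function(cm, class_names = behavior_classes()) {
  df <- expand.grid(true = class_names, predicted = class_names)
  df$count <- as.vector(cm)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), color = "white") +
    ggplot2::scale_y_discrete(limits = rev(class_names)) +
    ggplot2::labs(title = "Confusion matrix") +
    ggplot2::theme_minimal()
}
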