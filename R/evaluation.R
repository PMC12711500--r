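#' Confusion matrix with one-vs-rest marginals
#'
#' Rows are true classes, columns predicted classes. Per-class TP/FP/FN/TN
#' are derived by one-vs-rest marginalization.
#'
#' @param truth,pred Equal-length integer label vectors (1-based) or
#'   factors.
#' @param n_classes Number of classes K; defaults to the largest label seen.
#' @param labels Optional class names (length K).
#' @return An object of class `confusion_matrix`: list with `table` (K x K
#'   integer matrix), `tp`, `fp`, `fn`, `tn`, `n`.
#' @export
confusion_matrix <- function(truth, pred, n_classes = NULL, labels = NULL) {
  if (is.factor(truth)) {
    labels <- labels %||% levels(truth)
    truth <- as.integer(truth)
  }
  if (is.factor(pred)) pred <- as.integer(pred)
  if (length(truth) != length(pred)) {
    stop_caspnet("'truth' and 'pred' must have the same length")
  }
  k <- n_classes %||% max(truth, pred)
  if (any(truth < 1 | truth > k) || any(pred < 1 | pred > k)) {
    stop_caspnet(sprintf("labels must lie in [1, %d]", k))
  }
  tab <- matrix(0L, k, k)
  for (i in seq_along(truth)) {
    tab[truth[i], pred[i]] <- tab[truth[i], pred[i]] + 1L
  }
  if (!is.null(labels)) dimnames(tab) <- list(true = labels, pred = labels)
  new_confusion_matrix(tab)
}

new_confusion_matrix <- function(tab) {
  tp <- diag(tab)
  fp <- colSums(tab) - tp
  fn <- rowSums(tab) - tp
  n <- sum(tab)
  structure(list(table = tab, tp = tp, fp = fp, fn = fn,
                 tn = n - tp - fp - fn, n = n),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix (%d samples, %d classes; rows = truth)\n",
              x$n, nrow(x$table)))
  print(x$table)
  invisible(x)
}

#' @export
as.matrix.confusion_matrix <- function(x, ...) x$table

#' @export
plot.confusion_matrix <- function(x, ...) {
  k <- nrow(x$table)
  image(seq_len(k), seq_len(k), t(x$table[k:1, , drop = FALSE]),
        col = gray(seq(1, 0.2, length.out = 32)), axes = FALSE,
        xlab = "predicted", ylab = "true", main = "confusion matrix")
  nms <- colnames(x$table) %||% seq_len(k)
  axis(1, seq_len(k), nms, las = 2, cex.axis = 0.7)
  axis(2, seq_len(k), rev(nms), las = 2, cex.axis = 0.7)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      text(j, k - i + 1, x$table[i, j], cex = 0.8)
    }
  }
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Overall accuracy is `trace / total`. Per class: precision
#' `TP / (TP + FP)`, recall `TP / (TP + FN)`, F1 `2PR / (P + R)`; undefined
#' 0/0 ratios are reported as 0 with a warning. "Per-class accuracy" is the
#' class's recall (the reading under which a per-class accuracy table is
#' consistent with per-class false-negative counts); set
#' `per_class_accuracy = "ovr"` for the one-vs-rest binary-accuracy variant
#' `(TP + TN) / n` instead. Macro averages are unweighted means; weighted
#' averages use the true-class support.
#'
#' @param cm A [confusion_matrix()].
#' @param per_class_accuracy `"recall"` (default) or `"ovr"`.
#' @return An object of class `metrics_report`.
#' @export
compute_metrics <- function(cm, per_class_accuracy = c("recall", "ovr")) {
  stopifnot(inherits(cm, "confusion_matrix"))
  per_class_accuracy <- match.arg(per_class_accuracy)
  if (cm$n == 0L) stop_caspnet("empty confusion matrix")
  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) {
      warning(sprintf("%s undefined (0/0) for %d class(es); reported as 0",
                      what, sum(bad)), call. = FALSE)
    }
    ifelse(bad, 0, num / den)
  }
  precision <- safe_div(cm$tp, cm$tp + cm$fp, "precision")
  recall <- safe_div(cm$tp, cm$tp + cm$fn, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "F1")
  support <- rowSums(cm$table)
  w <- support / sum(support)
  per_acc <- if (per_class_accuracy == "recall") {
    recall
  } else {
    (cm$tp + cm$tn) / cm$n
  }
  structure(list(
    accuracy = sum(diag(cm$table)) / cm$n,
    precision = precision, recall = recall, f1 = f1,
    per_class_accuracy = per_acc, support = support,
    macro = c(precision = mean(precision), recall = mean(recall),
              f1 = mean(f1)),
    weighted = c(precision = sum(w * precision), recall = sum(w * recall),
                 f1 = sum(w * f1)),
    class_names = colnames(cm$table) %||%
      as.character(seq_along(cm$tp))), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("overall accuracy: %.2f%%\n", 100 * x$accuracy))
  df <- data.frame(class = x$class_names,
                   precision = round(x$precision, digits),
                   recall = round(x$recall, digits),
                   f1 = round(x$f1, digits),
                   accuracy = round(x$per_class_accuracy, digits),
                   support = x$support)
  print(df, row.names = FALSE)
  cat(sprintf("macro    P/R/F1: %.4f / %.4f / %.4f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  cat(sprintf("weighted P/R/F1: %.4f / %.4f / %.4f\n",
              x$weighted["precision"], x$weighted["recall"],
              x$weighted["f1"]))
  invisible(x)
}

#' One-vs-rest ROC curves and AUC
#'
#' For each class, sweeps all distinct score thresholds (descending, ties
#' grouped), computing TPR = TP/(TP+FN) and FPR = FP/(FP+TN); AUC by
#' trapezoidal integration. A class absent from the truth has undefined AUC
#' (`NA`, excluded from the macro average).
#'
#' @param scores `(n, K)` matrix of class probabilities (rows summing to 1
#'   within 1e-6).
#' @param truth Integer labels in `1..K` or a factor.
#' @return An object of class `roc_curve`: per-class list of `fpr`, `tpr`,
#'   `thresholds`, `auc`; plus `auc` vector and `macro_auc`.
#' @export
roc_auc <- function(scores, truth) {
  if (is.factor(truth)) truth <- as.integer(truth)
  scores <- as.matrix(scores)
  if (nrow(scores) != length(truth)) {
    stop_caspnet("one truth label per score row required")
  }
  if (any(abs(rowSums(scores) - 1) > 1e-6)) {
    stop_caspnet("score rows must sum to 1")
  }
  k <- ncol(scores)
  per_class <- vector("list", k)
  aucs <- rep(NA_real_, k)
  for (ci in seq_len(k)) {
    pos <- truth == ci
    n_pos <- sum(pos)
    n_neg <- sum(!pos)
    if (n_pos == 0L) {
      per_class[[ci]] <- list(fpr = NULL, tpr = NULL, thresholds = NULL,
                              auc = NA_real_)
      next
    }
    s <- scores[, ci]
    thr <- sort(unique(s), decreasing = TRUE)
    tpr <- numeric(length(thr) + 2L)
    fpr <- numeric(length(thr) + 2L)
    tpr[1] <- 0
    fpr[1] <- 0
    for (ti in seq_along(thr)) {
      pred_pos <- s >= thr[ti]
      tpr[ti + 1L] <- sum(pred_pos & pos) / n_pos
      fpr[ti + 1L] <- if (n_neg > 0) sum(pred_pos & !pos) / n_neg else 0
    }
    tpr[length(tpr)] <- 1
    fpr[length(fpr)] <- 1
    auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    per_class[[ci]] <- list(fpr = fpr, tpr = tpr,
                            thresholds = c(Inf, thr, -Inf), auc = auc)
    aucs[ci] <- auc
  }
  structure(list(per_class = per_class, auc = aucs,
                 macro_auc = mean(aucs, na.rm = TRUE)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("one-vs-rest ROC\n")
  for (ci in seq_along(x$auc)) {
    cat(sprintf("  class %d: AUC %s\n", ci,
                ifelse(is.na(x$auc[ci]), "undefined (absent from truth)",
                       sprintf("%.4f", x$auc[ci]))))
  }
  cat(sprintf("  macro AUC: %.4f\n", x$macro_auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(c(0, 1), c(0, 1), type = "n", xlab = "FPR", ylab = "TPR",
       main = "one-vs-rest ROC")
  abline(0, 1, lty = 3)
  for (ci in seq_along(x$per_class)) {
    pc <- x$per_class[[ci]]
    if (!is.null(pc$fpr)) lines(pc$fpr, pc$tpr, col = ci)
  }
  invisible(x)
}

#' Ablation report over model variants
#'
#' Builds each variant, counts parameters and FLOPs, and (optionally)
#' trains and evaluates it on the supplied dataset. The accounting columns
#' never require training.
#'
#' @param variants Character vector of variant names.
#' @param config An [arch_config()] shared by all variants.
#' @param data Optional list with `train`, `val`, `test` entries (each an
#'   `image_set` or `list(images, labels)`) used when `train = TRUE`.
#' @param train Logical; fit each variant and report test accuracy.
#' @param train_config A [training_config()] for the optional training.
#' @param steps Optional cap on optimizer steps per variant.
#' @param seed Seed for weight initialization.
#' @return A data.frame (class `ablation_report`) with columns `variant`,
#'   `params` (raw count), `params_millions`, `flops`, `test_accuracy`,
#'   `train_seconds`.
#' @export
ablation_report <- function(variants = c("full", "vit_only",
                                         "csp_sppf_only", "vit_csp"),
                            config = arch_config(), data = NULL,
                            train = FALSE,
                            train_config = training_config(),
                            steps = NULL, seed = 1L) {
  if (length(variants) == 0L) stop_caspnet("no variants given")
  rows <- lapply(seq_along(variants), function(i) {
    v <- variants[i]
    model <- caspnet(variant = v, config = config,
                     seed = derive_seed(seed, i))
    acc <- NA_real_
    secs <- NA_real_
    if (train && !is.null(data)) {
      t0 <- proc.time()[3]
      fit <- caspnet_train(model, data$train, val = data$val,
                           config = train_config, steps = steps)
      secs <- proc.time()[3] - t0
      test <- prepare_train_data(data$test, config$image_size)
      imgs <- if (test$preprocessed) {
        test$images
      } else {
        arr <- array(0, c(config$image_size, config$image_size, 3L,
                          length(test$labels)))
        for (j in seq_along(test$raw)) {
          arr[, , , j] <- eval_transform(test$raw[[j]],
                                         size = config$image_size)
        }
        arr
      }
      lg <- batched_logits(fit$best_model, imgs)
      acc <- 100 * mean(max.col(lg, ties.method = "first") == test$labels)
    }
    data.frame(variant = v,
               params = count_parameters(model),
               params_millions = round(count_parameters(model) / 1e6, 3),
               flops = count_flops(model),
               test_accuracy = acc, train_seconds = secs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ablation_report", class(out))
  out
}
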