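test_that("confusion matrix counts match exhaustive enumeration", {
  # 3-class toy: truth (1,1,2,3), preds (1,2,2,3)
  cm <- confusion_matrix(c(1, 1, 2, 3), c(1, 2, 2, 3), n_classes = 3)
  expect_equal(unname(cm$tp), c(1, 1, 1))
  expect_equal(unname(cm$fn), c(1, 0, 0))
  expect_equal(unname(cm$fp), c(0, 1, 0))
  expect_equal(cm$n, 4L)

  # perfect prediction: diagonal matrix
  cmp <- confusion_matrix(1:4, 1:4, n_classes = 4)
  expect_equal(cmp$table, diag(1L, 4), ignore_attr = TRUE)
  expect_equal(sum(cmp$fp) + sum(cmp$fn), 0)

  # conservation: grid total equals the sample count, per-class marginals
  set.seed(55)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    n <- sample(5:80, 1)
    tr <- sample.int(k, n, replace = TRUE)
    pr <- sample.int(k, n, replace = TRUE)
    cm2 <- confusion_matrix(tr, pr, n_classes = k)
    expect_equal(cm2$n, n)
    expect_equal(unname(cm2$tp + cm2$fn), unname(rowSums(cm2$table)))
    expect_equal(unname(cm2$tp + cm2$fp), unname(colSums(cm2$table)))
    expect_equal(unname(cm2$tp + cm2$fp + cm2$fn + cm2$tn), rep(n, k))
  }
  expect_error(confusion_matrix(1:3, 1:2), "length")
})

test_that("metrics agree with per-sample brute force and satisfy identities", {
  set.seed(66)
  for (rep in 1:8) {
    k <- sample(2:5, 1)
    n <- sample(20:200, 1)
    tr <- sample.int(k, n, replace = TRUE)
    # bias predictions toward the truth so every class gets predictions
    pr <- ifelse(runif(n) < 0.7, tr, sample.int(k, n, replace = TRUE))
    cm <- confusion_matrix(tr, pr, n_classes = k)
    mr <- suppressWarnings(compute_metrics(cm))
    for (ci in seq_len(k)) {
      want <- oracle_class_metrics(tr, pr, ci)
      expect_equal(mr$precision[ci], want["precision"], ignore_attr = TRUE,
                   tolerance = 1e-12)
      expect_equal(mr$recall[ci], want["recall"], ignore_attr = TRUE,
                   tolerance = 1e-12)
      expect_equal(mr$f1[ci], want["f1"], ignore_attr = TRUE,
                   tolerance = 1e-12)
    }
    expect_equal(mr$accuracy, mean(tr == pr), tolerance = 1e-12)
    # weighted recall equals overall accuracy; all metrics in [0, 1]
    expect_equal(unname(mr$weighted["recall"]), mr$accuracy,
                 tolerance = 1e-12)
    vals <- c(mr$precision, mr$recall, mr$f1, mr$accuracy,
              mr$macro, mr$weighted)
    expect_true(all(vals >= 0 & vals <= 1))
    expect_lte(mr$macro["f1"], max(mr$f1) + 1e-12)
    # F1 is the harmonic mean of its own P and R
    pos <- mr$precision + mr$recall > 0
    expect_equal(mr$f1[pos], (2 * mr$precision * mr$recall /
                                (mr$precision + mr$recall))[pos],
                 tolerance = 1e-12)
  }
  # perfect diagonal: every metric is one
  mp <- compute_metrics(confusion_matrix(1:3, 1:3, n_classes = 3))
  expect_equal(unname(c(mp$accuracy, mp$precision, mp$recall, mp$f1)),
               rep(1, 10))
  # 0/0 conventions warn and report zero
  cm0 <- confusion_matrix(c(1, 1), c(1, 1), n_classes = 2)
  w <- capture_warnings(m0 <- compute_metrics(cm0))
  expect_true(any(grepl("0/0", w)))   # P, R and F1 each warn once
  expect_equal(m0$precision[2], 0)
})

test_that("per-class accuracy is recall; a 3-FN/80-TP class reads 96.39%", {
  cm <- confusion_matrix(c(rep(1, 83), rep(2, 17)),
                         c(rep(1, 80), rep(2, 3), rep(2, 17)),
                         n_classes = 2)
  mr <- compute_metrics(cm)
  expect_equal(round(100 * mr$per_class_accuracy[1], 2), 96.39)
  expect_equal(mr$per_class_accuracy, mr$recall)
  # the one-vs-rest binary-accuracy variant is available behind the flag
  mo <- compute_metrics(cm, per_class_accuracy = "ovr")
  expect_equal(mo$per_class_accuracy[1], (80 + 17) / 100)
})

test_that("ROC/AUC: trivial orderings, Mann-Whitney oracle, invariances", {
  # perfectly separating scores
  s <- cbind(c(0.9, 0.8, 0.2, 0.1), c(0.1, 0.2, 0.8, 0.9))
  roc <- roc_auc(s, c(1, 1, 2, 2))
  expect_equal(roc$auc, c(1, 1))

  # scores carrying no information sit on the chance diagonal
  s0 <- matrix(0.5, 6, 2)
  roc0 <- roc_auc(s0, c(1, 2, 1, 2, 1, 2))
  expect_equal(roc0$auc, c(0.5, 0.5))

  # 8-sample toy equals exhaustive pairwise comparison counting
  set.seed(77)
  p1 <- runif(8)
  p1[3] <- p1[5]                        # inject a tie
  scores <- cbind(p1, 1 - p1)
  truth <- c(1, 1, 1, 2, 2, 1, 2, 2)
  roc8 <- roc_auc(scores / rowSums(scores) * rowSums(scores), truth)
  expect_equal(roc8$auc[1], oracle_mw_auc(scores[, 1], truth == 1),
               tolerance = 1e-12)
  expect_equal(roc8$auc[2], oracle_mw_auc(scores[, 2], truth == 2),
               tolerance = 1e-12)

  # monotone endpoints and non-decreasing sweep for random scores
  set.seed(78)
  raw <- matrix(runif(60), 20, 3)
  sm <- raw / rowSums(raw)
  tr <- sample.int(3, 20, replace = TRUE)
  rr <- roc_auc(sm, tr)
  for (pc in rr$per_class) {
    expect_true(all(diff(pc$fpr) >= 0))
    expect_true(all(diff(pc$tpr) >= 0))
    expect_equal(c(pc$fpr[1], pc$tpr[1]), c(0, 0))
    expect_equal(c(pc$fpr[length(pc$fpr)], pc$tpr[length(pc$tpr)]),
                 c(1, 1))
    expect_gte(pc$auc, 0)
    expect_lte(pc$auc, 1)
  }

  # AUC is invariant under strictly monotone score transforms
  mono <- sm^3
  mono <- mono / rowSums(mono)
  # (renormalizing by row breaks per-column monotonicity in general, so
  # compare through the sweep on a single class's transformed scores)
  one_class_auc <- function(score, pos) {
    sc <- cbind(score, 1 - score)
    roc_auc(sc / rowSums(sc), ifelse(pos, 1, 2))$auc[1]
  }
  score <- sm[, 1] / 2                 # keep within (0, 1)
  pos <- tr == 1
  expect_equal(one_class_auc(score, pos),
               one_class_auc(pmin(0.999, exp(score) / 3), pos),
               tolerance = 1e-12)

  # a class absent from the truth is reported as missing
  rmiss <- roc_auc(sm, ifelse(tr == 3, 1, tr))
  expect_true(is.na(rmiss$auc[3]))
  expect_false(is.na(rmiss$macro_auc))
  expect_error(roc_auc(raw, tr), "sum to 1")
})

test_that("ablation report accounts without training", {
  rep_ <- ablation_report(config = tiny_cfg(), seed = 3L)
  expect_equal(nrow(rep_), 4L)
  expect_equal(rep_$variant,
               c("full", "vit_only", "csp_sppf_only", "vit_csp"))
  expect_true(all(rep_$params_millions > 0))
  expect_true(all(rep_$flops > 0))
  expect_true(all(is.na(rep_$test_accuracy)))   # accounting-only mode
  # full-minus-vit_csp difference equals the SPPF component sum
  m_full <- tiny_model("full")
  sppf_n <- sum(vapply(caspnet:::flatten_params(m_full$params["sppf"]),
                       length, numeric(1)))
  expect_equal(rep_$params[1] - rep_$params[4], sppf_n)
  expect_error(ablation_report(variants = character(0)), "no variants")
  expect_error(ablation_report(variants = "nope", config = tiny_cfg()),
               "valid variants")
})
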