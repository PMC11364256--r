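# Open-set metric suite against direct enumeration and pairwise-count
# oracles, plus the fixed worked example used throughout.

# 5-record worked example: three knowns (two correctly classified), two
# unknowns; at delta = 0.5 exactly one known is correct AND accepted.
example_records <- function() {
  make_eval_records(labels = c("0", "1", "1", "poor_quality", "novel_category"),
                    predictions = c(0L, 0L, 1L, 0L, 0L),
                    scores = c(2.0, 1.5, 0.4, 0.3, 1.8))
}

test_that("accuracies match the worked example", {
  rec <- example_records()
  expect_equal(closed_set_accuracy(rec), 2 / 3)
  expect_equal(full_set_accuracy(rec, 0.5), 2 / 5)
  r <- tpr_fpr(rec, 0.5)
  expect_equal(r$tpr, 2 / 3)
  expect_equal(r$fpr, 1 / 2)
  expect_equal(r$balanced_accuracy, 7 / 12)
  expect_equal(openecho:::oscr_at(rec, 0.5), 1 / 3)
  # unknowns are ignored entirely by the closed-set accuracy
  rec_known_only <- rec[!rec$unknown, ]
  expect_equal(closed_set_accuracy(rec_known_only), 2 / 3)
  # limiting thresholds
  expect_equal(full_set_accuracy(rec, -Inf), 2 / 5) # closed-correct / total
  expect_equal(full_set_accuracy(rec, Inf), 2 / 5)  # unknown fraction
  expect_equal(unlist(tpr_fpr(rec, -Inf)), c(tpr = 1, fpr = 1,
                                             balanced_accuracy = 0.5))
  expect_equal(unlist(tpr_fpr(rec, Inf)), c(tpr = 0, fpr = 0,
                                            balanced_accuracy = 0.5))
  expect_error(closed_set_accuracy(rec[rec$unknown, ]), "known")
})

test_that("OSCR is dominated by TPR and reaches 1 for a perfect scorer", {
  rec <- example_records()
  for (d in c(-Inf, sort(rec$score), Inf)) {
    expect_lte(openecho:::oscr_at(rec, d), tpr_fpr(rec, d)$tpr)
  }
  perfect <- make_eval_records(labels = c("0", "1", "poor_quality"),
                               predictions = c(0L, 1L, 0L),
                               scores = c(5, 4, 1))
  expect_equal(oscr_auc(perfect), 1.0)
  curve <- oscr_curve(perfect)
  expect_equal(range(curve$fpr), c(0, 1))
})

test_that("unknown-view ROC-AUC equals the Mann-Whitney pair count", {
  sep <- make_eval_records(c("0", "1", "poor_quality", "multiple_views"),
                           c(0L, 1L, 0L, 0L), c(3, 2, 1, 0))
  expect_equal(unknown_roc_auc(sep), 1.0)
  tied <- make_eval_records(c("0", "1", "poor_quality"), c(0L, 1L, 0L),
                            c(1, 1, 1))
  expect_equal(unknown_roc_auc(tied), 0.5)
  set.seed(8)
  for (i in 1:20) {
    rec <- random_records(i + 300)
    expect_equal(unknown_roc_auc(rec), oracle_unknown_roc_auc(rec))
  }
})

test_that("one-vs-one ROC-AUC follows the pair-averaged construction", {
  # two classes, class-0 score perfectly ranked
  rec <- make_eval_records(c("0", "0", "1", "1"), c(0L, 0L, 1L, 1L),
                           rep(1, 4))
  cs <- rbind(c(5, 0), c(4, 0), c(1, 5), c(0, 4))
  expect_equal(ovo_roc_auc(rec, cs), 1.0)
  # scores independent of label (all tied) -> 0.5
  cs_tied <- matrix(1, 4, 2)
  expect_equal(ovo_roc_auc(rec, cs_tied), 0.5)
  set.seed(9)
  for (i in 1:20) {
    rec <- random_records(i + 600)
    cs <- attr(rec, "class_scores")
    expect_equal(suppressWarnings(
      ovo_roc_auc(rec, cs, num_classes = attr(rec, "C"))),
      oracle_ovo_roc_auc(rec, cs))
  }
  one_class <- make_eval_records(c("0", "0"), c(0L, 0L), c(1, 2))
  expect_error(ovo_roc_auc(one_class, matrix(0, 2, 3)), "two known classes")
  # absent classes are skipped from their pairs with a warning
  sparse <- make_eval_records(c("0", "0", "2", "2"), c(0L, 0L, 2L, 2L),
                              rep(1, 4))
  expect_warning(ovo_roc_auc(sparse, matrix(rnorm(12), 4, 3),
                             num_classes = 3), "skipped")
})

test_that("spearman matches the rank formula and rejects degenerate input", {
  expect_equal(spearman(1:3, c(10, 20, 30)), 1.0)
  expect_equal(spearman(1:3, c(3, 2, 1)), -1.0)
  expect_equal(spearman(1:3, c(1, 3, 2)), 0.5) # 1 - 6*2/(3*8)
  expect_error(spearman(1:3, rep(2, 3)), "constant")
  expect_error(spearman(1:3, 1:4), "equal-length")
})

test_that("the open-set confusion matrix partitions all records", {
  rec <- example_records()
  m <- open_confusion_matrix(rec, 0.5, num_classes = 2)
  expect_identical(dim(m), c(3L, 3L))
  expect_equal(sum(m), nrow(rec))
  expect_equal(sum(m[3, ]), 2)     # unknown reference row
  expect_equal(unname(m[3, 3]), 1) # one unknown correctly rejected
  # trace of the known block counts correct-and-accepted knowns
  expect_equal(sum(diag(m)[1:2]), 1)
  all_rejected <- open_confusion_matrix(rec, Inf, num_classes = 2)
  expect_true(all(all_rejected[, 1:2] == 0))
  expect_equal(sum(all_rejected[, 3]), nrow(rec))
})

test_that("per-subcategory ROC equals manual filtering", {
  set.seed(10)
  labels <- c(rep(c("0", "1"), each = 5),
              rep(c("novel_category", "poor_quality", "multiple_views"), 2))
  rec <- make_eval_records(labels,
                           predictions = sample(0:1, 16, replace = TRUE),
                           scores = rnorm(16))
  out <- per_subcategory_roc(rec)
  for (sub in names(out)) {
    manual <- rec[!rec$unknown | rec$subcategory == sub, ]
    expect_equal(out[[sub]]$auc, unknown_roc_auc(manual), info = sub)
  }
  only_poor <- make_eval_records(c("0", "1", "poor_quality"),
                                 c(0L, 1L, 0L), c(3, 2, 1))
  w <- capture_warnings(res <- per_subcategory_roc(only_poor))
  expect_length(w, 2) # one per absent subcategory
  expect_match(w, "skipped", all = TRUE)
  expect_identical(names(res), "poor_quality")
})

test_that("report assembly collects consistent metrics", {
  rec <- example_records()
  rep <- open_set_report(rec, 0.5, num_classes = 2,
                         class_scores = cbind(rec$score, -rec$score))
  expect_equal(rep$closed_set_accuracy, 2 / 3)
  expect_equal(rep$full_set_accuracy, 2 / 5)
  expect_equal(sum(rep$confusion), 5)
  expect_true(rep$oscr_auc >= 0 && rep$oscr_auc <= 1)
  expect_output(print(rep), "closed-set accuracy")
})
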