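# Open-set evaluation metrics: closed/full-set accuracy, accept/reject
# TPR/FPR and balanced accuracy, OSCR curves, one-vs-one and
# known-vs-unknown ROC-AUC, Spearman correlation, open-set confusion
# matrices and report assembly. Acceptance is uniformly "score >= delta".

#' Assemble per-clip evaluation records
#'
#' @param labels True labels: known class ids (integer or their character
#'   form) or unknown subcategory strings (`"novel_category"`,
#'   `"poor_quality"`, `"multiple_views"`, or the collapsed `"outlier"`).
#' @param predictions 0-based predicted class per clip.
#' @param scores Familiarity score per clip (higher = more familiar).
#' @param predicted_quality,true_quality Optional quality scores.
#' @return Data frame of class `eval_records` with columns `clip_id`,
#'   `label`, `unknown`, `subcategory`, `predicted`, `score` (plus the
#'   quality columns when given).
#' @export
make_eval_records <- function(labels, predictions, scores,
                              predicted_quality = NULL,
                              true_quality = NULL) {
  labels <- as.character(labels)
  unknown <- labels %in% c(unknown_labels, "outlier")
  if (any(!is.finite(scores))) stop("scores must be finite")
  out <- data.frame(clip_id = seq_along(labels), label = labels,
                    unknown = unknown,
                    subcategory = ifelse(unknown, labels, NA_character_),
                    predicted = as.integer(predictions),
                    score = as.numeric(scores), stringsAsFactors = FALSE)
  if (!is.null(predicted_quality)) out$predicted_quality <- predicted_quality
  if (!is.null(true_quality)) out$true_quality <- true_quality
  class(out) <- c("eval_records", "data.frame")
  out
}

known_correct <- function(records) {
  !records$unknown & records$predicted == suppressWarnings(as.integer(records$label))
}

#' Closed-set accuracy
#'
#' Prediction accuracy over known views only; unknown-labelled records
#' are omitted entirely.
#'
#' @param records An `eval_records` data frame.
#' @return Accuracy in `[0, 1]`.
#' @export
closed_set_accuracy <- function(records) {
  known <- !records$unknown
  if (!any(known)) stop("closed-set accuracy needs at least one known record")
  mean(known_correct(records)[known])
}

#' Full-set accuracy at a threshold
#'
#' Fraction of all videos that are either known, correctly classified and
#' accepted (`score >= delta`), or unknown and rejected
#' (`score < delta`).
#'
#' @param records An `eval_records` data frame.
#' @param delta Acceptance threshold.
#' @return Accuracy in `[0, 1]`.
#' @export
full_set_accuracy <- function(records, delta) {
  if (nrow(records) == 0) stop("no records")
  acc <- accept_reject(records$score, delta)
  (sum(known_correct(records) & acc) + sum(records$unknown & !acc)) /
    nrow(records)
}

#' Accept/reject TPR, FPR and balanced accuracy at a threshold
#'
#' Positives are accepted knowns; negatives are accepted unknowns
#' (false positives). Balanced accuracy is `(TPR + (1 - FPR)) / 2`.
#'
#' @param records An `eval_records` data frame with at least one known
#'   and one unknown record.
#' @param delta Acceptance threshold.
#' @return List with `tpr`, `fpr`, `balanced_accuracy`.
#' @export
tpr_fpr <- function(records, delta) {
  known <- !records$unknown
  if (!any(known) || all(known))
    stop("tpr_fpr needs both known and unknown records")
  acc <- accept_reject(records$score, delta)
  tpr <- sum(known & acc) / sum(known)
  fpr <- sum(!known & acc) / sum(!known)
  list(tpr = tpr, fpr = fpr, balanced_accuracy = (tpr + 1 - fpr) / 2)
}

oscr_at <- function(records, delta) {
  known <- !records$unknown
  acc <- accept_reject(records$score, delta)
  sum(known_correct(records) & acc) / sum(known)
}

#' Open-set classification rate curve and AUC
#'
#' `oscr_curve()` sweeps the threshold over all values inducing distinct
#' accept/reject partitions and records, per threshold, the false
#' positive rate of accepting unknowns and the fraction of knowns that
#' are correctly classified AND accepted (the OSCR). `oscr_auc()`
#' integrates OSCR over FPR by the trapezoidal rule, with endpoints at
#' FPR 0 and 1.
#'
#' @param records An `eval_records` data frame with knowns and unknowns.
#' @return `oscr_curve()`: data frame with columns `delta`, `fpr`,
#'   `oscr`, sorted by FPR; `oscr_auc()`: scalar in `[0, 1]`.
#' @export
oscr_curve <- function(records) {
  known <- !records$unknown
  if (!any(known) || all(known))
    stop("the OSCR curve needs both known and unknown records")
  cand <- threshold_candidates(records$score)
  fpr <- vapply(cand, function(d) tpr_fpr(records, d)$fpr, numeric(1))
  oscr <- vapply(cand, function(d) oscr_at(records, d), numeric(1))
  o <- order(fpr, oscr)
  data.frame(delta = cand[o], fpr = fpr[o], oscr = oscr[o])
}

#' @rdname oscr_curve
#' @param curve Result of `oscr_curve()` (computed from `records` when
#'   omitted).
#' @export
oscr_auc <- function(records, curve = NULL) {
  if (is.null(curve)) curve <- oscr_curve(records)
  trapz(curve$fpr, curve$oscr)
}

# Mann-Whitney AUC of scores separating positives from negatives; ties
# contribute 1/2.
mann_whitney_auc <- function(scores_pos, scores_neg) {
  np <- length(scores_pos)
  nn <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve and AUC for unknown-view recognition
#'
#' Positives are known views, negatives unknown views; the curve sweeps
#' the acceptance threshold. The AUC equals the Mann-Whitney statistic
#' of the familiarity score separating knowns from unknowns (ties count
#' one half).
#'
#' @param records An `eval_records` data frame with knowns and unknowns.
#' @return `unknown_roc_curve()`: data frame `delta`, `fpr`, `tpr`;
#'   `unknown_roc_auc()`: scalar in `[0, 1]`.
#' @export
unknown_roc_auc <- function(records) {
  known <- !records$unknown
  if (!any(known) || all(known))
    stop("unknown-view ROC needs both known and unknown records")
  mann_whitney_auc(records$score[known], records$score[!known])
}

#' @rdname unknown_roc_auc
#' @export
unknown_roc_curve <- function(records) {
  cand <- threshold_candidates(records$score)
  pts <- lapply(cand, function(d) {
    r <- tpr_fpr(records, d)
    data.frame(delta = d, fpr = r$fpr, tpr = r$tpr)
  })
  out <- do.call(rbind, pts)
  out[order(out$fpr, out$tpr), ]
}

#' One-vs-one multiclass ROC-AUC over known views
#'
#' For every unordered pair of known classes (i, j), the AUC of the
#' class-i score separating class-i from class-j records is averaged
#' with the symmetric class-j AUC; pair values are then averaged
#' unweighted (the Hand-and-Till construction), which keeps the metric
#' agnostic to the class distribution. Ties contribute one half. Classes
#' with no records are skipped from their pairs with a warning.
#'
#' @param records An `eval_records` data frame (unknown records are
#'   ignored).
#' @param class_scores `N x C` matrix of per-class scores (video logits
#'   by default; softmax probabilities give the same value per pair only
#'   up to ranking differences, so the score matrix is explicit).
#' @param num_classes Number of known classes C.
#' @return Scalar in `[0, 1]`.
#' @export
ovo_roc_auc <- function(records, class_scores, num_classes = ncol(class_scores)) {
  known <- !records$unknown
  records <- records[known, , drop = FALSE]
  class_scores <- class_scores[known, , drop = FALSE]
  y <- as.integer(records$label)
  present <- sort(unique(y))
  if (length(present) < 2)
    stop("one-vs-one ROC-AUC needs at least two known classes present")
  missing_cls <- setdiff(seq_len(num_classes) - 1L, present)
  if (length(missing_cls) > 0)
    warning("classes without records skipped from pairing: ",
            paste(missing_cls, collapse = ", "))
  pairs <- utils::combn(present, 2)
  vals <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    sel_i <- y == i
    sel_j <- y == j
    auc_i <- mann_whitney_auc(class_scores[sel_i, i + 1L],
                              class_scores[sel_j, i + 1L])
    auc_j <- mann_whitney_auc(class_scores[sel_j, j + 1L],
                              class_scores[sel_i, j + 1L])
    (auc_i + auc_j) / 2
  })
  mean(vals)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive average
#' ranks); measures how well the relation between two vectors is
#' described by a monotonic function.
#'
#' @param xs,ys Equal-length numeric vectors (length >= 2, neither
#'   constant).
#' @return Correlation in `[-1, 1]`.
#' @export
spearman <- function(xs, ys) {
  if (length(xs) != length(ys) || length(xs) < 2)
    stop("spearman needs two equal-length vectors of length >= 2")
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("spearman is undefined for constant input")
  stats::cor(xs, ys, method = "spearman")
}

#' Open-set confusion matrix
#'
#' `(C + 1) x (C + 1)` counts with rows = reference and columns =
#' prediction; the last row collects unknown reference labels (the three
#' subcategories collapsed) and the last column collects rejections
#' (`score < delta`). Accepted clips land in their predicted class
#' column. Entries sum to the record count.
#'
#' @param records An `eval_records` data frame.
#' @param delta Acceptance threshold.
#' @param num_classes Number of known classes C.
#' @return Integer matrix with dimnames; known classes `0..C-1` plus
#'   `"unknown"`.
#' @export
open_confusion_matrix <- function(records, delta, num_classes) {
  C <- num_classes
  lv <- c(as.character(seq_len(C) - 1L), "unknown")
  m <- matrix(0L, C + 1L, C + 1L, dimnames = list(reference = lv,
                                                  prediction = lv))
  acc <- accept_reject(records$score, delta)
  ref <- rep(C + 1L, nrow(records))
  ref[!records$unknown] <- as.integer(records$label[!records$unknown]) + 1L
  prd <- ifelse(acc, records$predicted + 1L, C + 1L)
  for (i in seq_len(nrow(records))) m[ref[i], prd[i]] <- m[ref[i], prd[i]] + 1L
  m
}

#' Per-subcategory unknown-view ROC
#'
#' For each unknown subcategory, removes the records of the other two
#' subcategories and computes the known-vs-unknown ROC-AUC on the
#' remaining set. Absent subcategories are skipped with a warning.
#'
#' @param records An `eval_records` data frame.
#' @return Named list (per present subcategory) with `auc` and `curve`.
#' @export
per_subcategory_roc <- function(records) {
  out <- list()
  for (sub in unknown_labels) {
    keep <- !records$unknown | records$subcategory == sub
    subrec <- records[keep, , drop = FALSE]
    if (!any(subrec$unknown)) {
      warning("no records for subcategory ", sub, "; skipped")
      next
    }
    out[[sub]] <- list(auc = unknown_roc_auc(subrec),
                       curve = unknown_roc_curve(subrec))
  }
  out
}

#' Assemble a full open-set evaluation report
#'
#' Computes every metric at the supplied threshold plus the
#' threshold-parametrised curves and the open-set confusion matrix.
#'
#' @param records An `eval_records` data frame.
#' @param delta Acceptance threshold (e.g. from
#'   [calibrate_threshold()]).
#' @param num_classes Number of known classes C.
#' @param class_scores Optional `N x C` matrix of per-class scores for
#'   the one-vs-one ROC-AUC (skipped when omitted or when fewer than two
#'   known classes are present).
#' @return An object of class `open_set_report`.
#' @export
open_set_report <- function(records, delta, num_classes,
                            class_scores = NULL) {
  rates <- tpr_fpr(records, delta)
  rep <- list(
    delta = delta,
    n_records = nrow(records),
    closed_set_accuracy = closed_set_accuracy(records),
    full_set_accuracy = full_set_accuracy(records, delta),
    balanced_accuracy = rates$balanced_accuracy,
    tpr = rates$tpr, fpr = rates$fpr,
    unknown_roc_auc = unknown_roc_auc(records),
    oscr_auc = oscr_auc(records),
    oscr_curve = oscr_curve(records),
    unknown_roc_curve = unknown_roc_curve(records),
    confusion = open_confusion_matrix(records, delta, num_classes),
    per_subcategory = tryCatch(per_subcategory_roc(records),
                               warning = function(w) {
                                 suppressWarnings(per_subcategory_roc(records))
                               }))
  if (!is.null(class_scores))
    rep$ovo_roc_auc <- ovo_roc_auc(records, class_scores,
                                   num_classes = num_classes)
  if (!is.null(records$predicted_quality) && !is.null(records$true_quality)) {
    ok <- !is.na(records$predicted_quality) & !is.na(records$true_quality)
    if (sum(ok) >= 2)
      rep$quality_spearman <- spearman(records$predicted_quality[ok],
                                       records$true_quality[ok])
  }
  structure(rep, class = "open_set_report")
}

#' @export
print.open_set_report <- function(x, ...) {
  cat("<open_set_report>\n")
  cat(sprintf("  records: %d, delta = %.6g\n", x$n_records, x$delta))
  cat(sprintf("  closed-set accuracy : %.4f\n", x$closed_set_accuracy))
  cat(sprintf("  full-set accuracy   : %.4f\n", x$full_set_accuracy))
  cat(sprintf("  balanced accuracy   : %.4f (TPR %.4f, FPR %.4f)\n",
              x$balanced_accuracy, x$tpr, x$fpr))
  cat(sprintf("  unknown ROC-AUC     : %.4f\n", x$unknown_roc_auc))
  cat(sprintf("  OSCR-AUC            : %.4f\n", x$oscr_auc))
  if (!is.null(x$ovo_roc_auc))
    cat(sprintf("  one-vs-one ROC-AUC  : %.4f\n", x$ovo_roc_auc))
  for (sub in names(x$per_subcategory))
    cat(sprintf("  ROC-AUC (%s): %.4f\n", sub, x$per_subcategory[[sub]]$auc))
  if (!is.null(x$quality_spearman))
    cat(sprintf("  quality Spearman    : %.4f\n", x$quality_spearman))
  invisible(x)
}
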