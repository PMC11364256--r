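# Independent brute-force oracles for the open-set metrics: plain-loop
# set enumeration and pairwise comparison counting, sharing no code with
# the package implementations they check.

oracle_closed_accuracy <- function(rec) {
  num <- 0L
  den <- 0L
  for (i in seq_len(nrow(rec))) {
    if (!rec$unknown[i]) {
      den <- den + 1L
      if (rec$predicted[i] == as.integer(rec$label[i])) num <- num + 1L
    }
  }
  num / den
}

oracle_full_set_accuracy <- function(rec, delta) {
  cnt <- 0L
  for (i in seq_len(nrow(rec))) {
    if (!rec$unknown[i]) {
      if (rec$predicted[i] == as.integer(rec$label[i]) &&
          rec$score[i] >= delta) cnt <- cnt + 1L
    } else {
      if (rec$score[i] < delta) cnt <- cnt + 1L
    }
  }
  cnt / nrow(rec)
}

oracle_tpr_fpr <- function(rec, delta) {
  tp <- 0L; nk <- 0L; fp <- 0L; nu <- 0L
  for (i in seq_len(nrow(rec))) {
    if (!rec$unknown[i]) {
      nk <- nk + 1L
      if (rec$score[i] >= delta) tp <- tp + 1L
    } else {
      nu <- nu + 1L
      if (rec$score[i] >= delta) fp <- fp + 1L
    }
  }
  list(tpr = tp / nk, fpr = fp / nu,
       balanced = (tp / nk + 1 - fp / nu) / 2)
}

oracle_oscr <- function(rec, delta) {
  num <- 0L; nk <- 0L
  for (i in seq_len(nrow(rec))) {
    if (!rec$unknown[i]) {
      nk <- nk + 1L
      if (rec$predicted[i] == as.integer(rec$label[i]) &&
          rec$score[i] >= delta) num <- num + 1L
    }
  }
  num / nk
}

# Pairwise Mann-Whitney count: P(pos > neg) + P(pos == neg) / 2.
oracle_pair_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

oracle_unknown_roc_auc <- function(rec) {
  oracle_pair_auc(rec$score[!rec$unknown], rec$score[rec$unknown])
}

oracle_ovo_roc_auc <- function(rec, class_scores) {
  known <- !rec$unknown
  y <- as.integer(rec$label[known])
  cs <- class_scores[known, , drop = FALSE]
  present <- sort(unique(y))
  vals <- c()
  for (a in seq_along(present)) {
    for (b in seq_along(present)) {
      if (b <= a) next
      i <- present[a]; j <- present[b]
      auc_i <- oracle_pair_auc(cs[y == i, i + 1L], cs[y == j, i + 1L])
      auc_j <- oracle_pair_auc(cs[y == j, j + 1L], cs[y == i, j + 1L])
      vals <- c(vals, (auc_i + auc_j) / 2)
    }
  }
  mean(vals)
}

# OSCR-vs-FPR area by an independent sweep over all distinct partitions.
oracle_oscr_auc <- function(rec) {
  s <- sort(unique(rec$score))
  deltas <- c(-Inf, if (length(s) > 1) s[-1] - diff(s) / 2, Inf)
  fpr <- sapply(deltas, function(d) oracle_tpr_fpr(rec, d)$fpr)
  oscr <- sapply(deltas, function(d) oracle_oscr(rec, d))
  o <- order(fpr, oscr)
  fpr <- fpr[o]; oscr <- oscr[o]
  sum(diff(fpr) * (oscr[-1] + oscr[-length(oscr)]) / 2)
}

# Exhaustive threshold search: evaluates the criterion on every distinct
# accept/reject partition and returns the best achievable value.
oracle_best_threshold <- function(rec, criterion) {
  s <- sort(unique(rec$score))
  deltas <- c(-Inf, if (length(s) > 1) s[-1] - diff(s) / 2, s, Inf)
  best <- -Inf
  for (d in deltas) {
    v <- if (criterion == "max_full_set_accuracy")
      oracle_full_set_accuracy(rec, d)
    else (oracle_oscr(rec, d) + 1 - oracle_tpr_fpr(rec, d)$fpr) / 2
    if (v > best) best <- v
  }
  best
}

# Random evaluation-record instances (N <= 50, C <= 5), with occasional
# score ties to exercise the tie conventions.
random_records <- function(seed) {
  set.seed(seed)
  C <- sample(2:5, 1)
  n_known <- sample(2:40, 1)
  n_unknown <- sample(1:10, 1)
  labels <- c(sample(0:(C - 1), n_known, replace = TRUE),
              sample(c("novel_category", "poor_quality", "multiple_views"),
                     n_unknown, replace = TRUE))
  # ensure at least two known classes present for one-vs-one checks
  labels[1:2] <- c("0", "1")
  preds <- sample(0:(C - 1), n_known + n_unknown, replace = TRUE)
  scores <- if (runif(1) < 0.3)
    sample(seq(-1, 1, by = 0.5), n_known + n_unknown, replace = TRUE)
  else stats::rnorm(n_known + n_unknown)
  rec <- make_eval_records(labels, preds, scores)
  attr(rec, "C") <- C
  attr(rec, "class_scores") <- matrix(stats::rnorm((n_known + n_unknown) * C),
                                      ncol = C)
  rec
}
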