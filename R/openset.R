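# Anomaly (familiarity) scores computed from classifier outputs, and
# calibration of the acceptance threshold delta. All scores are oriented
# so that LOWER values are more anomalous: a video is rejected (marked
# unknown) when its score falls below the threshold, and accepted when
# score >= delta (the boundary accepts).

#' Maximum-logit familiarity score
#'
#' The maximum over the known-class entries of the temporal-mean logit
#' vector; the primary anomaly score. Under outlier exposure the outlier
#' logit is explicitly ignored.
#'
#' @param video_logits Length-`C` (or `C + 1`) video logit vector.
#' @param outlier_exposure Whether the last entry is an outlier logit.
#' @return Scalar score (unbounded; may be negative).
#' @export
max_logit_score <- function(video_logits, outlier_exposure = FALSE) {
  C <- length(video_logits) - as.integer(outlier_exposure)
  max(video_logits[seq_len(C)])
}

#' Maximum softmax probability score
#'
#' Softmax over the full logit vector, returning its maximum entry;
#' shift-invariant in the logits, in `(0, 1]`.
#'
#' @param video_logits Video logit vector.
#' @return Scalar in `(0, 1]`.
#' @export
max_softmax_score <- function(video_logits) {
  z <- video_logits - max(video_logits)
  p <- exp(z) / sum(exp(z))
  max(p)
}

#' Mean feature activation (L1) score
#'
#' The arithmetic mean of the entries of the time-averaged penultimate
#' feature vector; low values indicate unfamiliar input.
#'
#' @param embedding Length-`D` time-averaged feature vector.
#' @return Scalar score.
#' @export
l1_feature_score <- function(embedding) {
  mean(embedding)
}

#' Negated feature-entropy score
#'
#' Normalises the (non-negative) time-averaged feature vector to sum 1,
#' computes its Shannon entropy (natural log, with `0 log 0 := 0`) and
#' returns the negation, so that low values again indicate anomalies.
#' The all-zero vector gets the minimum attainable score `-log(D)` with
#' a `degenerate` attribute flag.
#'
#' @param embedding Length-`D` non-negative feature vector.
#' @return Scalar score in `[-log(D), 0]`.
#' @export
feature_entropy_score <- function(embedding) {
  if (any(embedding < 0)) stop("feature entropy requires non-negative activations")
  s <- sum(embedding)
  if (s == 0) {
    out <- -log(length(embedding))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  p <- embedding / s
  p <- p[p > 0]
  -(-sum(p * log(p)))
}

#' Relative frequency of the modal per-frame prediction
#'
#' The fraction of frames whose argmax class equals the most frequently
#' predicted class; 1 when all frames agree.
#'
#' @param frame_logits `T' x C` matrix of per-frame known-class logits,
#'   or an integer vector of per-frame predicted classes.
#' @return Scalar in `(0, 1]`.
#' @export
relative_frequency_score <- function(frame_logits) {
  preds <- if (is.matrix(frame_logits))
    max.col(frame_logits, ties.method = "first")
  else as.integer(frame_logits)
  if (length(preds) < 1) stop("at least one frame required")
  max(table(preds)) / length(preds)
}

#' Summed known-class softmax score (outlier-exposed models)
#'
#' Softmax over the `C + 1` logits of an outlier-exposed model, returning
#' the summed probability of the known classes (1 minus the outlier
#' probability).
#'
#' @param video_logits Length-`C + 1` logit vector whose last entry is
#'   the outlier logit.
#' @param num_known Number of known classes C.
#' @return Scalar in `(0, 1)`.
#' @export
summed_softmax_score <- function(video_logits, num_known = length(video_logits) - 1L) {
  if (length(video_logits) != num_known + 1L)
    stop("expected a C + 1 logit vector from an outlier-exposed model")
  z <- video_logits - max(video_logits)
  p <- exp(z) / sum(exp(z))
  sum(p[seq_len(num_known)])
}

#' Accept/reject decision at a threshold
#'
#' A video is accepted as a known view iff its familiarity score is at
#' least the threshold (`S >= delta`; the boundary accepts).
#'
#' @param score Familiarity score(s).
#' @param delta Acceptance threshold (`-Inf` accepts everything).
#' @return Logical vector of acceptance flags.
#' @export
accept_reject <- function(score, delta) {
  score >= delta
}

threshold_candidates <- function(scores) {
  u <- sort(unique(scores))
  mids <- if (length(u) > 1) (utils::head(u, -1) + utils::tail(u, -1)) / 2
  else numeric(0)
  c(-Inf, mids, Inf)
}

#' Calibrate the acceptance threshold on a validation set
#'
#' Scans all thresholds that induce distinct accept/reject partitions
#' (midpoints between consecutive sorted unique scores, plus `-Inf` and
#' `+Inf` sentinels) and returns the one maximising the chosen
#' criterion:
#'
#' * `"max_full_set_accuracy"`: the full-set accuracy, i.e. correctly
#'   classified-and-accepted knowns plus correctly rejected unknowns
#'   over all videos — sensitive to the prevalence of unknowns;
#' * `"oscr_specificity_mean"`: the mean of the open-set classification
#'   rate and the unknown-view recognition specificity (`1 - FPR`) —
#'   invariant to the relative frequency of unknown views.
#'
#' Ties break towards the smallest candidate, favouring acceptance.
#'
#' @param scores Numeric familiarity scores of the validation videos.
#' @param labels True labels (known class ids as character/integer, or
#'   unknown subcategory strings).
#' @param predictions 0-based predicted class per video.
#' @param criterion Calibration criterion (see above).
#' @return An object of class `threshold_calibration`: list with
#'   `delta`, `criterion`, `criterion_value`, and the calibration score
#'   range. If the validation set lacks unknowns under
#'   `max_full_set_accuracy`, the `-Inf` sentinel (accept everything) is
#'   returned with a warning and a `degenerate` flag.
#' @export
calibrate_threshold <- function(scores, labels, predictions,
                                criterion = c("max_full_set_accuracy",
                                              "oscr_specificity_mean")) {
  criterion <- match.arg(criterion)
  stopifnot(length(scores) == length(labels),
            length(scores) == length(predictions))
  records <- make_eval_records(labels = labels, predictions = predictions,
                               scores = scores)
  degenerate <- FALSE
  if (!any(records$unknown)) {
    if (criterion == "max_full_set_accuracy") {
      warning("validation set has no unknown views; falling back to the ",
              "-Inf sentinel (accept everything)")
      return(structure(list(delta = -Inf, criterion = criterion,
                            criterion_value = NA_real_,
                            score_range = range(scores), degenerate = TRUE),
                       class = "threshold_calibration"))
    }
    stop("criterion 'oscr_specificity_mean' needs at least one unknown clip")
  }
  if (!any(!records$unknown))
    stop("validation set needs at least one known clip")
  cand <- threshold_candidates(scores)
  crit <- vapply(cand, function(d) {
    if (criterion == "max_full_set_accuracy") full_set_accuracy(records, d)
    else (oscr_at(records, d) + 1 - tpr_fpr(records, d)$fpr) / 2
  }, numeric(1))
  best <- which.max(crit) # first max: smallest candidate wins ties
  structure(list(delta = cand[best], criterion = criterion,
                 criterion_value = crit[best],
                 score_range = range(scores), degenerate = degenerate),
            class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf("<threshold_calibration> delta = %.6g (%s = %.4f)\n",
              x$delta, x$criterion, x$criterion_value))
  invisible(x)
}

#' Compute all familiarity scores for a set of inference results
#'
#' Convenience wrapper assembling every implemented score per clip from
#' an [infer_clips()] result.
#'
#' @param inference Result of [infer_clips()].
#' @param num_known Number of known classes C.
#' @param outlier_exposure Whether the model carries an outlier logit.
#' @return Data frame with one row per clip and one column per score
#'   kind (`max_logit`, `max_softmax`, `l1_feature`, `feature_entropy`,
#'   `relative_frequency`, and `summed_softmax` when outlier-exposed).
#' @export
anomaly_scores <- function(inference, num_known,
                           outlier_exposure = FALSE) {
  vl <- inference$video_logits
  emb <- inference$embeddings
  n <- nrow(vl)
  out <- data.frame(
    max_logit = vapply(seq_len(n), function(i)
      max_logit_score(vl[i, ], outlier_exposure), numeric(1)),
    max_softmax = vapply(seq_len(n), function(i)
      max_softmax_score(vl[i, ]), numeric(1)),
    l1_feature = vapply(seq_len(n), function(i)
      l1_feature_score(emb[i, ]), numeric(1)),
    feature_entropy = vapply(seq_len(n), function(i)
      as.numeric(feature_entropy_score(pmax(emb[i, ], 0))), numeric(1)),
    relative_frequency = vapply(inference$frame_predictions,
                                relative_frequency_score, numeric(1)))
  if (outlier_exposure)
    out$summed_softmax <- vapply(seq_len(n), function(i)
      summed_softmax_score(vl[i, ], num_known), numeric(1))
  out
}
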