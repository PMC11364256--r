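# End-to-end desk-scale benchmark: synthetic data generation,
# preprocessing, classifier training, threshold calibration on the
# validation split, open-set evaluation on the test split, and the
# quality-regression stage on a separately generated quality-rated set.

#' Desk-scale benchmark configuration
#'
#' The standard study conditions for the synthetic open-set benchmark:
#' 10 known view classes with 50 training clips each, validation and
#' test splits carrying all three unknown subcategories, phantom frames
#' rendered at 256 x 256 and preprocessed to 64 x 64 network inputs, and
#' a small CNN trained from scratch for 12 epochs with AdamW.
#'
#' @param seed Master seed for the whole benchmark.
#' @param outlier_exposure Train with unknown clips collapsed to an
#'   extra outlier class.
#' @param epochs Training epochs (desk default 12).
#' @param input_size Network input side length.
#' @param n_frames Frames per generated clip.
#' @return List of the four component configurations.
#' @export
benchmark_config <- function(seed = 1L, outlier_exposure = FALSE,
                             epochs = 12L, input_size = 64L,
                             n_frames = 16L) {
  list(
    dataset = dataset_config(
      n_known = 10L,
      clips_per_class = c(train = 50L, val = 5L, test = 8L),
      unknown_fraction = c(train = 0, val = 0.3, test = 0.45),
      n_frames = n_frames, height = 256L, width = 256L,
      quality_spread = "default", outlier_exposure = outlier_exposure),
    preprocess = preprocess_config(target_size = input_size),
    backbone = backbone_config(architecture = "small_cnn",
                               num_classes = 10L,
                               outlier_exposure = outlier_exposure,
                               input_size = input_size),
    train = train_config(batch_videos = 16L, frames_per_video = 8L,
                         epochs = epochs, lr = 1e-3,
                         lr_drops = c(8L, 11L), seed = seed))
}

#' Run the synthetic open-set benchmark end to end
#'
#' Generates the phantom dataset (training split known views only,
#' unless outlier-exposed), trains the frame classifier, calibrates the
#' max-logit acceptance threshold on the validation split by maximum
#' full-set accuracy, and evaluates the full open-set metric suite on
#' the test split.
#'
#' @param seed Master seed.
#' @param config A [benchmark_config()]; built from `seed` when omitted.
#' @param verbose Print progress.
#' @return List with `model`, `calibration`, `report`
#'   (an [open_set_report()]), `val` / `test` inference results with
#'   their score tables, and the training `log`.
#' @export
run_open_set_benchmark <- function(seed = 1L, config = NULL,
                                   verbose = FALSE) {
  if (is.null(config)) config <- benchmark_config(seed = seed)
  pp <- config$preprocess
  say <- function(...) if (verbose) message(...)
  say("generating phantom dataset ...")
  ds <- generate_dataset(config$dataset, seed = seed,
                         transform = function(clip) preprocess_clip(clip, pp))
  say("training classifier (", config$train$epochs, " epochs) ...")
  tr <- train_classifier(ds$train, val_clips = NULL,
                         train_cfg = config$train,
                         backbone_cfg = config$backbone,
                         preprocess_cfg = pp)
  oe <- config$backbone$outlier_exposure
  C <- config$backbone$num_classes
  say("calibrating acceptance threshold on the validation split ...")
  val_inf <- infer_clips(tr$model, ds$val)
  val_scores <- anomaly_scores(val_inf, num_known = C, outlier_exposure = oe)
  cal <- calibrate_threshold(val_scores$max_logit, val_inf$records$label,
                             val_inf$records$predicted,
                             criterion = "max_full_set_accuracy")
  say("evaluating on the test split ...")
  test_inf <- infer_clips(tr$model, ds$test)
  test_scores <- anomaly_scores(test_inf, num_known = C, outlier_exposure = oe)
  records <- make_eval_records(test_inf$records$label,
                               test_inf$records$predicted,
                               test_scores$max_logit)
  records$subcategory <- test_inf$records$subcategory
  report <- open_set_report(records, cal$delta, num_classes = C,
                            class_scores = test_inf$video_logits[, seq_len(C),
                                                                 drop = FALSE])
  list(model = tr$model, log = tr$log, calibration = cal, report = report,
       val = list(inference = val_inf, scores = val_scores),
       test = list(inference = test_inf, scores = test_scores,
                   records = records),
       config = config, seed = seed)
}

#' Run the quality-regression benchmark against a frozen classifier
#'
#' Generates a quality-rated phantom set spanning the full quality range
#' (50 clips per known class for fitting, a held-out set for
#' evaluation), extracts time-averaged embeddings with the frozen
#' classifier, fits the cross-validated Lasso quality head, and scores
#' the held-out clips against the generator's ground-truth quality.
#'
#' @param model A trained `openecho_model` (weights are not touched).
#' @param seed Master seed for the quality dataset and fold partition.
#' @param preprocess_cfg The [preprocess_config()] the classifier was
#'   trained with.
#' @param clips_per_class Quality-labelled clips per class in the
#'   fitting set.
#' @param test_per_class Held-out quality-labelled clips per class.
#' @param n_frames Frames per generated clip.
#' @return List with `quality_model`, held-out `spearman`, and the
#'   held-out `predicted` / `truth` scores.
#' @export
run_quality_benchmark <- function(model, seed = 1L,
                                  preprocess_cfg = preprocess_config(target_size = 64L),
                                  clips_per_class = 50L,
                                  test_per_class = 10L,
                                  n_frames = 16L) {
  C <- model$config$num_classes
  qa_cfg <- dataset_config(
    n_known = C,
    clips_per_class = c(train = clips_per_class, val = 1L,
                        test = test_per_class),
    unknown_fraction = c(train = 0, val = 0, test = 0),
    n_frames = n_frames, height = 256L, width = 256L,
    quality_spread = "wide")
  ds <- generate_dataset(qa_cfg, seed = derive_seed(seed, 404),
                         transform = function(clip)
                           preprocess_clip(clip, preprocess_cfg))
  fit_inf <- infer_clips(model, ds$train)
  qm <- fit_quality_lasso(fit_inf$embeddings,
                          fit_inf$records$true_quality,
                          folds = 5L, seed = derive_seed(seed, 405))
  test_inf <- infer_clips(model, ds$test)
  pred <- predict_quality(qm, test_inf$embeddings)
  truth <- test_inf$records$true_quality
  list(quality_model = qm, spearman = spearman(pred, truth),
       predicted = pred, truth = truth)
}

#' Cross-validated replication of the benchmark
#'
#' Trains the classifier under k-fold cross-validation of the training
#' split (each model sees k-1 folds), calibrates each model's threshold
#' on the validation split, evaluates each on the common test split,
#' and reports the mean and standard deviation of closed/full-set
#' accuracy, OSCR-AUC and both ROC-AUCs across folds — the standard
#' presentation for comparing training variants.
#'
#' @param seed Master seed.
#' @param folds Number of cross-validation folds.
#' @param config A [benchmark_config()]; built from `seed` when omitted.
#' @param verbose Print per-fold progress.
#' @return List with `per_fold` (one row of metrics per fold) and
#'   `summary` (mean and sd per metric).
#' @export
run_cv_benchmark <- function(seed = 1L, folds = 5L, config = NULL,
                             verbose = FALSE) {
  if (is.null(config)) config <- benchmark_config(seed = seed)
  pp <- config$preprocess
  ds <- generate_dataset(config$dataset, seed = seed,
                         transform = function(clip) preprocess_clip(clip, pp))
  C <- config$backbone$num_classes
  oe <- config$backbone$outlier_exposure
  labels <- vapply(ds$train, function(cl) as.character(cl$label), character(1))
  fold_id <- with_seed(derive_seed(seed, 606),
                       sample(rep_len(seq_len(folds), length(ds$train))))
  rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    if (verbose) message("fold ", f, "/", folds)
    tc <- config$train
    tc$seed <- derive_seed(seed, 607, f)
    tr <- train_classifier(ds$train[fold_id != f], train_cfg = tc,
                           backbone_cfg = config$backbone,
                           preprocess_cfg = pp)
    val_inf <- infer_clips(tr$model, ds$val)
    val_sc <- anomaly_scores(val_inf, num_known = C, outlier_exposure = oe)
    cal <- calibrate_threshold(val_sc$max_logit, val_inf$records$label,
                               val_inf$records$predicted)
    test_inf <- infer_clips(tr$model, ds$test)
    test_sc <- anomaly_scores(test_inf, num_known = C, outlier_exposure = oe)
    rec <- make_eval_records(test_inf$records$label,
                             test_inf$records$predicted, test_sc$max_logit)
    rows[[f]] <- data.frame(
      fold = f,
      closed_set_accuracy = closed_set_accuracy(rec),
      full_set_accuracy = full_set_accuracy(rec, cal$delta),
      oscr_auc = oscr_auc(rec),
      ovo_roc_auc = ovo_roc_auc(rec, test_inf$video_logits[, seq_len(C),
                                                           drop = FALSE],
                                num_classes = C),
      unknown_roc_auc = unknown_roc_auc(rec))
  }
  per_fold <- do.call(rbind, rows)
  metrics <- setdiff(names(per_fold), "fold")
  summary <- data.frame(metric = metrics,
                        mean = vapply(metrics, function(m)
                          mean(per_fold[[m]]), numeric(1)),
                        sd = vapply(metrics, function(m)
                          stats::sd(per_fold[[m]]), numeric(1)),
                        row.names = NULL)
  list(per_fold = per_fold, summary = summary)
}
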