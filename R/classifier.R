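# Frame-level view classifier: training, per-frame inference, and
# temporal aggregation of logits and penultimate features to video level.

#' Training configuration
#'
#' Defaults follow the full-scale training recipe (AdamW with
#' `beta = (0, 0.999)`, `eps = 1e-8`, decoupled weight decay 0.01,
#' learning rate 1e-4 dropped tenfold after epochs 150 and 250, batches
#' of 16 videos times 8 frames, 300 epochs, class-balanced sampling). All
#' fields are overridable for desk-scale runs.
#'
#' An epoch is defined as the number of iterations needed to sample the
#' whole training set once at the configured batch size
#' (`ceil(N / batch_videos)`); under balanced sampling, clips of
#' over-represented classes may be skipped and clips of under-represented
#' classes repeated within an epoch.
#'
#' @param batch_videos Videos per mini-batch.
#' @param frames_per_video Frames sampled per video during training.
#' @param epochs Training epochs.
#' @param lr Base learning rate.
#' @param lr_drops Epochs after which the learning rate is divided by 10.
#' @param betas AdamW `(beta1, beta2)`.
#' @param eps AdamW epsilon.
#' @param weight_decay Decoupled weight decay.
#' @param balanced_sampling Sample classes uniformly with replacement.
#' @param augment Apply the augmentation cascade during training.
#' @param seed Master seed funnelling all training randomness.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_videos = 16L, frames_per_video = 8L,
                         epochs = 300L, lr = 1e-4, lr_drops = c(150L, 250L),
                         betas = c(0, 0.999), eps = 1e-8,
                         weight_decay = 0.01, balanced_sampling = TRUE,
                         augment = TRUE, seed = 1L) {
  structure(list(batch_videos = as.integer(batch_videos),
                 frames_per_video = as.integer(frames_per_video),
                 epochs = as.integer(epochs), lr = lr,
                 lr_drops = as.integer(lr_drops), betas = betas, eps = eps,
                 weight_decay = weight_decay,
                 balanced_sampling = isTRUE(balanced_sampling),
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "train_config")
}

lr_at_epoch <- function(cfg, epoch) {
  cfg$lr * 0.1^sum(epoch > cfg$lr_drops)
}

#' Run the frame classifier over the frames of one clip
#'
#' Frames are processed independently: one logit row and one penultimate
#' feature row per frame.
#'
#' @param model A trained (or freshly built) `openecho_model`.
#' @param frames `T' x S x S` array of preprocessed frames.
#' @return List with `logits` (`T' x K` matrix, `K = C` or `C + 1` under
#'   outlier exposure) and `features` (`T' x D` matrix).
#' @export
forward_frames <- function(model, frames) {
  stopifnot(inherits(model, "openecho_model"))
  d <- dim(frames)
  S <- model$config$input_size
  if (length(d) != 3 || d[2] != S || d[3] != S)
    stop("frames must be T x ", S, " x ", S, " for this model")
  x <- aperm(frames, c(2, 3, 1))
  dim(x) <- c(S, S, 1L, d[1])
  f <- nn_forward(model, x, train = FALSE)
  list(logits = t(f$logits), features = t(f$features))
}

#' Temporal mean of per-frame logits
#'
#' @param frame_logits `T' x K` matrix of per-frame class logits.
#' @return Length-`K` vector: the exact arithmetic column mean.
#' @export
aggregate_logits <- function(frame_logits) {
  if (is.null(dim(frame_logits)) || nrow(frame_logits) < 1)
    stop("frame_logits must be a matrix with at least one row")
  colMeans(frame_logits)
}

#' Temporal mean of per-frame penultimate features
#'
#' @param frame_features `T' x D` matrix of per-frame features.
#' @return Length-`D` time-averaged embedding.
#' @export
aggregate_features <- function(frame_features) {
  if (is.null(dim(frame_features)) || nrow(frame_features) < 1)
    stop("frame_features must be a matrix with at least one row")
  colMeans(frame_features)
}

#' Video-level view prediction
#'
#' Argmax over the known-class entries of the temporal-mean logit
#' vector. Under outlier exposure the extra outlier logit is never
#' predicted. Ties break towards the lowest class index.
#'
#' @param video_logits Length-`C` (or `C + 1`) vector of video logits.
#' @param outlier_exposure Whether the last entry is an outlier logit.
#' @return 0-based class index in `[0, C)`.
#' @export
predict_view <- function(video_logits, outlier_exposure = FALSE) {
  C <- length(video_logits) - as.integer(outlier_exposure)
  which.max(video_logits[seq_len(C)]) - 1L
}

#' Class-balanced infinite index sampler
#'
#' Each draw picks a class uniformly at random, then a clip uniformly
#' within that class, with replacement. Under outlier exposure the
#' collapsed outlier class participates as one of the in-distribution
#' classes.
#'
#' @param labels Vector of per-clip class labels (any atomic type).
#' @param seed Integer seed; a fixed seed yields an identical stream.
#' @return A function `f(k)` returning the next `k` clip indices.
#' @export
make_balanced_sampler <- function(labels, seed = 1L) {
  if (length(labels) == 0) stop("every class needs at least one clip")
  classes <- sort(unique(labels))
  by_class <- lapply(classes, function(cl) which(labels == cl))
  if (any(lengths(by_class) == 0)) stop("every class needs at least one clip")
  counter <- 0L
  function(k) {
    counter <<- counter + 1L
    with_seed(derive_seed(seed, 7919, counter), {
      cls <- sample.int(length(classes), k, replace = TRUE)
      vapply(cls, function(ci) {
        pool <- by_class[[ci]]
        pool[sample.int(length(pool), 1L)]
      }, integer(1))
    })
  }
}

clip_class_index <- function(clip, config) {
  lab <- clip$label
  if (is.numeric(lab)) return(as.integer(lab))
  if (identical(lab, "outlier") && config$outlier_exposure)
    return(config$num_classes) # 0-based index C: the extra logit
  stop("training clips must carry known class labels",
       if (!config$outlier_exposure)
         " (unknown views require outlier_exposure)" else "")
}

#' Train the frame-level view classifier
#'
#' Per-frame softmax cross-entropy over the C known classes (C + 1 under
#' outlier exposure), AdamW optimisation, class-balanced sampling with
#' replacement, and the augmentation cascade applied per sampled clip.
#' All randomness funnels through `train_cfg$seed`; the per-epoch
#' learning rate, loss and frame accuracy are recorded in the returned
#' log.
#'
#' @param train_clips List of preprocessed `video_clip`s with known-class
#'   labels (plus collapsed `"outlier"` clips when the backbone is
#'   outlier-exposed).
#' @param val_clips Optional list of validation clips; when supplied, the
#'   final video-level closed-set accuracy on their known views is
#'   recorded in the log (validation uses test-mode sampling: all
#'   frames).
#' @param train_cfg A [train_config()].
#' @param backbone_cfg A [backbone_config()].
#' @param preprocess_cfg A [preprocess_config()] (used for augmentation
#'   parameters).
#' @return List with `model` (trained `openecho_model`) and `log`
#'   (data frame of epoch, lr, loss, frame accuracy).
#' @export
train_classifier <- function(train_clips, val_clips = NULL,
                             train_cfg = train_config(),
                             backbone_cfg = backbone_config(),
                             preprocess_cfg = preprocess_config()) {
  labels0 <- vapply(train_clips, clip_class_index, integer(1),
                    config = backbone_cfg)
  nclass <- backbone_cfg$num_classes + as.integer(backbone_cfg$outlier_exposure)
  model <- build_backbone(backbone_cfg, seed = derive_seed(train_cfg$seed, 1))
  opt <- adamw_init(model)
  N <- length(train_clips)
  iters <- ceiling(N / train_cfg$batch_videos)
  sampler <- if (train_cfg$balanced_sampling)
    make_balanced_sampler(labels0, seed = derive_seed(train_cfg$seed, 2))
  else {
    counter <- 0L
    function(k) {
      counter <<- counter + 1L
      with_seed(derive_seed(train_cfg$seed, 2, counter),
                sample.int(N, k, replace = TRUE))
    }
  }
  S <- backbone_cfg$input_size
  log_rows <- vector("list", train_cfg$epochs)
  step <- 0L
  for (epoch in seq_len(train_cfg$epochs)) {
    lr <- lr_at_epoch(train_cfg, epoch)
    ep_loss <- 0
    ep_correct <- 0L
    ep_frames <- 0L
    for (it in seq_len(iters)) {
      step <- step + 1L
      idx <- sampler(train_cfg$batch_videos)
      nb <- length(idx)
      nf <- train_cfg$frames_per_video
      batch <- array(0, dim = c(S, S, 1L, nb * nf))
      labs <- integer(nb * nf)
      for (j in seq_len(nb)) {
        clip <- train_clips[[idx[j]]]
        fr <- sample_frames(clip, "train", n = nf,
                            seed = derive_seed(train_cfg$seed, 3, step, j))
        if (train_cfg$augment && preprocess_cfg$augment)
          fr <- augment(fr, preprocess_cfg,
                        seed = derive_seed(train_cfg$seed, 5, step, j))
        batch[, , 1L, ((j - 1L) * nf + 1L):(j * nf)] <- aperm(fr, c(2, 3, 1))
        labs[((j - 1L) * nf + 1L):(j * nf)] <- labels0[idx[j]] + 1L
      }
      fwd <- nn_forward(model, batch, train = TRUE)
      model <- fwd$model
      ce <- softmax_xent(fwd$logits, labs)
      grads <- nn_backward(model, fwd$caches, ce$dlogits)
      stepres <- adamw_step(model, grads, opt, lr = lr,
                            betas = train_cfg$betas, eps = train_cfg$eps,
                            weight_decay = train_cfg$weight_decay)
      model <- stepres$model
      opt <- stepres$opt
      ep_loss <- ep_loss + ce$loss
      ep_correct <- ep_correct + sum(ce$correct)
      ep_frames <- ep_frames + length(labs)
    }
    log_rows[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                    loss = ep_loss / iters,
                                    frame_accuracy = ep_correct / ep_frames)
  }
  log <- do.call(rbind, log_rows)
  if (!is.null(val_clips)) {
    inf <- infer_clips(model, val_clips)
    known <- !inf$records$unknown
    if (any(known)) {
      acc <- mean(inf$records$predicted[known] ==
                    as.integer(inf$records$label[known]))
      attr(log, "val_closed_accuracy") <- acc
    }
  }
  attr(log, "nclass") <- nclass
  list(model = model, log = log)
}

#' Video-level inference over a list of clips
#'
#' Runs the classifier over every frame of each clip (test-time
#' sampling), aggregates logits and features over time, and assembles
#' per-clip records.
#'
#' @param model A trained `openecho_model`.
#' @param clips List of preprocessed `video_clip`s.
#' @return List with `records` (data frame: `clip_id`, `label`,
#'   `subcategory`, `unknown` flag, `true_quality`, `predicted`),
#'   `video_logits` (`N x K` matrix), `embeddings` (`N x D` matrix of
#'   time-averaged features) and `frame_predictions` (list of per-frame
#'   0-based argmax classes, for frequency-based scores).
#' @export
infer_clips <- function(model, clips) {
  oe <- model$config$outlier_exposure
  N <- length(clips)
  K <- model$config$num_classes + as.integer(oe)
  D <- model$config$embedding_dim
  vl <- matrix(0, N, K)
  emb <- matrix(0, N, D)
  preds <- integer(N)
  fp <- vector("list", N)
  rows <- vector("list", N)
  for (i in seq_len(N)) {
    clip <- clips[[i]]
    f <- forward_frames(model, sample_frames(clip, "test"))
    vl[i, ] <- aggregate_logits(f$logits)
    emb[i, ] <- aggregate_features(f$features)
    preds[i] <- predict_view(vl[i, ], outlier_exposure = oe)
    Ck <- model$config$num_classes
    fp[[i]] <- max.col(f$logits[, seq_len(Ck), drop = FALSE],
                       ties.method = "first") - 1L
    rows[[i]] <- data.frame(
      clip_id = i, label = as.character(clip$label),
      subcategory = clip$subcategory %||% NA_character_,
      unknown = is.character(clip$label),
      true_quality = clip$true_quality %||% NA_real_,
      predicted = preds[i], stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, rows), video_logits = vl, embeddings = emb,
       frame_predictions = fp)
}

#' Save / load a model checkpoint
#'
#' The model is serialised with `saveRDS()`; a JSON manifest
#' (architecture, class count, embedding dimension, outlier-exposure
#' flag, initialisation seed) is written alongside.
#'
#' @param model A trained `openecho_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `save_checkpoint()`: invisibly, the manifest path;
#'   `load_checkpoint()`: the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "openecho_model"))
  saveRDS(model, path)
  manifest <- model$config
  manifest$seed <- model$seed
  mpath <- paste0(sub("\\.rds$", "", path), "_manifest.json")
  jsonlite::write_json(unclass(manifest), mpath, auto_unbox = TRUE)
  invisible(mpath)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "openecho_model"))
  model
}
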