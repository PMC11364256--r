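# Temporal aggregation, view prediction, balanced sampling, the learning
# rate schedule, and a small overfit-sanity training run.

test_that("logit and feature aggregation are exact temporal means", {
  expect_equal(aggregate_logits(rbind(c(1, 2), c(3, 4))), c(2, 3))
  expect_equal(aggregate_logits(matrix(c(5, 1, 0), 1)), c(5, 1, 0))
  m <- matrix(rnorm(20), 5, 4)
  expect_equal(aggregate_logits(m[sample(5), ]), aggregate_logits(m))
  expect_equal(aggregate_features(rbind(c(1, 3), c(3, 1))), c(2, 2))
  v <- c(0.3, -1, 2)
  expect_equal(aggregate_features(matrix(v, 4, 3, byrow = TRUE)), v)
  expect_error(aggregate_logits(matrix(numeric(0), 0, 2)), "at least one")
  # linearity in the frame logits
  a <- matrix(rnorm(12), 3, 4)
  b <- matrix(rnorm(12), 3, 4)
  expect_equal(aggregate_logits(a + 2 * b),
               aggregate_logits(a) + 2 * aggregate_logits(b))
})

test_that("predict_view takes the argmax over known classes only", {
  expect_identical(predict_view(c(0.1, 2.0, -1.0)), 1L)
  # outlier logit excluded even when it is the largest activation
  expect_identical(predict_view(c(1.0, 2.0, 5.0), outlier_exposure = TRUE), 1L)
  # ties break towards the lowest index
  expect_identical(predict_view(c(3.0, 3.0)), 0L)
  # invariant to adding a constant to all known logits
  v <- rnorm(6)
  expect_identical(predict_view(v), predict_view(v + 17.3))
})

test_that("the balanced sampler draws classes uniformly", {
  labels <- c(rep("a", 1), rep("b", 99))
  sampler <- make_balanced_sampler(labels, seed = 11)
  draws <- sampler(10000)
  frac_a <- mean(labels[draws] == "a")
  # 3 sigma of a fair binomial around 0.5
  expect_lt(abs(frac_a - 0.5), 3 * sqrt(0.25 / 10000))
  # fixed seed gives an identical stream
  s1 <- make_balanced_sampler(labels, seed = 4)
  s2 <- make_balanced_sampler(labels, seed = 4)
  expect_identical(c(s1(50), s1(50)), c(s2(50), s2(50)))
  # degenerate single class
  s3 <- make_balanced_sampler(rep("x", 3), seed = 1)
  expect_true(all(s3(100) %in% 1:3))
  expect_error(make_balanced_sampler(character(0)), "at least one")
})

test_that("the learning-rate schedule drops tenfold after epochs 150 and 250", {
  cfg <- train_config()
  expect_equal(openecho:::lr_at_epoch(cfg, 149), 1e-4)
  expect_equal(openecho:::lr_at_epoch(cfg, 151), 1e-5)
  expect_equal(openecho:::lr_at_epoch(cfg, 251), 1e-6)
})

test_that("a two-class toy problem is fit to perfect training accuracy", {
  pp <- preprocess_config(target_size = 64)
  cfg <- dataset_config(n_known = 2,
                        clips_per_class = c(train = 10L, val = 2L, test = 2L),
                        unknown_fraction = c(train = 0, val = 0, test = 0),
                        n_frames = 8, height = 128, width = 128)
  ds <- generate_dataset(cfg, seed = 11,
                         transform = function(cl) preprocess_clip(cl, pp))
  bb <- backbone_config(num_classes = 2, input_size = 64)
  tc <- train_config(batch_videos = 16L, frames_per_video = 8L,
                     epochs = 30L, lr = 1e-3, lr_drops = c(20L, 27L),
                     seed = 5)
  tr <- train_classifier(ds$train, train_cfg = tc, backbone_cfg = bb,
                         preprocess_cfg = pp)
  expect_identical(nrow(tr$log), 30L)
  inf <- infer_clips(tr$model, ds$train)
  acc <- mean(inf$records$predicted == as.integer(inf$records$label))
  expect_equal(acc, 1.0)
  # unknown labels are rejected without outlier exposure
  bad <- ds$train
  bad[[1]]$label <- "poor_quality"
  bad[[1]]$subcategory <- "poor_quality"
  expect_error(train_classifier(bad, train_cfg = tc, backbone_cfg = bb,
                                preprocess_cfg = pp), "known class labels")
})

test_that("checkpoints round-trip through disk", {
  model <- build_backbone(backbone_config(num_classes = 3, input_size = 32),
                          seed = 8)
  fr <- array(runif(2 * 32 * 32), c(2, 32, 32))
  before <- forward_frames(model, fr)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  expect_true(file.exists(paste0(sub("\\.rds$", "", path), "_manifest.json")))
  reloaded <- load_checkpoint(path)
  expect_equal(forward_frames(reloaded, fr), before)
})
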