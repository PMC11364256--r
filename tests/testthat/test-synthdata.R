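# Phantom video generator: determinism, label soundness, layout
# separability, quality formula, and dataset split contracts.

test_that("layouts are deterministic and pairwise separable", {
  a1 <- make_view_layout(0, seed = 1)
  a2 <- make_view_layout(0, seed = 1)
  expect_identical(a1, a2)
  b <- make_view_layout(1, seed = 1)
  expect_true(openecho:::layouts_separable(a1, b))
  lays <- lapply(0:11, make_view_layout, seed = 1)
  for (i in 1:11) for (j in (i + 1):12)
    expect_true(openecho:::layouts_separable(lays[[i]], lays[[j]]),
                info = sprintf("classes %d vs %d", i - 1, j - 1))
  # every ellipse centre lies inside the sector fan
  for (L in lays)
    for (e in L$ellipses)
      expect_true(openecho:::point_in_sector(e$center[1], e$center[2]))
})

test_that("rendered frames obey the clipping, masking and determinism contracts", {
  lay <- make_view_layout(3)
  q <- quality_params()
  f1 <- render_frame(lay, 0.25, q, seed = 9, H = 128, W = 128)
  f2 <- render_frame(lay, 0.25, q, seed = 9, H = 128, W = 128)
  expect_identical(f1, f2)
  expect_gte(min(f1), 0)
  expect_lte(max(f1), 1)
  msk <- openecho:::sector_mask(128, 128)$mask
  expect_true(all(f1[!msk] == 0))
  # zero visibility removes all structure: pure background texture
  q0 <- quality_params(visibility = 0, speckle_strength = 0)
  f0 <- render_frame(lay, 0.25, q0, seed = 9, H = 128, W = 128)
  expect_equal(length(unique(f0[msk])), 1)
  fother <- render_frame(make_view_layout(7), 0.25, q0, seed = 9,
                         H = 128, W = 128)
  expect_identical(f0, fother)
})

test_that("true_quality is the documented convex combination", {
  expect_equal(true_quality(quality_params(1, 0, 0, 0)), 1.0)
  expect_equal(true_quality(quality_params(0, 1, 1, 1)), 0.0)
  expect_equal(true_quality(quality_params(0.5, 0.5, 0.5, 0.5)), 0.5)
  # range invariant over random valid parameters
  set.seed(4)
  for (i in 1:50) {
    q <- quality_params(runif(1), runif(1), runif(1), runif(1))
    tq <- true_quality(q)
    expect_gte(tq, 0)
    expect_lte(tq, 1)
  }
  expect_error(quality_params(visibility = 1.5), "lie in")
})

test_that("generate_video produces sound labels for every branch", {
  q <- quality_params()
  known <- generate_video(2, n_frames = 4, q = q, seed = 5, H = 64, W = 64)
  expect_identical(known$label, 2L)
  expect_true(all(known$frames >= 0 & known$frames <= 1))
  expect_identical(dim(known$frames), c(4L, 64L, 64L))

  again <- generate_video(2, n_frames = 4, q = q, seed = 5, H = 64, W = 64)
  expect_identical(known, again)

  poor <- generate_video("poor_quality", n_frames = 4, q = q, seed = 6,
                         H = 64, W = 64)
  expect_identical(poor$label, "poor_quality")
  expect_lte(poor$quality$visibility, 0.1)
  # visibility <= 0.1 bounds the quality score by the formula
  expect_lte(poor$true_quality, 0.4 * 0.1 + 0.6)

  multi <- generate_video("multiple_views", n_frames = 16, q = q, seed = 7,
                          H = 64, W = 64)
  expect_identical(multi$label, "multiple_views")
  expect_true(multi$switch_at >= 4 && multi$switch_at <= 12)
  # first and last frames come from different known layouts
  expect_gt(sum(abs(multi$frames[1, , ] - multi$frames[16, , ])), 0)

  novel <- generate_video("novel_category", n_frames = 2, q = q, seed = 8,
                          H = 64, W = 64)
  expect_identical(novel$label, "novel_category")

  expect_error(generate_video("multiple_views", n_frames = 1, q = q),
               "n_frames >= 2")
  expect_error(generate_video(10, n_frames = 2, q = q), "out of range")
})

test_that("dataset splits respect the open-set training contract", {
  cfg <- dataset_config(n_known = 3,
                        clips_per_class = c(train = 2L, val = 2L, test = 2L),
                        unknown_fraction = c(train = 0, val = 0.5, test = 0.5),
                        n_frames = 2, height = 64, width = 64)
  ds <- generate_dataset(cfg, seed = 7)
  train_labels <- sapply(ds$train, `[[`, "label")
  expect_length(ds$train, 6)
  expect_true(all(vapply(train_labels, is.numeric, logical(1))))
  val_sub <- na.omit(sapply(ds$val, `[[`, "subcategory"))
  expect_setequal(unique(val_sub),
                  c("novel_category", "poor_quality", "multiple_views"))
  ds2 <- generate_dataset(cfg, seed = 7)
  expect_identical(ds, ds2)

  expect_error(dataset_config(unknown_fraction = c(train = 0.1, val = 0.3,
                                                   test = 0.3)),
               "outlier_exposure")
  cfg_oe <- dataset_config(n_known = 3,
                           clips_per_class = c(train = 4L, val = 1L, test = 1L),
                           unknown_fraction = c(train = 0.5, val = 0.5,
                                                test = 0.5),
                           n_frames = 2, height = 64, width = 64,
                           outlier_exposure = TRUE)
  ds_oe <- generate_dataset(cfg_oe, seed = 7)
  oe_labels <- sapply(ds_oe$train, `[[`, "label")
  expect_true("outlier" %in% oe_labels)
  # collapsed: no fine-grained subcategory in the training split
  expect_true(all(is.na(sapply(ds_oe$train, `[[`, "subcategory"))))
})

test_that("a pixel-space nearest-centroid classifier separates the classes", {
  # sanity property: the generated learning task is solvable
  n_class <- 10
  mean_frame <- function(k, r) {
    clip <- generate_video(k, n_frames = 2, q = quality_params(),
                           seed = derive_seed_test(k, r), H = 128, W = 128)
    colMeans(clip$frames, dims = 1)
  }
  derive_seed_test <- function(k, r) 1000L + 37L * k + r
  train <- lapply(0:(n_class - 1), function(k)
    Reduce(`+`, lapply(1:3, function(r) mean_frame(k, r))) / 3)
  correct <- 0
  total <- 0
  for (k in 0:(n_class - 1)) {
    for (r in 4:5) {
      f <- mean_frame(k, r)
      dists <- vapply(train, function(ctr) sum((f - ctr)^2), numeric(1))
      correct <- correct + (which.min(dists) - 1 == k)
      total <- total + 1
    }
  }
  expect_gt(correct / total, 0.9)
})

test_that("clips round-trip through PNG frame directories", {
  clip <- generate_video(1, n_frames = 3, q = quality_params(), seed = 2,
                         H = 64, W = 64)
  dir <- withr::local_tempdir()
  export_clip_png(clip, dir)
  back <- read_clip_png(dir, label = 1L)
  expect_identical(dim(back$frames), dim(clip$frames))
  # 8-bit PNG quantisation bounds the round-trip error
  expect_lt(max(abs(back$frames - clip$frames)), 1 / 255)
})

test_that("datasets round-trip through the directory container", {
  cfg <- dataset_config(n_known = 2,
                        clips_per_class = c(train = 1L, val = 1L, test = 1L),
                        unknown_fraction = c(train = 0, val = 0, test = 0),
                        n_frames = 2, height = 64, width = 64)
  ds <- generate_dataset(cfg, seed = 3)
  dir <- withr::local_tempdir()
  meta <- write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  ds2 <- read_dataset(dir)
  expect_equal(length(ds2$train), length(ds$train))
  expect_equal(ds2$train[[1]]$frames, ds$train[[1]]$frames)
  expect_equal(ds2$test[[1]]$label, ds$test[[1]]$label)
})
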