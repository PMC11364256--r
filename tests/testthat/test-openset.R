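# Familiarity scores and threshold calibration.

test_that("max-logit score takes the maximum known-class mean logit", {
  expect_equal(max_logit_score(c(2, 3)), 3)
  expect_equal(max_logit_score(c(-5, -1)), -1) # scores may be negative
  # outlier slot explicitly ignored
  expect_equal(max_logit_score(c(1, 2, 9), outlier_exposure = TRUE), 2)
})

test_that("softmax-based scores obey their closed forms and invariances", {
  expect_equal(max_softmax_score(c(0, 0)), 0.5)
  expect_equal(max_softmax_score(c(10, 0)), 1 / (1 + exp(-10)))
  v <- rnorm(5)
  expect_equal(max_softmax_score(v), max_softmax_score(v + 123.4))
  # prediction from logits equals the class attaining max softmax
  p <- exp(v) / sum(exp(v))
  expect_identical(which.max(v), which.max(p))
  expect_gt(max_softmax_score(v), 0)
  expect_lte(max_softmax_score(v), 1)
})

test_that("feature-based scores follow their definitions", {
  expect_equal(l1_feature_score(c(1, 2, 3)), 2)
  expect_equal(l1_feature_score(rep(0, 8)), 0)
  v <- runif(16)
  expect_equal(l1_feature_score(3 * v), 3 * l1_feature_score(v))

  expect_equal(feature_entropy_score(c(0, 0, 1, 0)), 0)
  expect_equal(feature_entropy_score(rep(1, 4)), -log(4))
  expect_equal(feature_entropy_score(c(2, 2, 0, 0)), -log(2))
  z <- feature_entropy_score(rep(0, 4))
  expect_equal(as.numeric(z), -log(4))
  expect_true(isTRUE(attr(z, "degenerate")))
  expect_error(feature_entropy_score(c(-1, 2)), "non-negative")
})

test_that("relative frequency counts the modal per-frame prediction", {
  expect_equal(relative_frequency_score(c(0, 0, 1, 0)), 0.75)
  expect_equal(relative_frequency_score(rep(3, 7)), 1.0)
  expect_equal(relative_frequency_score(5L), 1.0)
  fl <- rbind(c(5, 0), c(4, 1), c(0, 9), c(2, 1))
  expect_equal(relative_frequency_score(fl), 0.75)
})

test_that("summed softmax complements the outlier probability", {
  expect_equal(summed_softmax_score(c(0, 0, 0), num_known = 2), 2 / 3)
  v <- c(rnorm(4), 50) # near-certain outlier
  expect_lt(summed_softmax_score(v, num_known = 4), 1e-10)
  v2 <- rnorm(5)
  p_out <- exp(v2[5] - max(v2)) / sum(exp(v2 - max(v2)))
  expect_equal(summed_softmax_score(v2, num_known = 4) + p_out, 1)
  expect_error(summed_softmax_score(c(1, 2), num_known = 2), "C \\+ 1")
})

test_that("acceptance uses the boundary-accepting convention", {
  expect_true(accept_reject(1.5, 1.5))
  expect_false(accept_reject(1.5 - 1e-9, 1.5))
  expect_true(all(accept_reject(rnorm(10), -Inf)))
})

test_that("threshold calibration maximises its criterion over all partitions", {
  # derived example: knowns correct with scores {2, 3}, unknown at 1
  cal <- calibrate_threshold(scores = c(2, 3, 1), labels = c("0", "1", "poor_quality"),
                             predictions = c(0L, 1L, 0L))
  expect_gt(cal$delta, 1)
  expect_lt(cal$delta, 2)
  expect_equal(cal$criterion_value, 1.0)

  # all scores tied: the sentinel choice equals the better of
  # accept-all / reject-all
  cal2 <- calibrate_threshold(scores = rep(1, 4),
                              labels = c("0", "0", "poor_quality", "novel_category"),
                              predictions = c(0L, 1L, 0L, 0L))
  rec <- make_eval_records(c("0", "0", "poor_quality", "novel_category"),
                           c(0L, 1L, 0L, 0L), rep(1, 4))
  expect_equal(cal2$criterion_value,
               max(full_set_accuracy(rec, -Inf), full_set_accuracy(rec, Inf)))

  # degenerate: no unknowns -> -Inf sentinel with warning
  expect_warning(
    cal3 <- calibrate_threshold(c(1, 2), c("0", "1"), c(0L, 1L)),
    "no unknown views")
  expect_identical(cal3$delta, -Inf)
})

test_that("calibration matches exhaustive search on random instances", {
  for (seed in 1:40) {
    rec <- random_records(seed)
    for (crit in c("max_full_set_accuracy", "oscr_specificity_mean")) {
      cal <- calibrate_threshold(rec$score, rec$label, rec$predicted,
                                 criterion = crit)
      expect_equal(cal$criterion_value, oracle_best_threshold(rec, crit),
                   info = paste("seed", seed, crit))
    }
  }
})
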