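test_that("class-mean differencing is exact, symmetric and additive", {
  m <- structure(list(labels = c("a", "b"),
                      mu = rbind(a = c(1, 0), b = c(0, 1)),
                      priors = c(a = 0.5, b = 0.5), p = 2L,
                      method = "diagonal", var = c(1, 1)),
                 class = "lda_model")
  expect_equal(unname(lda_diff(m)), c(1, 1))
  expect_equal(lda_distance(lda_diff(m)), 2)
  m0 <- m; m0$mu["b", ] <- m0$mu["a", ]
  expect_equal(unname(lda_diff(m0)), c(0, 0))
  expect_equal(lda_distance(lda_diff(m0)), 0)
  # swapping the class rows leaves the difference unchanged
  ms <- m; ms$mu <- m$mu[2:1, ]
  expect_equal(unname(lda_diff(ms)), unname(lda_diff(m)))
  # additivity over concatenated difference vectors
  d1 <- c(0.2, 0.5); d2 <- c(1, 0, 0.3)
  expect_equal(lda_distance(c(d1, d2)), lda_distance(d1) + lda_distance(d2))
  expect_error(lda_distance(c(-1, 2)), class = "emgdiff_invalid_argument")
})

test_that("a single dominant feature is isolated at the first qualifying step", {
  tm <- toy_trial_matrix(signal_col = 3, sep = 2, noise = 0.1, seed = 2)
  folds <- make_folds(tm$meta$subject, 3, seed = 1)
  sel <- threshold_search(tm, folds, step_frac = 0.05)
  expect_equal(which(sel$high_mask), 3L)
  expect_equal(nrow(sel$search_trace), 1L)
  expect_gt(sel$accuracy_high, sel$accuracy_low)
  # brute force over the scanned thresholds: the returned threshold is the
  # first (highest) one where the above-set beats the below-set
  d <- sel$lda_diff
  thrs <- max(d) - seq_len(20) * 0.05 * (max(d) - min(d))
  ok <- vapply(thrs, function(thr) {
    high <- d > thr
    if (!any(high)) return(FALSE)
    ah <- cross_validate(tm, folds, features = which(high))$mean_accuracy
    al <- cross_validate(tm, folds, features = which(!high))$mean_accuracy
    ah > al
  }, TRUE)
  expect_equal(sel$threshold, thrs[which(ok)[1]])
})

test_that("selection results satisfy their structural identities", {
  cfg <- small_cfg(seed = 31)
  tm <- small_tm(cfg)
  folds <- make_folds(tm$meta$subject, 3, seed = 3)
  sel <- threshold_search(tm, folds)
  expect_true(all(sel$lda_diff >= 0))
  expect_identical(sel$high_mask, sel$lda_diff > sel$threshold)
  expect_identical(sel$low_mask, !sel$high_mask)
  expect_true(all(xor(sel$high_mask, sel$low_mask)))
  expect_equal(sel$lda_distance, sum(sel$lda_diff))
  # stopping guarantee, read from the trace
  last <- sel$search_trace[nrow(sel$search_trace), ]
  expect_gt(last$accuracy_high, last$accuracy_low)
  expect_equal(last$accuracy_high, sel$accuracy_high)
  expect_equal(sel$lda_distance, lda_distance(sel$lda_diff))
  # channel partition
  expect_setequal(c(sel$high_channels, sel$low_channels),
                  unique(tm$index_map$channel))
})

test_that("the selection is invariant to swapping the class labels", {
  cfg <- small_cfg(seed = 32)
  ds <- gen_emg_dataset(cfg)
  ds_sw <- ds
  for (i in seq_along(ds_sw$trials)) {
    ds_sw$trials[[i]]$condition <- if (ds_sw$trials[[i]]$condition == "A") "B" else "A"
  }
  tm <- minmax_normalize(vectorize_dataset(ds), grouping = "joint")
  tm_sw <- minmax_normalize(vectorize_dataset(ds_sw), grouping = "joint")
  folds <- make_folds(tm$meta$subject, 3, seed = 4)
  sel <- threshold_search(tm, folds)
  sel_sw <- threshold_search(tm_sw, folds)
  expect_equal(sel_sw$lda_diff, sel$lda_diff)
  expect_identical(sel_sw$high_mask, sel$high_mask)
  expect_equal(sel_sw$threshold, sel$threshold)
  expect_equal(sel_sw$accuracy_high, sel$accuracy_high)
  expect_equal(sel_sw$accuracy_low, sel$accuracy_low)
  expect_identical(sel_sw$high_channels, sel$high_channels)
})

test_that("channel membership follows the contains-parts rule and min_frac", {
  im <- data.frame(channel = rep(c("AD", "MD"), each = 10),
                   sample = rep(1:10, 2))
  mask <- rep(FALSE, 20)
  mask[1:5] <- TRUE  # 50% of AD
  expect_equal(channels_from_mask(mask, im), "AD")
  expect_equal(channels_from_mask(rep(FALSE, 20), im), character(0))
  expect_equal(channels_from_mask(mask, im, min_frac = 0.6), character(0))
  expect_equal(channels_from_mask(mask, im, min_frac = 0.5), "AD")
  expect_error(channels_from_mask(mask[1:5], im), class = "emgdiff_invalid_argument")
})

test_that("search fails informatively when no threshold separates the sets", {
  # pure-noise toy: no threshold should let above beat below systematically;
  # accept either a selection-failed error or a chance-level stop
  tm <- toy_trial_matrix(signal_col = 3, sep = 0, noise = 1, seed = 5)
  folds <- make_folds(tm$meta$subject, 3, seed = 5)
  res <- tryCatch(threshold_search(tm, folds), error = function(e) e)
  if (inherits(res, "emgdiff_selection_failed")) {
    expect_s3_class(res$data, "data.frame")
    expect_true(nrow(res$data) >= 1)
  } else {
    expect_lt(abs(res$accuracy_high - 50), 30)
  }
})

test_that("temporal halves are compared with the signal where it was planted", {
  # one channel, 40 samples; the class difference lives in the first half
  set.seed(7)
  n_sub <- 6; tpc <- 5
  n <- n_sub * tpc * 2
  X <- matrix(rnorm(n * 40, 0, 0.3), nrow = n)
  cls <- rep(rep(c("a", "b"), each = tpc), times = n_sub)
  bump <- exp(-((1:20) - 10)^2 / 8)
  X[cls == "b", 1:20] <- X[cls == "b", 1:20] + rep(bump, each = sum(cls == "b"))
  meta <- data.frame(subject = rep(sprintf("S%d", 1:n_sub), each = 2 * tpc),
                     trial = rep(1:(2 * tpc), n_sub), condition = cls,
                     stringsAsFactors = FALSE)
  tm <- trial_matrix(X, meta, data.frame(channel = rep("AD", 40), sample = 1:40))
  folds <- make_folds(meta$subject, 3, seed = 1)
  res <- temporal_split_compare(tm, folds, "AD")
  expect_gt(res$accuracy_first_half, res$accuracy_second_half)
  expect_gt(res$accuracy_first_half, 90)
  expect_s3_class(res$test, "stat_test")
  # identical halves: duplicate the first half into the second
  X2 <- X; X2[, 21:40] <- X[, 1:20]
  tm2 <- trial_matrix(X2, meta, tm$index_map)
  res2 <- suppressWarnings(temporal_split_compare(tm2, folds, "AD"))
  expect_equal(res2$accuracy_first_half, res2$accuracy_second_half)
  # odd length: the middle sample goes to the first half
  tm3 <- trial_matrix(X[, 1:39], meta,
                      data.frame(channel = rep("AD", 39), sample = 1:39))
  res3 <- suppressWarnings(temporal_split_compare(tm3, folds, "AD"))
  expect_gt(res3$accuracy_first_half, res3$accuracy_second_half)
  expect_error(temporal_split_compare(tm, folds, "XX"),
               class = "emgdiff_invalid_argument")
})

test_that("when all signal lies in one half, that half matches the full vector", {
  set.seed(17)
  tm <- toy_trial_matrix(p = 20, signal_col = 4, sep = 3, noise = 0.2, seed = 17)
  tm$index_map <- data.frame(channel = rep("AD", 20), sample = 1:20)
  folds <- make_folds(tm$meta$subject, 3, seed = 2)
  full <- cross_validate(tm, folds)$mean_accuracy
  res <- temporal_split_compare(tm, folds, "AD")
  expect_equal(res$accuracy_first_half, full)
})
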