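test_that("fitting recovers sample means, priors and handles degenerate input", {
  X <- rbind(c(0, 0), c(2, 2), c(5, 1), c(7, 3))
  y <- c("k1", "k1", "k2", "k2")
  m <- lda_fit(X, y)
  expect_equal(unname(m$mu["k1", ]), c(1, 1))
  expect_equal(unname(m$mu["k2", ]), c(6, 2))
  expect_equal(unname(m$priors), c(0.5, 0.5))
  # balanced 9 + 9 design: priors are exactly one half
  set.seed(1)
  Xb <- matrix(rnorm(18 * 4), nrow = 18)
  yb <- rep(c("a", "b"), each = 9)
  expect_equal(unname(lda_fit(Xb, yb)$priors), c(0.5, 0.5))
  # duplicating every sample changes neither means nor priors
  m2 <- lda_fit(rbind(Xb, Xb), c(yb, yb))
  expect_equal(m2$mu, lda_fit(Xb, yb)$mu)
  expect_equal(m2$priors, lda_fit(Xb, yb)$priors)
  expect_error(lda_fit(Xb, rep("a", 18)), class = "emgdiff_invalid_argument")
  # zero-variance feature is floored with a warning
  Xz <- cbind(Xb, 1)
  expect_warning(mz <- lda_fit(Xz, yb), "floored")
  expect_true(all(mz$var >= mz$var_floor))
})

test_that("posteriors match a brute-force Bayes-rule oracle", {
  set.seed(42)
  for (i in 1:100) {
    p <- sample(1:5, 1)
    n <- sample(c(12, 20, 30), 1)
    X <- matrix(rnorm(n * p, sd = runif(1, 0.5, 2)), nrow = n)
    y <- sample(rep(c("a", "b"), times = c(floor(n / 3), n - floor(n / 3))))
    m <- lda_fit(X, y)
    x <- rnorm(p)
    post <- lda_posterior(m, x)
    oracle <- posterior_oracle(m, x)
    expect_equal(as.numeric(post), as.numeric(oracle), tolerance = 1e-10)
    expect_equal(sum(post), 1, tolerance = 1e-12)
  }
})

test_that("posterior geometry: means, midpoints and ties behave canonically", {
  m <- structure(list(labels = c("a", "b"),
                      mu = rbind(a = c(1, 0), b = c(0, 1)),
                      priors = c(a = 0.5, b = 0.5), p = 2L,
                      method = "diagonal", var_floor = 1e-8,
                      var = c(1, 1)), class = "lda_model")
  expect_gt(lda_posterior(m, c(1, 0))[, "a"], 0.5)
  mid <- lda_posterior(m, c(0.5, 0.5))
  expect_equal(as.numeric(mid), c(0.5, 0.5))
  # exact tie breaks to the first sorted label
  expect_equal(lda_predict(m, c(0.5, 0.5)), "a")
  expect_equal(lda_predict(m, c(1, 0)), "a")
  expect_error(lda_posterior(m, c(1, 2, 3)), class = "emgdiff_invalid_argument")
})

test_that("posterior of the nearer class is monotone along the mean segment", {
  set.seed(5)
  for (i in 1:10) {
    p <- sample(2:6, 1)
    X <- matrix(rnorm(40 * p), nrow = 40)
    y <- rep(c("a", "b"), each = 20)
    X[y == "b", ] <- X[y == "b", ] + rnorm(p)
    m <- lda_fit(X, y)
    ts <- seq(0, 1, length.out = 21)
    pa <- vapply(ts, function(t) {
      lda_posterior(m, m$mu["b", ] + t * (m$mu["a", ] - m$mu["b", ]))[, "a"]
    }, 0)
    expect_true(all(diff(pa) >= -1e-12))
  }
})

test_that("label encoding does not change the decisions", {
  set.seed(8)
  X <- matrix(rnorm(30 * 4), nrow = 30)
  y <- rep(c("a", "b"), each = 15)
  X[y == "b", 1] <- X[y == "b", 1] + 2
  m1 <- lda_fit(X, y)
  y2 <- ifelse(y == "a", "z_a", "b")  # flips the sorted order
  m2 <- lda_fit(X, y2)
  xnew <- matrix(rnorm(20 * 4), nrow = 20)
  p1 <- lda_predict(m1, xnew)
  p2 <- lda_predict(m2, xnew)
  expect_equal(p1 == "a", p2 == "z_a")
})

test_that("pooled-covariance variant agrees with a reference implementation", {
  set.seed(21)
  for (i in 1:3) {
    p <- 10; n <- 120
    X <- matrix(rnorm(n * p), nrow = n)
    y <- rep(c("a", "b"), each = n / 2)
    X[y == "b", 1:3] <- X[y == "b", 1:3] + 1.2
    m <- lda_fit(X, y, method = "pooled")
    Xt <- matrix(rnorm(200 * p), nrow = 200)
    Xt[101:200, 1:3] <- Xt[101:200, 1:3] + 1.2
    ref <- MASS::lda(X, grouping = y)
    agree <- mean(lda_predict(m, Xt) == as.character(predict(ref, Xt)$class))
    expect_gte(agree, 0.99)
  }
})

test_that("subject-wise cross-validation scores separable and degenerate cases", {
  cfg <- small_cfg(effect_size = 3, noise_sd = 0.02, subject_gain_sd = 0,
                   seed = 6)
  tm <- small_tm(cfg)
  folds <- make_folds(tm$meta$subject, 3, seed = 1)
  cv <- cross_validate(tm, folds)
  expect_equal(cv$mean_accuracy, 100)
  expect_equal(sum(cv$folds$n_right) + sum(cv$folds$n_wrong), nrow(tm$X))
  expect_equal(cv$mean_accuracy, mean(cv$folds$accuracy))
  # no trial is ever predicted by a model trained on its own subject
  merged <- merge(cv$predictions, data.frame(subject = names(folds$fold),
                                             fold_of_subject = folds$fold))
  expect_true(all(merged$fold == merged$fold_of_subject))
  # degenerate plug-in classifier: always predicts class A
  const <- list(fit = function(X, y) list(lab = "A"),
                predict = function(model, X) rep(model$lab, nrow(X)))
  cv_const <- cross_validate(tm, folds, classifier = const)
  expect_equal(cv_const$mean_accuracy, 50)
  expect_equal(sum(cv_const$folds$n_right), sum(tm$meta$condition == "A"))
})

test_that("shuffled labels classify at chance over repeated draws", {
  cfg <- small_cfg(effect_size = 1, seed = 13)
  tm0 <- small_tm(cfg)
  folds <- make_folds(tm0$meta$subject, 3, seed = 2)
  accs <- vapply(1:20, function(s) {
    tm <- tm0
    # permute condition labels within each subject to keep folds trainable
    set.seed(s)
    for (sub in unique(tm$meta$subject)) {
      rows <- which(tm$meta$subject == sub)
      tm$meta$condition[rows] <- sample(tm$meta$condition[rows])
    }
    cross_validate(tm, folds)$mean_accuracy
  }, 0)
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 50), 3 * se + 1e-9)
})

test_that("a training split missing a class raises a fold-degenerate error", {
  X <- matrix(rnorm(12 * 3), nrow = 12)
  meta <- data.frame(subject = rep(c("S1", "S2"), each = 6),
                     trial = rep(1:6, 2),
                     condition = rep(c("a", "b"), times = 6),
                     stringsAsFactors = FALSE)
  meta$condition[meta$subject == "S2"] <- "a"
  tm <- trial_matrix(X, meta)
  folds <- make_folds(c("S1", "S2"), 2, seed = 1)
  expect_error(cross_validate(tm, folds), class = "emgdiff_fold_degenerate")
})

test_that("models serialize to JSON and back without loss", {
  set.seed(3)
  X <- matrix(rnorm(20 * 5), nrow = 20)
  y <- rep(c("a", "b"), each = 10)
  m <- lda_fit(X, y)
  path <- withr::local_tempfile(fileext = ".json")
  write_lda_model(m, path)
  m2 <- read_lda_model(path)
  expect_equal(m2$mu, m$mu)
  expect_equal(m2$var, unname(m$var))
  expect_equal(unname(m2$priors), unname(m$priors))
  expect_equal(lda_predict(m2, X), lda_predict(m, X))
})
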