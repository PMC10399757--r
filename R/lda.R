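#' Fit a binary Gaussian discriminant (LDA) model
#'
#' Models each class as a multivariate Gaussian with its own mean vector and
#' a covariance shared between the classes; class priors are the training
#' class proportions. With `method = "diagonal"` (the default) the shared
#' covariance is the pooled within-class *diagonal* — the standard stable
#' choice when the number of features far exceeds the number of trials, as
#' with concatenated EMG vectors (p = 9000 against at most a few hundred
#' trials), where the full pooled covariance is necessarily singular. With
#' `method = "pooled"` the full pooled covariance is used (pseudo-inverted
#' when singular), appropriate for low-dimensional problems.
#'
#' @param X n x p numeric matrix of training vectors.
#' @param y class labels; exactly two distinct labels must be present, each
#'   with at least two samples.
#' @param method `"diagonal"` or `"pooled"`.
#' @param var_floor lower bound applied to pooled variances; features with
#'   zero within-class variance are floored to this value with a warning.
#' @return An object of class `lda_model` with elements `labels` (the two
#'   class labels in sorted order), `mu` (2 x p matrix of class means),
#'   `priors`, `p`, `method`, and the covariance representation (`var` for
#'   diagonal, `sigma_inv` for pooled).
#' @export
lda_fit <- function(X, y, method = c("diagonal", "pooled"), var_floor = 1e-8) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- as.character(y)
  if (nrow(X) != length(y)) stop_invalid("X rows and y length differ")
  labels <- sort(unique(y))
  if (length(labels) != 2L) {
    stop_invalid("exactly two classes must be present (got ", length(labels), ")")
  }
  n_k <- c(sum(y == labels[1L]), sum(y == labels[2L]))
  if (any(n_k < 2L)) stop_invalid("each class needs at least 2 samples")
  n <- nrow(X)
  p <- ncol(X)
  mu <- rbind(colMeans(X[y == labels[1L], , drop = FALSE]),
              colMeans(X[y == labels[2L], , drop = FALSE]))
  rownames(mu) <- labels
  model <- list(labels = labels, mu = mu, priors = stats::setNames(n_k / n, labels),
                p = p, method = method, var_floor = var_floor)
  C1 <- sweep(X[y == labels[1L], , drop = FALSE], 2L, mu[1L, ])
  C2 <- sweep(X[y == labels[2L], , drop = FALSE], 2L, mu[2L, ])
  if (method == "diagonal") {
    v <- (colSums(C1^2) + colSums(C2^2)) / (n - 2L)
    if (p > 0L && any(v < var_floor)) {
      warning(sum(v < var_floor), " feature(s) with near-zero pooled variance",
              " floored at ", var_floor)
      v <- pmax(v, var_floor)
    }
    model$var <- v
  } else {
    S <- (crossprod(C1) + crossprod(C2)) / (n - 2L)
    model$sigma_inv <- tryCatch(solve(S), error = function(e) {
      warning("pooled covariance is singular; using the Moore-Penrose pseudo-inverse")
      MASS::ginv(S)
    })
  }
  structure(model, class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("lda_model (%s): classes %s vs %s, p = %d, priors %.3f / %.3f\n",
              x$method, x$labels[1L], x$labels[2L], x$p,
              x$priors[1L], x$priors[2L]))
  invisible(x)
}

## Per-class log posterior numerators, computed in log space: Gaussian
## log-density plus log prior. With a covariance shared across classes the
## normalization constant cancels in the posterior; it is included for the
## diagonal representation (where it is cheap and makes the log-densities
## exact) and dropped for the pooled one.
lda_log_posterior_num <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$p) {
    stop_invalid("x has ", ncol(X), " features but the model expects ", model$p)
  }
  ll <- matrix(0, nrow = nrow(X), ncol = 2L,
               dimnames = list(NULL, model$labels))
  for (k in 1:2) {
    C <- sweep(X, 2L, model$mu[k, ])
    if (model$method == "diagonal") {
      q <- as.numeric(C^2 %*% (1 / model$var))
      const <- -0.5 * sum(log(2 * pi * model$var))
    } else {
      q <- rowSums((C %*% model$sigma_inv) * C)
      const <- 0
    }
    ll[, k] <- const - 0.5 * q + log(model$priors[k])
  }
  ll
}

#' Posterior class probabilities under a fitted LDA model
#'
#' Bayes-rule posteriors computed from the class-conditional Gaussian
#' log-densities and log priors, normalized in log space so the computation
#' is stable at very high dimension (raw densities of 9000-element vectors
#' under- or overflow).
#'
#' @param model an `lda_model`.
#' @param x a p-vector or an n x p matrix.
#' @return An n x 2 matrix of probabilities (columns named by class label);
#'   each row sums to 1.
#' @export
lda_posterior <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  ll <- lda_log_posterior_num(model, x)
  m <- pmax(ll[, 1L], ll[, 2L])
  w <- exp(ll - m)
  w / rowSums(w)
}

#' Predict class labels under a fitted LDA model
#'
#' Assigns each vector to the class with the larger posterior; an exact tie
#' goes deterministically to the first class label in sorted order.
#'
#' @param model an `lda_model`.
#' @param x a p-vector or an n x p matrix.
#' @return Character vector of predicted labels.
#' @export
lda_predict <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  ll <- lda_log_posterior_num(model, x)
  model$labels[max.col(ll, ties.method = "first")]
}

#' A plug-in classifier wrapping the package's LDA
#'
#' [cross_validate()] and [threshold_search()] accept any classifier given
#' as a list with `fit(X, y)` and `predict(model, X)` functions, so external
#' algorithms can be plugged in. This constructor builds the default LDA
#' pair.
#'
#' @param method,var_floor passed to [lda_fit()].
#' @return A list with elements `fit`, `predict` and `name`.
#' @export
lda_classifier <- function(method = "diagonal", var_floor = 1e-8) {
  list(
    fit = function(X, y) lda_fit(X, y, method = method, var_floor = var_floor),
    predict = function(model, X) lda_predict(model, X),
    name = paste0("lda_", method)
  )
}

#' Subject-wise cross-validated classification
#'
#' For each fold: fit the classifier on the trials of all other folds,
#' predict the held-out trials, and tally right and wrong answers. Because
#' folds partition subjects, no subject's data ever plays training and
#' testing roles at the same time. The summary accuracy is the mean of the
#' per-fold accuracies, in percent.
#'
#' @param tm a `trial_matrix`.
#' @param folds a [make_folds()] assignment covering all subjects in `tm`.
#' @param classifier a fit/predict pair, e.g. [lda_classifier()].
#' @param features optional column subset (integer or logical) restricting
#'   the classification to those features; an empty selection degenerates to
#'   a prior-only rule.
#' @return An object of class `cv_result`: list with `folds` (per-fold
#'   data.frame: fold, n_right, n_wrong, accuracy), `predictions` (per-trial
#'   data.frame), and `mean_accuracy` (percent).
#' @export
cross_validate <- function(tm, folds, classifier = lda_classifier(),
                           features = NULL) {
  if (!inherits(tm, "trial_matrix")) stop_invalid("tm must be a trial_matrix")
  if (!inherits(folds, "fold_assignment")) stop_invalid("folds must be a fold_assignment")
  if (folds$k < 2L) stop_invalid("need at least 2 folds")
  missing_sub <- setdiff(unique(tm$meta$subject), names(folds$fold))
  if (length(missing_sub)) {
    stop_invalid("subjects without a fold: ", paste(missing_sub, collapse = ", "))
  }
  X <- if (is.null(features)) tm$X else tm$X[, features, drop = FALSE]
  y <- tm$meta$condition
  trial_fold <- unname(folds$fold[tm$meta$subject])
  fold_stats <- data.frame(fold = seq_len(folds$k), n_right = 0L, n_wrong = 0L,
                           accuracy = NA_real_)
  preds <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    test <- which(trial_fold == f)
    train <- which(trial_fold != f)
    if (!length(test)) next
    if (length(unique(y[train])) < 2L) {
      stop_with_class("emgdiff_fold_degenerate",
                      paste0("training split for fold ", f, " is missing a class"))
    }
    model <- classifier$fit(X[train, , drop = FALSE], y[train])
    pred <- classifier$predict(model, X[test, , drop = FALSE])
    ok <- pred == y[test]
    fold_stats$n_right[f] <- sum(ok)
    fold_stats$n_wrong[f] <- sum(!ok)
    fold_stats$accuracy[f] <- 100 * mean(ok)
    preds[[f]] <- data.frame(subject = tm$meta$subject[test],
                             trial = tm$meta$trial[test],
                             condition = y[test], fold = f,
                             predicted = pred, correct = ok,
                             stringsAsFactors = FALSE)
  }
  fold_stats <- fold_stats[!is.na(fold_stats$accuracy), , drop = FALSE]
  structure(list(
    folds = fold_stats,
    predictions = do.call(rbind, preds),
    mean_accuracy = mean(fold_stats$accuracy)
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: mean accuracy %.2f%% over %d folds (right %d / wrong %d)\n",
              x$mean_accuracy, nrow(x$folds), sum(x$folds$n_right),
              sum(x$folds$n_wrong)))
  invisible(x)
}
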