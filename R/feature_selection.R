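#' Class-mean difference vector of a fitted model
#'
#' The elementwise absolute difference between the two class mean vectors —
#' the importance score this method assigns to every feature. Features where
#' the two class representations differ strongly are the ones that carried
#' the classification.
#'
#' @param model an `lda_model`.
#' @return Non-negative numeric p-vector.
#' @export
lda_diff <- function(model) {
  if (!inherits(model, "lda_model")) stop_invalid("model must be an lda_model")
  abs(model$mu[1L, ] - model$mu[2L, ])
}

#' Composite between-class separation index
#'
#' The sum of all elements of the class-mean difference vector: a single
#' non-negative number quantifying how far apart the two class
#' representations are overall. Zero exactly when the class means coincide.
#'
#' @param diff a non-negative difference vector (from [lda_diff()]).
#' @return Non-negative scalar.
#' @export
lda_distance <- function(diff) {
  if (!is.numeric(diff) || any(diff < 0)) {
    stop_invalid("diff must be a non-negative numeric vector")
  }
  sum(diff)
}

#' Cross-validation-averaged class-mean difference vector
#'
#' Fits the model on each fold's training split, differences the class
#' means, and averages the per-fold difference vectors. Because
#' normalization precedes the fold split, per-fold difference vectors are
#' near-identical; averaging gives one well-defined reported vector.
#'
#' @param tm a `trial_matrix`.
#' @param folds a fold assignment.
#' @param method,var_floor passed to [lda_fit()].
#' @return Non-negative numeric p-vector.
#' @export
fold_average_diff <- function(tm, folds, method = "diagonal", var_floor = 1e-8) {
  trial_fold <- unname(folds$fold[tm$meta$subject])
  acc <- numeric(ncol(tm$X))
  n_used <- 0L
  for (f in seq_len(folds$k)) {
    train <- which(trial_fold != f)
    if (length(unique(tm$meta$condition[train])) < 2L) next
    model <- lda_fit(tm$X[train, , drop = FALSE], tm$meta$condition[train],
                     method = method, var_floor = var_floor)
    acc <- acc + lda_diff(model)
    n_used <- n_used + 1L
  }
  if (!n_used) stop_invalid("no fold yields a two-class training split")
  acc / n_used
}

#' Iterative cutoff-threshold partition into High-Diff and Low-Diff features
#'
#' Scans a cutoff on the class-mean difference vector from its maximum
#' downward in decrements of `step_frac` of the range. At each step the
#' features strictly above the cutoff (the High-Diff set) and those at or
#' below it (the Low-Diff set) are classified separately under the same
#' subject-wise cross-validation — non-selected features are removed, not
#' zeroed. The scan stops at the first cutoff where the High-Diff accuracy
#' exceeds the Low-Diff accuracy with a non-empty High-Diff set. If the
#' scan reaches the minimum of the difference vector without success, an
#' error of class `emgdiff_selection_failed` carrying the full search trace
#' is raised.
#'
#' @param tm a `trial_matrix` (normalized).
#' @param folds a fold assignment.
#' @param classifier a fit/predict pair, e.g. [lda_classifier()].
#' @param step_frac cutoff decrement as a fraction of the difference range,
#'   in (0, 0.5] (default 0.05, a 20-step scan).
#' @param diff optional difference vector; defaults to
#'   [fold_average_diff()] on `tm`.
#' @param min_frac channel-membership threshold passed to
#'   [channels_from_mask()].
#' @return An object of class `feature_selection`: list with `lda_diff`,
#'   `threshold`, `high_mask`, `low_mask`, `high_channels`, `low_channels`
#'   (the complement of the High-Diff channels), `lda_distance`,
#'   `accuracy_high`, `accuracy_low` (percent) and `search_trace` (one row
#'   per scanned threshold).
#' @export
threshold_search <- function(tm, folds, classifier = lda_classifier(),
                             step_frac = 0.05, diff = NULL, min_frac = 0) {
  step_frac <- check_number(step_frac, "step_frac", min = 1e-9, max = 0.5)
  if (is.null(diff)) diff <- fold_average_diff(tm, folds)
  if (length(diff) != ncol(tm$X)) stop_invalid("diff length must match ncol(tm$X)")
  hi <- max(diff); lo <- min(diff)
  if (!(hi > lo) || hi <= 0) {
    stop_invalid("difference vector is constant; nothing to threshold")
  }
  n_steps <- ceiling(1 / step_frac)
  trace <- data.frame(threshold = numeric(0), n_high = integer(0),
                      accuracy_high = numeric(0), accuracy_low = numeric(0))
  for (j in seq_len(n_steps)) {
    thr <- hi - j * step_frac * (hi - lo)
    if (j == n_steps) thr <- lo
    high <- diff > thr
    if (!any(high)) {
      trace[nrow(trace) + 1L, ] <- list(thr, 0L, NA_real_, NA_real_)
      next
    }
    acc_high <- cross_validate(tm, folds, classifier, features = which(high))$mean_accuracy
    acc_low <- cross_validate(tm, folds, classifier,
                              features = which(!high))$mean_accuracy
    trace[nrow(trace) + 1L, ] <- list(thr, sum(high), acc_high, acc_low)
    if (acc_high > acc_low) {
      return(structure(list(
        lda_diff = diff, threshold = thr,
        high_mask = high, low_mask = !high,
        high_channels = channels_from_mask(high, tm$index_map, min_frac),
        low_channels = setdiff(unique(tm$index_map$channel),
                               channels_from_mask(high, tm$index_map, min_frac)),
        lda_distance = lda_distance(diff),
        accuracy_high = acc_high, accuracy_low = acc_low,
        search_trace = trace
      ), class = "feature_selection"))
    }
  }
  stop_with_class("emgdiff_selection_failed",
                  "no threshold yields higher accuracy above than below",
                  data = trace)
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf(paste0("feature_selection: threshold %.4g, %d/%d features High-Diff\n",
                     "  High-Diff channels: %s\n",
                     "  accuracy high %.2f%% vs low %.2f%%; separation index %.4g\n"),
              x$threshold, sum(x$high_mask), length(x$high_mask),
              paste(x$high_channels, collapse = ", "),
              x$accuracy_high, x$accuracy_low, x$lda_distance))
  invisible(x)
}

#' Channels containing parts of a feature mask
#'
#' A channel is included when the fraction of its features set in the mask
#' exceeds zero (`min_frac = 0`, the "contains parts" reading) or is at
#' least `min_frac` when a positive threshold is given (to suppress
#' single-sample noise).
#'
#' @param mask logical p-vector.
#' @param index_map the matching index map.
#' @param min_frac minimum masked fraction for membership.
#' @return Character vector of channel labels, in index-map order.
#' @export
channels_from_mask <- function(mask, index_map, min_frac = 0) {
  if (length(mask) != nrow(index_map)) {
    stop_invalid("mask length must equal the index map length")
  }
  min_frac <- check_number(min_frac, "min_frac", min = 0, max = 1)
  chans <- unique(index_map$channel)
  frac <- vapply(chans, function(ch) mean(mask[index_map$channel == ch]), 0)
  keep <- if (min_frac == 0) frac > 0 else frac >= min_frac
  chans[keep]
}

#' Compare classification on the first vs second half of one channel
#'
#' Restricts the trial matrix to a single channel, splits its time base into
#' first and second halves (an odd middle sample goes to the first half),
#' cross-validates each half separately, and compares the pooled right/wrong
#' counts with a chi-squared test. Used to ask *when* within the movement
#' the discriminative adjustments occur.
#'
#' @param tm a `trial_matrix`.
#' @param folds a fold assignment.
#' @param channel channel label to analyse.
#' @param classifier a fit/predict pair.
#' @param alpha,m_comparisons significance level and Bonferroni divisor for
#'   the chi-squared comparison.
#' @return A list with `accuracy_first_half`, `accuracy_second_half`
#'   (percent), the two `cv_result`s, and `test` (a `stat_test`).
#' @export
temporal_split_compare <- function(tm, folds, channel,
                                   classifier = lda_classifier(),
                                   alpha = 0.05, m_comparisons = 1) {
  cols <- which(tm$index_map$channel == channel)
  if (!length(cols)) stop_invalid("channel ", channel, " not in the index map")
  L <- length(cols)
  first <- cols[seq_len(ceiling(L / 2))]
  second <- setdiff(cols, first)
  cv1 <- cross_validate(tm, folds, classifier, features = first)
  cv2 <- cross_validate(tm, folds, classifier, features = second)
  # a zero right or wrong column (e.g. both halves at 100%) leaves the
  # chi-squared table degenerate; report the accuracies without a test then
  test <- tryCatch(
    chi2_accuracy_test(sum(cv1$folds$n_right), sum(cv1$folds$n_wrong),
                       sum(cv2$folds$n_right), sum(cv2$folds$n_wrong),
                       alpha = alpha, m_comparisons = m_comparisons),
    emgdiff_degenerate_table = function(e) NULL)
  list(accuracy_first_half = cv1$mean_accuracy,
       accuracy_second_half = cv2$mean_accuracy,
       cv_first = cv1, cv_second = cv2, test = test)
}
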