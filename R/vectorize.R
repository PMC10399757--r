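#' Concatenate a trial's channels into one feature vector
#'
#' Lays the per-channel time series end to end in the declared channel order
#' and records the provenance of every element, so any position in the
#' vector can be traced back to (channel, within-channel sample).
#'
#' @param channels a samples x channels numeric matrix with column names, or
#'   a named list of equal-length numeric vectors.
#' @param channel_order optional character vector fixing the concatenation
#'   order; defaults to the order the channels are supplied in.
#' @return A list with `x` (the concatenated vector, length
#'   `n_channels * samples`) and `index_map` (a data.frame with columns
#'   `channel` and `sample`).
#' @export
concatenate_trial <- function(channels, channel_order = NULL) {
  if (is.list(channels) && !is.data.frame(channels)) {
    lens <- lengths(channels)
    if (length(unique(lens)) != 1L) {
      stop_invalid("all channels must have the same length (ragged input)")
    }
    channels <- do.call(cbind, channels)
  }
  channels <- as.matrix(channels)
  if (is.null(colnames(channels))) {
    colnames(channels) <- sprintf("CH%02d", seq_len(ncol(channels)))
  }
  if (!is.null(channel_order)) {
    if (!setequal(channel_order, colnames(channels))) {
      stop_invalid("channel_order must be a permutation of the channel names")
    }
    channels <- channels[, channel_order, drop = FALSE]
  }
  L <- nrow(channels)
  list(
    x = as.numeric(channels),
    index_map = data.frame(
      channel = rep(colnames(channels), each = L),
      sample = rep(seq_len(L), times = ncol(channels)),
      stringsAsFactors = FALSE)
  )
}

#' Recover per-channel series from a concatenated vector
#'
#' Inverse of [concatenate_trial()]: splits `x` by the index map back into
#' the original channel series.
#'
#' @param x concatenated feature vector.
#' @param index_map the matching index map.
#' @return A named list of numeric vectors, one per channel.
#' @export
de_concatenate <- function(x, index_map) {
  if (length(x) != nrow(index_map)) stop_invalid("x and index_map lengths differ")
  split(x, factor(index_map$channel, levels = unique(index_map$channel)))
}

#' Build the trial-by-feature matrix for a dataset
#'
#' Concatenates every trial (all trials must share channel names and
#' lengths) into one row of a matrix whose columns follow a fixed,
#' documented channel order.
#'
#' @param dataset an `emg_dataset` of equal-length trials (after
#'   preprocessing, or envelope-mode synthetic data).
#' @param channel_order optional channel order; defaults to the column order
#'   of the first trial.
#' @return An object of class `trial_matrix`: list with `X` (n_trials x p),
#'   `meta` (data.frame: subject, trial, condition), and `index_map`.
#' @export
vectorize_dataset <- function(dataset, channel_order = NULL) {
  trials <- dataset$trials
  if (!length(trials)) stop_invalid("dataset has no trials")
  first <- concatenate_trial(trials[[1L]]$channels, channel_order)
  p <- length(first$x)
  X <- matrix(0, nrow = length(trials), ncol = p)
  X[1L, ] <- first$x
  order_used <- unique(first$index_map$channel)
  for (i in seq_along(trials)[-1L]) {
    ci <- concatenate_trial(trials[[i]]$channels, order_used)
    if (length(ci$x) != p) stop_invalid("trial ", i, " has a different vector length")
    X[i, ] <- ci$x
  }
  meta <- data.frame(
    subject = vapply(trials, `[[`, "", "subject"),
    trial = vapply(trials, function(t) as.integer(t$trial), 0L),
    condition = vapply(trials, `[[`, "", "condition"),
    stringsAsFactors = FALSE)
  trial_matrix(X, meta, first$index_map)
}

#' Construct a trial matrix from its parts
#'
#' @param X n_trials x p numeric matrix.
#' @param meta data.frame with columns `subject`, `trial`, `condition`.
#' @param index_map data.frame with columns `channel`, `sample` (one row per
#'   feature); a default single-channel map is built when omitted.
#' @return An object of class `trial_matrix`.
#' @export
trial_matrix <- function(X, meta, index_map = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != nrow(meta)) stop_invalid("X and meta row counts differ")
  if (!all(c("subject", "trial", "condition") %in% names(meta))) {
    stop_invalid("meta must have subject, trial, condition columns")
  }
  if (is.null(index_map)) {
    index_map <- data.frame(channel = rep("CH01", ncol(X)),
                            sample = seq_len(ncol(X)), stringsAsFactors = FALSE)
  }
  if (nrow(index_map) != ncol(X)) stop_invalid("index_map must have one row per feature")
  structure(list(X = X, meta = meta, index_map = index_map),
            class = "trial_matrix")
}

#' @export
print.trial_matrix <- function(x, ...) {
  cat(sprintf("trial_matrix: %d trials x %d features (%d channels), %d subjects\n",
              nrow(x$X), ncol(x$X), length(unique(x$index_map$channel)),
              length(unique(x$meta$subject))))
  cat("conditions:", paste(unique(x$meta$condition), collapse = ", "), "\n")
  invisible(x)
}

#' Per-subject, per-channel min-max normalization to [-1, 1]
#'
#' Within each subject and channel, the maximum value over all trials of a
#' normalization group is mapped to 1 and the minimum to -1, all other
#' values linearly in between. With `grouping = "per_class"` (the default)
#' the min and max are computed separately for each condition; with
#' `"joint"` they are computed over both conditions together, which is the
#' variant that preserves between-condition amplitude differences. A channel
#' that is constant within a group is mapped to all zeros with a warning.
#'
#' @param tm a `trial_matrix`.
#' @param grouping `"per_class"` or `"joint"`.
#' @return The trial matrix with `X` rescaled.
#' @export
minmax_normalize <- function(tm, grouping = c("per_class", "joint")) {
  grouping <- match.arg(grouping)
  X <- tm$X
  chan <- tm$index_map$channel
  groups <- if (grouping == "per_class") tm$meta$condition else
    rep("all", nrow(X))
  for (s in unique(tm$meta$subject)) {
    for (g in unique(groups)) {
      rows <- which(tm$meta$subject == s & groups == g)
      if (!length(rows)) next
      for (ch in unique(chan)) {
        cols <- which(chan == ch)
        block <- X[rows, cols, drop = FALSE]
        lo <- min(block); hi <- max(block)
        if (hi > lo) {
          X[rows, cols] <- 2 * (block - lo) / (hi - lo) - 1
        } else {
          warning("constant channel ", ch, " for subject ", s,
                  " (group ", g, "); mapped to 0")
          X[rows, cols] <- 0
        }
      }
    }
  }
  tm$X <- X
  tm
}

#' Assign subjects to cross-validation folds
#'
#' Subjects are shuffled with the given seed and dealt round-robin into `k`
#' folds, so fold sizes differ by at most one subject (e.g. 11 subjects in 5
#' folds give sizes 2, 2, 2, 2, 3). All trials of a subject share its fold,
#' so no subject ever contributes to both training and test sets of a split.
#'
#' @param subjects character vector of subject ids (duplicates allowed and
#'   collapsed).
#' @param k number of folds (must not exceed the number of subjects).
#' @param seed integer seed for the shuffle.
#' @return An object of class `fold_assignment`: list with `fold` (named
#'   integer vector, one entry per subject) and `k`.
#' @export
make_folds <- function(subjects, k, seed = 1L) {
  ids <- unique(as.character(subjects))
  k <- check_count(k, "k")
  if (k > length(ids)) stop_invalid("k must not exceed the number of subjects")
  shuffled <- with_seed(seed, sample(ids))
  fold <- stats::setNames(rep_len(seq_len(k), length(ids)), shuffled)
  structure(list(fold = fold[ids], k = k), class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("fold_assignment: %d subjects in %d folds (sizes %s)\n",
              length(x$fold), x$k,
              paste(sort(as.integer(table(x$fold))), collapse = ", ")))
  invisible(x)
}
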