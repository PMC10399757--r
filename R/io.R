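#' Long-format view of a dataset
#'
#' @param dataset an `emg_dataset`.
#' @return A `data.table` with columns `subject`, `trial`, `condition`,
#'   `channel`, `sample`, `value` (one row per sample).
#' @export
emg_long_format <- function(dataset) {
  data.table::rbindlist(lapply(dataset$trials, function(tr) {
    ch <- as.matrix(tr$channels)
    data.table::data.table(
      subject = tr$subject, trial = tr$trial, condition = tr$condition,
      channel = rep(colnames(ch), each = nrow(ch)),
      sample = rep(seq_len(nrow(ch)), times = ncol(ch)),
      value = as.numeric(ch))
  }))
}

#' Write / read a dataset as long-format CSV
#'
#' The on-disk schema is the package's exchange format: columns `subject`,
#' `trial`, `condition`, `channel`, `sample`, `value`.
#'
#' @param dataset an `emg_dataset`.
#' @param path CSV file path.
#' @return `write_emg_csv` invisibly returns `path`; `read_emg_csv` returns
#'   an `emg_dataset`.
#' @export
write_emg_csv <- function(dataset, path) {
  data.table::fwrite(emg_long_format(dataset), path)
  invisible(path)
}

#' @rdname write_emg_csv
#' @param sampling_rate sampling rate to attach to the trials (the CSV does
#'   not carry it).
#' @export
read_emg_csv <- function(path, sampling_rate = 1000) {
  long <- data.table::fread(path)
  need <- c("subject", "trial", "condition", "channel", "sample", "value")
  if (!all(need %in% names(long))) {
    stop_invalid("CSV must have columns ", paste(need, collapse = ", "))
  }
  keys <- unique(long[, c("subject", "trial", "condition")])
  channels_order <- unique(long$channel)
  trials <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- long[long$subject == keys$subject[i] & long$trial == keys$trial[i] &
                  long$condition == keys$condition[i], ]
    L <- max(sub$sample)
    ch <- matrix(NA_real_, nrow = L, ncol = length(channels_order),
                 dimnames = list(NULL, channels_order))
    for (cn in channels_order) {
      rows <- sub[sub$channel == cn, ]
      ch[rows$sample, cn] <- rows$value
    }
    list(subject = as.character(keys$subject[i]),
         trial = as.integer(keys$trial[i]),
         condition = as.character(keys$condition[i]),
         sampling_rate = sampling_rate, channels = ch)
  })
  structure(list(trials = trials, config = NULL, ground_truth = NULL),
            class = "emg_dataset")
}

#' Write the ground-truth sidecar of a synthetic dataset
#'
#' @param dataset an `emg_dataset` carrying `ground_truth`.
#' @param path JSON file path.
#' @export
write_ground_truth <- function(dataset, path) {
  if (is.null(dataset$ground_truth)) stop_invalid("dataset has no ground truth")
  jsonlite::write_json(dataset$ground_truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a trial matrix as delimited text plus a JSON index map
#'
#' The matrix file is tab-separated with columns `subject`, `trial`,
#' `condition` followed by the p feature values.
#'
#' @param tm a `trial_matrix`.
#' @param matrix_path TSV file path.
#' @param index_path JSON index-map path.
#' @export
write_trial_matrix <- function(tm, matrix_path, index_path) {
  dt <- data.table::data.table(subject = tm$meta$subject, trial = tm$meta$trial,
                               condition = tm$meta$condition)
  dt <- cbind(dt, data.table::as.data.table(tm$X))
  data.table::fwrite(dt, matrix_path, sep = "\t")
  jsonlite::write_json(tm$index_map, index_path, digits = NA)
  invisible(matrix_path)
}

#' @rdname write_trial_matrix
#' @export
read_trial_matrix <- function(matrix_path, index_path) {
  dt <- data.table::fread(matrix_path, sep = "\t")
  meta <- data.frame(subject = as.character(dt$subject),
                     trial = as.integer(dt$trial),
                     condition = as.character(dt$condition),
                     stringsAsFactors = FALSE)
  X <- as.matrix(dt[, -(1:3)])
  dimnames(X) <- NULL
  index_map <- as.data.frame(jsonlite::read_json(index_path, simplifyVector = TRUE))
  trial_matrix(X, meta, index_map)
}

#' Write / read a fold assignment as JSON
#'
#' @param folds a `fold_assignment`.
#' @param path JSON file path.
#' @export
write_folds <- function(folds, path) {
  jsonlite::write_json(list(k = folds$k, fold = as.list(folds$fold)), path,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_folds
#' @export
read_folds <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(fold = unlist(obj$fold), k = as.integer(obj$k)),
            class = "fold_assignment")
}

#' Serialize / restore a fitted LDA model as JSON
#'
#' Stores labels, priors, class means, the diagonal variance vector (or the
#' pooled inverse covariance) and the fitting configuration.
#'
#' @param model an `lda_model`.
#' @param path JSON file path.
#' @export
write_lda_model <- function(model, path) {
  obj <- list(labels = model$labels, priors = as.list(model$priors),
              mu = unname(split(model$mu, row(model$mu))), p = model$p,
              method = model$method, var_floor = model$var_floor)
  if (model$method == "diagonal") obj$var <- model$var else
    obj$sigma_inv <- model$sigma_inv
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lda_model
#' @export
read_lda_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mu <- if (is.list(obj$mu)) do.call(rbind, obj$mu) else as.matrix(obj$mu)
  rownames(mu) <- obj$labels
  model <- list(labels = obj$labels, mu = mu,
                priors = stats::setNames(unlist(obj$priors), obj$labels),
                p = as.integer(obj$p), method = obj$method,
                var_floor = obj$var_floor)
  if (obj$method == "diagonal") model$var <- obj$var else
    model$sigma_inv <- as.matrix(obj$sigma_inv)
  structure(model, class = "lda_model")
}
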