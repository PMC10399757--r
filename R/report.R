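#' Assemble a machine-readable analysis report
#'
#' Gathers the classification, feature-selection and statistical outputs of
#' one or more binary comparisons into a single list suitable for JSON
#' serialization, together with a configuration echo so a run can be
#' reproduced. The Bonferroni-corrected level over the configured number of
#' comparisons is included (0.0125 for four comparisons at alpha 0.05).
#'
#' @param comparisons named list; each element is a list with components
#'   `cv` (a `cv_result`), optionally `selection` (a `feature_selection`, or
#'   `NULL` if selection failed), optionally `temporal` (from
#'   [temporal_split_compare()]) and `stat_tests` (named list of
#'   `stat_test`s).
#' @param config list echoing the run configuration (including seeds).
#' @param alpha base significance level.
#' @return A plain list of class `emgdiff_report`.
#' @export
build_report <- function(comparisons, config = list(), alpha = 0.05) {
  if (!length(comparisons) || is.null(names(comparisons))) {
    stop_invalid("comparisons must be a non-empty named list")
  }
  m <- length(comparisons)
  out_cmp <- lapply(comparisons, function(cmp) {
    entry <- list(
      mean_accuracy = cmp$cv$mean_accuracy,
      n_right = sum(cmp$cv$folds$n_right),
      n_wrong = sum(cmp$cv$folds$n_wrong),
      per_fold_accuracy = cmp$cv$folds$accuracy
    )
    if (!is.null(cmp[["selection"]])) {
      sel <- cmp$selection
      entry$selection <- list(
        threshold = sel$threshold,
        n_high_features = sum(sel$high_mask),
        high_channels = sel$high_channels,
        low_channels = sel$low_channels,
        accuracy_high = sel$accuracy_high,
        accuracy_low = sel$accuracy_low,
        lda_distance = sel$lda_distance
      )
    } else {
      entry$selection_failed <- TRUE
    }
    if (!is.null(cmp$temporal)) {
      entry$temporal <- list(
        accuracy_first_half = cmp$temporal$accuracy_first_half,
        accuracy_second_half = cmp$temporal$accuracy_second_half,
        p_value = cmp$temporal$test$p_value
      )
    }
    if (!is.null(cmp$stat_tests)) {
      entry$stat_tests <- lapply(cmp$stat_tests, function(st) {
        list(test = st$test_name, statistic = st$statistic,
             p_value = st$p_value, corrected_alpha = st$corrected_alpha,
             significant = st$significant)
      })
    }
    entry
  })
  structure(list(
    config = config,
    alpha = alpha,
    n_comparisons = m,
    corrected_alpha = bonferroni(alpha, m),
    comparisons = out_cmp
  ), class = "emgdiff_report")
}

#' Write a report as JSON and Markdown
#'
#' @param report an `emgdiff_report` from [build_report()].
#' @param dir output directory (created if absent); writes `report.json` and
#'   `report.md`.
#' @return Invisibly, the path of the JSON file.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  md <- c("# Classification and feature-selection report", "",
          sprintf("Significance level %.4g over %d comparison(s): corrected alpha %.4g",
                  report$alpha, report$n_comparisons, report$corrected_alpha), "")
  for (nm in names(report$comparisons)) {
    cmp <- report$comparisons[[nm]]
    md <- c(md, sprintf("## %s", nm),
            sprintf("- mean accuracy: %.2f%% (right %d / wrong %d)",
                    cmp$mean_accuracy, cmp$n_right, cmp$n_wrong))
    if (!is.null(cmp[["selection"]])) {
      md <- c(md,
              sprintf("- High-Diff channels: %s",
                      paste(cmp$selection$high_channels, collapse = ", ")),
              sprintf("- accuracy High-Diff %.2f%% vs Low-Diff %.2f%%",
                      cmp$selection$accuracy_high, cmp$selection$accuracy_low),
              sprintf("- separation index: %.4g", cmp$selection$lda_distance))
    } else if (isTRUE(cmp$selection_failed)) {
      md <- c(md, "- feature selection: no qualifying threshold (selection failed)")
    }
    md <- c(md, "")
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(json_path)
}
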