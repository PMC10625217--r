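# Published benchmark results shipped with the package.

#' Reported benchmark metrics on the neck-pain screening corpus
#'
#' Percentage metrics (precision, recall, specificity, accuracy, F1, AUC)
#' reported for the attention screening model and its competitors on the
#' held-out test split of the original neck-pain corpus, as published.
#' `"baselines"` holds the model-comparison table (random forest,
#' L1-penalized logistic regression, BiLSTM with and without attention,
#' TextCNN, TextRCNN, a fine-tuned biomedical transformer, and the full
#' attention screener); `"ablation"` holds the feature-ablation table
#' (title/abstract/journal feature subsets).
#'
#' These are reference values for arithmetic consistency checks (e.g.
#' recomputing F1 from a row's precision and recall, or metric deltas
#' between models); the package does not reproduce the underlying corpus.
#'
#' @param which `"baselines"` or `"ablation"`.
#' @return data frame with a `model` column and percentage metric columns.
#' @export
reported_benchmarks <- function(which = c("baselines", "ablation")) {
  which <- match.arg(which)
  path <- system.file("extdata",
    paste0("benchmark_", which, ".csv"),
    package = "guidescreen", mustWork = TRUE
  )
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' One benchmark row as a metrics report
#'
#' @param model model name as listed in [reported_benchmarks].
#' @param which table to look in.
#' @return `metrics_report` with the row's percentage metrics.
#' @export
benchmark_report <- function(model, which = c("baselines", "ablation")) {
  tab <- reported_benchmarks(which)
  row <- tab[tab$model == model, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop(sprintf("unknown benchmark model '%s'", model), call. = FALSE)
  }
  do.call(metrics_from_rates, as.list(row[, -1L]))
}
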