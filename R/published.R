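#' Published confusion matrices for the panel and single-gene classifiers
#'
#' The confusion counts (TP/FN/FP/TN) reported for the k-means discrimination
#' of viral versus bacterial infections, the discrimination of SLE from
#' diseases with a bacterial dysregulation pattern, and the cross-dataset
#' single-gene logistic biomarkers, together with the published two-decimal
#' F1 values.  Shipped as a plain-text table so the metric computations can
#' be checked against the printed numbers.
#'
#' Note the published recall/precision columns are internally inconsistent
#' with the stated formulas (they appear swapped for several rows); the F1
#' column is self-consistent and is the value retained here.
#'
#' @return Data.frame with columns `table`, `dataset`, `comparison`, `model`,
#'   `gene`, `tp`, `fn`, `fp`, `tn`, `f1_published`.
#' @export
published_confusion_tables <- function() {
  path <- system.file("extdata", "published_confusion_tables.tsv",
                      package = "bloodsig", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
}
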