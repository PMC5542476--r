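# small builders shared across test files

expr_mat <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("G%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("S%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tmp_tsv <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

toy_meta <- function(sample_ids, groups, class_labels = NULL, ...) {
  data.frame(sample_id = sample_ids, group = groups,
             class_label = class_labels %||% ifelse(groups == "case",
                                                    "disease", "healthy"),
             ..., stringsAsFactors = FALSE)
}

toy_panel <- function(n = 10) {
  gene_panel(sprintf("VRG%02d", seq_len(n)), sprintf("BRG%02d", seq_len(n)))
}

# frequency table from a gene x dataset matrix of fold changes (NA = absent)
ft_from_matrix <- function(fc, thresholds = deg_thresholds()) {
  fc_list <- lapply(seq_len(ncol(fc)), function(j) {
    v <- fc[, j]
    v[!is.na(v)]
  })
  names(fc_list) <- colnames(fc)
  frequency_table(fc_list, thresholds)
}
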