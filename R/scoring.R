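#' Per-sample fold-change matrix against the control median
#'
#' Per gene, the reference is the median log2 expression over the control
#' group; each sample's linear fold change is two to the power of its log2
#' value minus that reference.  Controls themselves may be scored (their
#' per-gene median fold change is 1 by construction), which is useful for
#' monitoring.
#'
#' @param expr Gene-level log2 matrix (after QC, so flooring has already been
#'   applied).
#' @param metadata Data.frame with `sample_id` and `group` columns; at least
#'   one control sample must be present in `expr`.
#' @param genes Optional gene subset (e.g. the panel genes).  Genes absent
#'   from the matrix are reported in a warning and dropped.
#' @param samples Optional sample subset to score (default: all samples with
#'   metadata).
#' @return Linear fold-change matrix (genes x samples) with the per-gene
#'   reference in attribute `"reference"`.
#' @export
build_fc_matrix <- function(expr, metadata, genes = NULL, samples = NULL) {
  assert_expr_matrix(expr)
  metadata <- metadata[metadata$sample_id %in% colnames(expr), , drop = FALSE]
  control_ids <- metadata$sample_id[metadata$group == "control"]
  if (!length(control_ids)) {
    stop("no control samples available to define the fold-change reference")
  }
  if (is.null(genes)) {
    genes <- rownames(expr)
  } else {
    genes <- toupper(genes)
    absent <- setdiff(genes, rownames(expr))
    if (length(absent)) {
      warning("genes absent from expression matrix dropped: ",
              paste(absent, collapse = ", "))
      genes <- intersect(genes, rownames(expr))
    }
    if (!length(genes)) stop("none of the requested genes are present")
  }
  samples <- samples %||% metadata$sample_id
  assert_samples_present(expr, samples)
  ref <- row_medians(expr[genes, control_ids, drop = FALSE])
  fc <- 2^sweep(expr[genes, samples, drop = FALSE], 1L, ref)
  attr(fc, "reference") <- ref
  fc
}

#' NG_V / NG_B dysregulation counts
#'
#' Per sample, counts how many panel genes exceed the fold-change threshold
#' (strictly: `fc > threshold`, so a gene at exactly 2.0 does not count).
#' NG_V counts over the virus-response genes, NG_B over the bacteria-response
#' genes.  Panel genes missing from the matrix reduce the attainable maximum;
#' the effective panel sizes are carried in attributes so downstream
#' classifiers can normalize.
#'
#' @param fc Linear fold-change matrix from [build_fc_matrix()].
#' @param panel A [gene_panel()].
#' @param threshold Linear fold-change threshold (default 2.0).
#' @return Data.frame with columns `sample_id`, `ng_v`, `ng_b`; attributes
#'   `threshold`, `n_vrg_effective`, `n_brg_effective`.
#' @export
count_dysregulated <- function(fc, panel, threshold = 2.0) {
  assert_expr_matrix(fc)
  stopifnot(inherits(panel, "gene_panel"), is.numeric(threshold))
  vrg <- intersect(panel$vrg, rownames(fc))
  brg <- intersect(panel$brg, rownames(fc))
  ng_v <- if (length(vrg)) colSums(fc[vrg, , drop = FALSE] > threshold, na.rm = TRUE)
          else rep(0L, ncol(fc))
  ng_b <- if (length(brg)) colSums(fc[brg, , drop = FALSE] > threshold, na.rm = TRUE)
          else rep(0L, ncol(fc))
  out <- data.frame(sample_id = colnames(fc), ng_v = unname(ng_v),
                    ng_b = unname(ng_b), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "n_vrg_effective") <- length(vrg)
  attr(out, "n_brg_effective") <- length(brg)
  out
}

#' Relative expression against a housekeeping reference
#'
#' Linear ratio `2^(x_target - x_reference)` per sample.  Useful as a
#' classifier input for datasets without a healthy-control group, with a
#' stably expressed housekeeping gene (e.g. B2M) as the internal denominator.
#'
#' @param expr Gene-level log2 matrix.
#' @param target_gene,reference_gene Gene symbols; both must be present
#'   (matched upper-case).
#' @return Named numeric vector of per-sample linear ratios.
#' @export
relative_expression <- function(expr, target_gene, reference_gene) {
  assert_expr_matrix(expr)
  target_gene <- toupper(target_gene)
  reference_gene <- toupper(reference_gene)
  if (!reference_gene %in% rownames(expr)) {
    stop("reference gene missing from expression matrix: ", reference_gene)
  }
  if (!target_gene %in% rownames(expr)) {
    stop("target gene missing from expression matrix: ", target_gene)
  }
  2^(expr[target_gene, ] - expr[reference_gene, ])
}
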