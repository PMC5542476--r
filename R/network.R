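#' Pearson correlation matrix over a gene subset
#'
#' Pairwise-complete Pearson correlations of the log2 expression rows.
#' Symmetric with unit diagonal for non-degenerate genes; correlations
#' involving a zero-variance gene are undefined and reported as `NA` (the
#' affected genes are listed in a message).
#'
#' @param expr Gene-level log2 matrix with >= 3 samples.
#' @param genes Optional gene subset (default: all genes).
#' @return Symmetric correlation matrix with entries in `[-1, 1]` or `NA`.
#' @export
pearson_matrix <- function(expr, genes = NULL) {
  assert_expr_matrix(expr)
  if (!is.null(genes)) {
    genes <- toupper(genes)
    absent <- setdiff(genes, rownames(expr))
    if (length(absent)) {
      warning("genes absent from expression matrix dropped: ",
              paste(absent, collapse = ", "))
      genes <- intersect(genes, rownames(expr))
    }
    expr <- expr[genes, , drop = FALSE]
  }
  if (ncol(expr) < 3L) stop("need >= 3 samples for correlation")
  sds <- apply(expr, 1L, stats::sd, na.rm = TRUE)
  degenerate <- rownames(expr)[!is.na(sds) & sds == 0]
  if (length(degenerate)) {
    message("zero-variance gene(s), correlations undefined: ",
            paste(degenerate, collapse = ", "))
  }
  suppressWarnings(stats::cor(t(expr), use = "pairwise.complete.obs"))
}

#' Build a co-expression network from a correlation matrix
#'
#' Keeps an undirected edge between two genes when their *signed* Pearson
#' correlation strictly exceeds `cutoff` (the convention retains strong
#' positive co-regulation; negative correlations never form edges).
#' Connected components are computed so sub-network structure — e.g. a
#' viral-response and a bacterial-response block — can be reported.
#'
#' @param pcc Symmetric correlation matrix ([pearson_matrix()]).
#' @param cutoff Minimum correlation for an edge (default 0.50).
#' @param panel Optional [gene_panel()] used to tag nodes as
#'   `vrg`/`brg`/`other`.
#' @return An object of class `coexpression_network`: list with `nodes`
#'   (gene, tag), `edges` (source, target, pcc; endpoints sorted within and
#'   across rows), `cutoff`, `membership` (component id per gene) and
#'   `n_components`.
#' @export
build_network <- function(pcc, cutoff = 0.50, panel = NULL) {
  stopifnot(is.matrix(pcc), nrow(pcc) == ncol(pcc),
            !is.null(rownames(pcc)))
  genes <- rownames(pcc)
  idx <- which(upper.tri(pcc) & !is.na(pcc) & pcc > cutoff, arr.ind = TRUE)
  if (nrow(idx)) {
    a <- genes[idx[, 1L]]
    b <- genes[idx[, 2L]]
    edges <- data.frame(source = pmin(a, b), target = pmax(a, b),
                        pcc = pcc[idx], stringsAsFactors = FALSE)
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(source = character(), target = character(),
                        pcc = numeric(), stringsAsFactors = FALSE)
  }
  tag <- rep("other", length(genes))
  if (!is.null(panel)) {
    tag[genes %in% panel$vrg] <- "vrg"
    tag[genes %in% panel$brg] <- "brg"
  }
  g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                     directed = FALSE, vertices = genes)
  comp <- igraph::components(g)
  structure(list(nodes = data.frame(gene = genes, tag = tag,
                                    stringsAsFactors = FALSE),
                 edges = edges, cutoff = cutoff,
                 membership = comp$membership[genes],
                 n_components = comp$no),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("Co-expression network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges (pcc >", x$cutoff, "),", x$n_components, "components\n")
  invisible(x)
}

#' Sex-stratified fold changes
#'
#' Median fold change computed within each sex stratum (cases versus controls
#' of the same sex) and overall, with the between-sex ratio
#' `max(fc_male, fc_female) / min(fc_male, fc_female)`.  A gene is flagged
#' when the ratio exceeds 1.4.  Strata with no cases or no controls give `NA`
#' for that stratum.
#'
#' @param expr Gene-level log2 matrix.
#' @param metadata Data.frame with `sample_id`, `group` and `sex` columns.
#' @param genes Optional gene subset.
#' @return Data.frame with columns `gene`, `fc_all`, `fc_male`, `fc_female`,
#'   `sex_ratio`, `flagged`.
#' @export
sex_stratified_fc <- function(expr, metadata, genes = NULL) {
  assert_expr_matrix(expr)
  if (!"sex" %in% names(metadata)) stop("metadata lacks a `sex` column")
  metadata <- metadata[metadata$sample_id %in% colnames(expr), , drop = FALSE]
  if (!is.null(genes)) {
    genes <- intersect(toupper(genes), rownames(expr))
    expr <- expr[genes, , drop = FALSE]
  }
  fc_in <- function(keep) {
    m <- metadata[keep, , drop = FALSE]
    cases <- m$sample_id[m$group == "case"]
    ctrls <- m$sample_id[m$group == "control"]
    if (!length(cases) || !length(ctrls)) {
      return(rep(NA_real_, nrow(expr)))
    }
    median_fold_change(expr, cases, ctrls)
  }
  fc_all <- fc_in(rep(TRUE, nrow(metadata)))
  fc_male <- fc_in(!is.na(metadata$sex) & metadata$sex == "male")
  fc_female <- fc_in(!is.na(metadata$sex) & metadata$sex == "female")
  sex_ratio <- pmax(fc_male, fc_female) / pmin(fc_male, fc_female)
  data.frame(gene = rownames(expr), fc_all = unname(fc_all),
             fc_male = unname(fc_male), fc_female = unname(fc_female),
             sex_ratio = unname(sex_ratio),
             flagged = !is.na(sex_ratio) & sex_ratio > 1.4,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene correlation of expression with age
#'
#' Pearson correlation of log2 expression against age over samples with
#' recorded age (complete observations per gene).
#'
#' @param expr Gene-level log2 matrix.
#' @param metadata Data.frame with `sample_id` and `age` columns; >= 3
#'   samples with age are required and the age vector must not be constant.
#' @param genes Optional gene subset.
#' @return Named numeric vector of correlations in `[-1, 1]` (`NA` for
#'   constant genes).
#' @export
age_correlation <- function(expr, metadata, genes = NULL) {
  assert_expr_matrix(expr)
  if (!"age" %in% names(metadata)) stop("metadata lacks an `age` column")
  metadata <- metadata[metadata$sample_id %in% colnames(expr) &
                         !is.na(metadata$age), , drop = FALSE]
  if (nrow(metadata) < 3L) stop("need >= 3 samples with recorded age")
  if (stats::sd(metadata$age) == 0) stop("age vector is constant")
  if (!is.null(genes)) {
    genes <- intersect(toupper(genes), rownames(expr))
    expr <- expr[genes, , drop = FALSE]
  }
  x <- expr[, metadata$sample_id, drop = FALSE]
  out <- suppressWarnings(
    apply(x, 1L, function(v) stats::cor(v, metadata$age,
                                        use = "complete.obs")))
  stats::setNames(as.numeric(out), rownames(x))
}
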