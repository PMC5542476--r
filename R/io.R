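#' Read a tab-delimited expression table
#'
#' Reads a GEO series-matrix style table: first column feature (probe or gene)
#' ids, header row of sample ids, one row per feature.  Values on linear scale
#' are log2-transformed on read, so downstream code always works on log2
#' intensities.  Empty cells and the literal string `"NA"` become missing
#' values (`NA` in the returned matrix).
#'
#' @param path Path to a tab-delimited text file.
#' @param scale Either `"log2"` (values stored as is) or `"linear"`
#'   (values are log2-transformed on read; non-positive values are an error).
#' @return A numeric matrix, rows = features, columns = samples, log2 scale.
#'   Missing entries are `NA`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id\ts1\ts2", "g1\t6.5\t7.0", "g2\t\t8.1"), tf)
#' m <- read_expression_table(tf)
#' is.na(m["g2", "s1"])
#' @export
read_expression_table <- function(path, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  nf <- utils::count.fields(path, sep = "\t", quote = "\"", comment.char = "")
  if (length(nf) < 2L) stop("expression table needs a header row and at least one data row")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged row in '%s' at line %d (%d fields, expected %d)",
                 path, bad, nf[bad], nf[1L]))
  }
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), comment.char = "")
  ids <- as.character(tab[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate feature ids in expression table: ",
         paste(unique(dup), collapse = ", "))
  }
  vals <- tab[, -1L, drop = FALSE]
  ok <- vapply(vals, is.numeric, logical(1L))
  if (!all(ok)) {
    stop("non-numeric values in columns: ",
         paste(names(vals)[!ok], collapse = ", "))
  }
  vals <- as.matrix(vals)
  rownames(vals) <- ids
  if (scale == "linear") {
    if (any(vals <= 0, na.rm = TRUE)) {
      stop("linear-scale table contains non-positive values; cannot log2-transform")
    }
    vals <- log2(vals)
  }
  vals
}

#' Write an expression matrix as a tab-delimited table
#'
#' Inverse of [read_expression_table()] (for log2-scale data): missing values
#' are written as `"NA"`, feature ids in the first column.
#'
#' @param x Numeric matrix with rownames (features) and colnames (samples).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  assert_expr_matrix(x)
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects a tab-delimited file with required columns `sample_id`, `group`
#' (case/control, matched case-insensitively) and `class_label`, plus optional
#' `sex` (male/female), `age` (years) and `timepoint` (day index).
#'
#' @param path Path to a tab-delimited text file.
#' @return A data.frame with normalized (lower-case) `group` and `sex`.
#' @export
read_metadata <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  required <- c("sample_id", "group", "class_label")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("metadata is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  tab$sample_id <- as.character(tab$sample_id)
  dup <- tab$sample_id[duplicated(tab$sample_id)]
  if (length(dup)) stop("duplicate sample ids in metadata: ", paste(unique(dup), collapse = ", "))
  tab$group <- tolower(trimws(as.character(tab$group)))
  bad <- setdiff(unique(tab$group), c("case", "control"))
  if (length(bad)) {
    stop("unknown group value(s) in metadata: ", paste(bad, collapse = ", "),
         " (expected case/control)")
  }
  if ("sex" %in% names(tab)) {
    tab$sex <- tolower(trimws(as.character(tab$sex)))
    bad_sex <- setdiff(unique(tab$sex[!is.na(tab$sex)]), c("male", "female"))
    if (length(bad_sex)) stop("unknown sex value(s): ", paste(bad_sex, collapse = ", "))
  }
  if ("age" %in% names(tab)) tab$age <- as.numeric(tab$age)
  if ("timepoint" %in% names(tab)) tab$timepoint <- as.numeric(tab$timepoint)
  tab
}

#' Align sample metadata to the columns of an expression matrix
#'
#' Errors (listing the offending ids) when samples present in the expression
#' matrix have no metadata row; extra metadata rows are dropped.
#'
#' @param x Expression matrix (features x samples).
#' @param metadata Data.frame as returned by [read_metadata()].
#' @return The metadata rows reordered to match `colnames(x)`.
#' @export
align_metadata <- function(x, metadata) {
  assert_expr_matrix(x)
  missing <- setdiff(colnames(x), metadata$sample_id)
  if (length(missing)) {
    stop("samples present in expression but absent in metadata: ",
         paste(missing, collapse = ", "))
  }
  metadata[match(colnames(x), metadata$sample_id), , drop = FALSE]
}

#' Read a probe-to-gene mapping table
#'
#' Tab-delimited with columns `probe_id` and `gene_symbol`.  A probe may map
#' to several genes (one row per mapping).  Gene symbols are stored upper-case
#' since platform annotations vary in case.
#'
#' @param path Path to a tab-delimited text file.
#' @return Data.frame with columns `probe_id`, `gene_symbol`.
#' @export
read_probe_map <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  required <- c("probe_id", "gene_symbol")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("probe map is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  tab$probe_id <- as.character(tab$probe_id)
  tab$gene_symbol <- toupper(as.character(tab$gene_symbol))
  tab[!is.na(tab$gene_symbol) & nzchar(tab$gene_symbol), required, drop = FALSE]
}

#' Construct a VRG/BRG gene panel
#'
#' @param vrg Character vector of virus-response gene symbols.
#' @param brg Character vector of bacteria-response gene symbols; must be
#'   disjoint from `vrg`.
#' @param provenance Optional data.frame recording the selection statistics
#'   (mean fold changes, dataset counts, selection rule) per gene.
#' @return An object of class `gene_panel`.
#' @export
gene_panel <- function(vrg, brg, provenance = NULL) {
  vrg <- toupper(as.character(vrg))
  brg <- toupper(as.character(brg))
  if (anyDuplicated(vrg) || anyDuplicated(brg)) {
    stop("panel gene lists contain duplicates")
  }
  overlap <- intersect(vrg, brg)
  if (length(overlap)) {
    stop("vrg and brg must be disjoint; shared genes: ",
         paste(overlap, collapse = ", "))
  }
  structure(list(vrg = vrg, brg = brg, provenance = provenance),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("Gene panel:", length(x$vrg), "VRGs /", length(x$brg), "BRGs\n")
  cat("  VRG:", paste(x$vrg, collapse = ", "), "\n")
  cat("  BRG:", paste(x$brg, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a gene panel to JSON
#'
#' @param panel A [gene_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "gene_panel"))
  jsonlite::write_json(list(vrg = panel$vrg, brg = panel$brg,
                            provenance = panel$provenance),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a gene panel from JSON
#'
#' @param path Path written by [write_panel()].
#' @return A [gene_panel()].
#' @export
read_panel <- function(path) {
  obj <- jsonlite::fromJSON(path)
  prov <- obj$provenance
  if (!is.null(prov) && !is.data.frame(prov)) prov <- as.data.frame(prov)
  gene_panel(obj$vrg, obj$brg, provenance = prov)
}

#' Write a co-expression network as a Cytoscape-importable edge list
#'
#' One row per undirected edge with columns `source`, `target`, `pcc`;
#' endpoints are lexicographically ordered within each row, rows sorted by
#' (source, target), no self-loops.  An empty network yields a header-only
#' file.
#'
#' @param network A `coexpression_network` (see [build_network()]) or a
#'   data.frame with columns `source`, `target`, `pcc`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  edges <- if (inherits(network, "coexpression_network")) network$edges else network
  stopifnot(is.data.frame(edges), all(c("source", "target", "pcc") %in% names(edges)))
  if (nrow(edges)) {
    a <- pmin(edges$source, edges$target)
    b <- pmax(edges$source, edges$target)
    keep <- a != b
    edges <- data.frame(source = a[keep], target = b[keep], pcc = edges$pcc[keep])
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  }
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
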