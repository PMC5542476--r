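#' Fold-change thresholds for differential expression
#'
#' The stringent cutoff calls a gene differentially expressed at linear fold
#' change above 2.0 or below 0.5; the lenient preset (1.5 / 0.7) admits more
#' genes for consideration.  Comparisons downstream are strict (`>` / `<`).
#'
#' @param preset `"stringent"` (2.0 / 0.5) or `"lenient"` (1.5 / 0.7).
#' @param up,down Optional explicit thresholds overriding the preset; must
#'   satisfy `up > 1 > down > 0`.
#' @return A list with elements `up` and `down`, class `deg_thresholds`.
#' @export
deg_thresholds <- function(preset = c("stringent", "lenient"),
                           up = NULL, down = NULL) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
                     stringent = c(up = 2.0, down = 0.5),
                     lenient   = c(up = 1.5, down = 0.7))
  up <- up %||% defaults[["up"]]
  down <- down %||% defaults[["down"]]
  if (!(up > 1 && down < 1 && down > 0)) {
    stop("thresholds must satisfy up > 1 > down > 0")
  }
  structure(list(up = up, down = down), class = "deg_thresholds")
}

#' Median-based fold change, case versus control
#'
#' Per gene, the linear fold change is `2^(median(case) - median(control))`,
#' medians taken over non-missing log2 values.  The median (rather than the
#' mean) damps the influence of samples far from the group centre.  Genes
#' entirely missing in either group get `NA` and should be excluded
#' downstream.
#'
#' @param expr Gene-level log2 matrix (genes x samples).
#' @param case_ids,control_ids Sample ids of the two groups (each non-empty).
#' @return Named numeric vector of linear fold changes (`NA` = undefined).
#' @export
median_fold_change <- function(expr, case_ids, control_ids) {
  assert_expr_matrix(expr)
  if (!length(case_ids) || !length(control_ids)) {
    stop("both case and control groups must contain at least one sample")
  }
  assert_samples_present(expr, case_ids, "case")
  assert_samples_present(expr, control_ids, "control")
  m_case <- row_medians(expr[, case_ids, drop = FALSE])
  m_ctrl <- row_medians(expr[, control_ids, drop = FALSE])
  2^(m_case - m_ctrl)
}

## rank-product statistics from a genes x comparisons matrix of log ratios
.rp_from_ratios <- function(ratios) {
  rk_up <- apply(ratios, 2L, function(v) rank(-v, ties.method = "average",
                                              na.last = "keep"))
  rk_down <- apply(ratios, 2L, function(v) rank(v, ties.method = "average",
                                                na.last = "keep"))
  if (is.null(dim(rk_up))) {  # single gene edge case
    rk_up <- matrix(rk_up, nrow = 1L)
    rk_down <- matrix(rk_down, nrow = 1L)
  }
  list(up = exp(rowMeans(log(rk_up), na.rm = TRUE)),
       down = exp(rowMeans(log(rk_down), na.rm = TRUE)))
}

.rp_ratio_matrix <- function(expr, pairs) {
  expr[, pairs$case, drop = FALSE] - expr[, pairs$control, drop = FALSE]
}

## proportion of false predictions: expected count of null RP values at or
## below each observed RP, divided by the gene's position in the RP ordering
.rp_pfp <- function(rp_obs, perm_values, n_perm) {
  e_fp <- findInterval(rp_obs, sort(perm_values)) / n_perm
  pos <- rank(rp_obs, ties.method = "max")
  pmin(pmax(e_fp / pos, 0), 1)
}

#' Rank-product differential expression
#'
#' For every case/control sample pair, genes are ranked by the pairwise log2
#' ratio (rank 1 = most up-regulated); the up rank product of a gene is the
#' geometric mean of its ranks over all pairs, and the down statistic uses
#' ascending ranks.  Significance is estimated as the proportion of false
#' predictions (pfp) by the standard rank-product resampling: `n_perm` null
#' experiments are generated by randomly permuting the observed ranks across
#' genes within each comparison, the null rank products are pooled, and the
#' expected number of null values at or below a gene's observed statistic is
#' divided by the gene's position in the observed ordering.  When the number
#' of case x control pairs exceeds `max_pairs`, a uniform subsample of pairs
#' is used.
#'
#' @inheritParams median_fold_change
#' @param n_perm Number of permutations for the pfp estimate (>= 1).
#' @param max_pairs Cap on the number of case x control pairs (default 200).
#' @param seed Optional integer seed making pair subsampling and permutations
#'   reproducible.
#' @return Data.frame with columns `gene`, `rp_up`, `rp_down`, `pfp_up`,
#'   `pfp_down`.
#' @export
rank_product <- function(expr, case_ids, control_ids, n_perm = 100,
                         max_pairs = 200, seed = NULL) {
  assert_expr_matrix(expr)
  if (nrow(expr) < 2L) stop("rank product needs at least 2 genes")
  if (!length(case_ids) || !length(control_ids)) {
    stop("both case and control groups must contain at least one sample")
  }
  if (!is.numeric(n_perm) || n_perm < 1) stop("`n_perm` must be >= 1")
  assert_samples_present(expr, case_ids, "case")
  assert_samples_present(expr, control_ids, "control")

  with_optional_seed(seed, {
    pairs <- expand.grid(case = case_ids, control = control_ids,
                         stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    if (nrow(pairs) > max_pairs) {
      pairs <- pairs[sample.int(nrow(pairs), max_pairs), , drop = FALSE]
    }
    ratios <- .rp_ratio_matrix(expr, pairs)
    obs <- .rp_from_ratios(ratios)

    # observed rank matrices, reused (column-shuffled) for the null
    rk_up <- apply(ratios, 2L, function(v) rank(-v, ties.method = "average",
                                                na.last = "keep"))
    rk_down <- apply(ratios, 2L, function(v) rank(v, ties.method = "average",
                                                  na.last = "keep"))
    n_g <- nrow(expr)
    perm_up <- vector("list", n_perm)
    perm_down <- vector("list", n_perm)
    for (b in seq_len(n_perm)) {
      idx <- replicate(ncol(rk_up), sample.int(n_g))
      null_up <- matrix(rk_up[cbind(as.vector(idx), rep(seq_len(ncol(rk_up)),
                                                        each = n_g))],
                        n_g, ncol(rk_up))
      null_down <- matrix(rk_down[cbind(as.vector(idx),
                                        rep(seq_len(ncol(rk_down)),
                                            each = n_g))],
                          n_g, ncol(rk_down))
      perm_up[[b]] <- exp(rowMeans(log(null_up), na.rm = TRUE))
      perm_down[[b]] <- exp(rowMeans(log(null_down), na.rm = TRUE))
    }
    data.frame(gene = rownames(expr),
               rp_up = obs$up, rp_down = obs$down,
               pfp_up = .rp_pfp(obs$up, unlist(perm_up), n_perm),
               pfp_down = .rp_pfp(obs$down, unlist(perm_down), n_perm),
               row.names = NULL, stringsAsFactors = FALSE)
  })
}

#' Select differentially expressed genes by fold-change cutoff
#'
#' Up-regulated genes have fold change strictly above `thresholds$up`,
#' down-regulated strictly below `thresholds$down` (a gene at exactly 2.0 is
#' excluded).  When a rank-product table is supplied, genes within each set
#' are ordered by the corresponding rank-product statistic (ascending, i.e.
#' strongest first); otherwise by fold change.
#'
#' @param fc Named vector of linear fold changes ([median_fold_change()]);
#'   `NA` entries (undefined fold change) are dropped.
#' @param rp Optional data.frame from [rank_product()].
#' @param thresholds A [deg_thresholds()] object.
#' @return List with character vectors `up` and `down`.
#' @export
select_degs <- function(fc, rp = NULL, thresholds = deg_thresholds()) {
  stopifnot(inherits(thresholds, "deg_thresholds"))
  fc <- fc[!is.na(fc)]
  up <- names(fc)[fc > thresholds$up]
  down <- names(fc)[fc < thresholds$down]
  if (!is.null(rp)) {
    up <- up[order(rp$rp_up[match(up, rp$gene)])]
    down <- down[order(rp$rp_down[match(down, rp$gene)])]
  } else {
    up <- up[order(-fc[up])]
    down <- down[order(fc[down])]
  }
  list(up = up, down = down)
}

#' Differential expression for one dataset
#'
#' Convenience wrapper: median fold change plus rank product for the case
#' versus control groups defined in the metadata, with a per-gene direction
#' call at the given thresholds.
#'
#' @param expr Gene-level log2 matrix.
#' @param metadata Data.frame with `sample_id` and `group` columns
#'   ([read_metadata()]); only samples present in `expr` are used.
#' @param thresholds A [deg_thresholds()] object.
#' @inheritParams rank_product
#' @return Data.frame with columns `gene`, `fc`, `rp_up`, `rp_down`,
#'   `pfp_up`, `pfp_down`, `direction` (up/down/none).
#' @export
run_de <- function(expr, metadata, thresholds = deg_thresholds(),
                   n_perm = 100, max_pairs = 200, seed = NULL) {
  metadata <- metadata[metadata$sample_id %in% colnames(expr), , drop = FALSE]
  case_ids <- metadata$sample_id[metadata$group == "case"]
  control_ids <- metadata$sample_id[metadata$group == "control"]
  fc <- median_fold_change(expr, case_ids, control_ids)
  rp <- rank_product(expr, case_ids, control_ids, n_perm = n_perm,
                     max_pairs = max_pairs, seed = seed)
  direction <- ifelse(is.na(fc), "none",
                      ifelse(fc > thresholds$up, "up",
                             ifelse(fc < thresholds$down, "down", "none")))
  data.frame(gene = rownames(expr), fc = unname(fc),
             rp_up = rp$rp_up, rp_down = rp$rp_down,
             pfp_up = rp$pfp_up, pfp_down = rp$pfp_down,
             direction = unname(direction),
             row.names = NULL, stringsAsFactors = FALSE)
}
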