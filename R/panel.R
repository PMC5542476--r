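#' Cross-dataset dysregulation frequency table
#'
#' Counts, per gene, in how many datasets its median fold change passes the
#' cutoff (up: `fc > up`, down: `fc < down`; each dataset contributes at most
#' one direction).  Genes absent from a dataset (not on the platform or
#' removed by QC) contribute no count there.
#'
#' @param fc_list Named list of per-dataset fold-change vectors
#'   ([median_fold_change()]); names are dataset ids.
#' @param thresholds A [deg_thresholds()] object (default stringent).
#' @return An object of class `frequency_table`: list with `genes`, `fc`
#'   (gene x dataset matrix, `NA` where absent), `n_up`, `n_down`,
#'   `n_significant`, `thresholds`.
#' @export
frequency_table <- function(fc_list, thresholds = deg_thresholds()) {
  stopifnot(length(fc_list) >= 1L, inherits(thresholds, "deg_thresholds"))
  if (is.null(names(fc_list)) || any(!nzchar(names(fc_list)))) {
    stop("`fc_list` must be a named list (dataset ids)")
  }
  genes <- sort(unique(unlist(lapply(fc_list, names))))
  fc <- matrix(NA_real_, nrow = length(genes), ncol = length(fc_list),
               dimnames = list(genes, names(fc_list)))
  for (d in names(fc_list)) {
    v <- fc_list[[d]]
    fc[names(v), d] <- unname(v)
  }
  up <- !is.na(fc) & fc > thresholds$up
  down <- !is.na(fc) & fc < thresholds$down
  structure(list(genes = genes, fc = fc,
                 n_up = rowSums(up), n_down = rowSums(down),
                 n_significant = rowSums(up) + rowSums(down),
                 thresholds = thresholds),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("Frequency table:", length(x$genes), "genes x", ncol(x$fc), "datasets\n")
  cat("  genes significant in >= 8 datasets:", sum(x$n_significant >= 8), "\n")
  invisible(x)
}

#' @export
as.data.frame.frequency_table <- function(x, ...) {
  data.frame(gene = x$genes, n_up = unname(x$n_up), n_down = unname(x$n_down),
             n_significant = unname(x$n_significant),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mean fold change over a set of datasets
#'
#' Arithmetic mean of the linear fold changes over the given dataset columns,
#' ignoring datasets where the gene is absent.
#'
#' @param ft A [frequency_table()].
#' @param dataset_ids Dataset ids (columns of `ft$fc`).
#' @param genes Genes to evaluate (default all).
#' @return Named numeric vector.
#' @export
mean_fc <- function(ft, dataset_ids, genes = ft$genes) {
  stopifnot(inherits(ft, "frequency_table"))
  missing_ds <- setdiff(dataset_ids, colnames(ft$fc))
  if (length(missing_ds)) stop("unknown dataset ids: ", paste(missing_ds, collapse = ", "))
  rowMeans(ft$fc[genes, dataset_ids, drop = FALSE], na.rm = TRUE)
}

#' Panel-selection rules
#'
#' Encodes the published selection procedure: candidates are genes
#' significant in at least `min_datasets` of the discovery datasets; the VRG
#' list is the `n_viral_top` candidates with the highest mean fold change in
#' the viral datasets; the BRG list is the union of (a) candidates with
#' bacterial mean FC above `bacterial_high_fc`, (b) candidates significant in
#' at least `rescue_min_datasets` datasets, and (c) candidates with bacterial
#' mean FC inside `bacterial_mid_fc_range` (closed interval) significant in at
#' least `mid_fc_min_datasets` datasets, truncated or padded to
#' `n_bacterial_top` by bacterial mean FC.  The `include`/`exclude` overrides
#' reproduce manual curation steps (e.g. preferring a TLR-signaling gene over
#' a close-ranked alternative) as configuration rather than hard-coded logic.
#'
#' @param min_datasets Minimum dataset count for candidacy (default 8).
#' @param n_viral_top,n_bacterial_top Panel sizes (default 10 each).
#' @param bacterial_high_fc Rule (a) threshold (default 8.0).
#' @param bacterial_mid_fc_range Rule (c) closed interval (default `c(5, 8)`).
#' @param mid_fc_min_datasets Rule (c) dataset count (default 10).
#' @param rescue_min_datasets Rule (b) dataset count (default 13).
#' @param include,exclude Character vectors of genes to force in / keep out of
#'   the bacterial list (applied last).
#' @return An object of class `selection_rules`.
#' @export
selection_rules <- function(min_datasets = 8, n_viral_top = 10,
                            n_bacterial_top = 10, bacterial_high_fc = 8.0,
                            bacterial_mid_fc_range = c(5, 8),
                            mid_fc_min_datasets = 10, rescue_min_datasets = 13,
                            include = character(), exclude = character()) {
  stopifnot(min_datasets >= 1, n_viral_top >= 1, n_bacterial_top >= 1,
            bacterial_high_fc > 0, length(bacterial_mid_fc_range) == 2L,
            bacterial_mid_fc_range[1] <= bacterial_mid_fc_range[2])
  structure(list(min_datasets = min_datasets, n_viral_top = n_viral_top,
                 n_bacterial_top = n_bacterial_top,
                 bacterial_high_fc = bacterial_high_fc,
                 bacterial_mid_fc_range = bacterial_mid_fc_range,
                 mid_fc_min_datasets = mid_fc_min_datasets,
                 rescue_min_datasets = rescue_min_datasets,
                 include = toupper(include), exclude = toupper(exclude)),
            class = "selection_rules")
}

#' Candidate genes by dysregulation frequency
#'
#' @param ft A [frequency_table()].
#' @param rules A [selection_rules()] object.
#' @return Character vector of genes with `n_significant >= min_datasets`
#'   ("at least" — a gene at exactly the threshold is included).  Warns when
#'   empty.
#' @export
select_candidates <- function(ft, rules = selection_rules()) {
  stopifnot(inherits(ft, "frequency_table"), inherits(rules, "selection_rules"))
  out <- ft$genes[ft$n_significant >= rules$min_datasets]
  if (!length(out)) warning("no candidate genes pass the frequency cutoff")
  out
}

## candidates ordered by mean FC over `dataset_ids` (desc), ties broken by
## n_significant (desc) then alphabetically
.order_by_mean_fc <- function(ft, genes, dataset_ids) {
  m <- mean_fc(ft, dataset_ids, genes)
  ns <- ft$n_significant[match(genes, ft$genes)]
  genes[order(-m, -ns, genes)]
}

#' Select the virus-response gene (VRG) list
#'
#' Candidates ranked by mean fold change over the viral datasets, descending;
#' the top `n_viral_top` are returned.  Ties are broken by higher
#' `n_significant`, then alphabetically.
#'
#' @param ft A [frequency_table()].
#' @param candidates Character vector from [select_candidates()].
#' @param viral_dataset_ids Dataset ids of the viral-infection cohorts.
#' @param rules A [selection_rules()] object.
#' @return Ordered character vector (warns and returns all when fewer
#'   candidates than `n_viral_top`).
#' @export
select_vrgs <- function(ft, candidates, viral_dataset_ids,
                        rules = selection_rules()) {
  ordered <- .order_by_mean_fc(ft, candidates, viral_dataset_ids)
  if (length(ordered) < rules$n_viral_top) {
    warning("fewer candidates (", length(ordered), ") than requested VRGs (",
            rules$n_viral_top, "); returning all")
  }
  utils::head(ordered, rules$n_viral_top)
}

#' Select the bacteria-response gene (BRG) list
#'
#' Applies rules (a) high bacterial mean FC, (b) rescue by overall dataset
#' count, and (c) mid-range bacterial FC with high dataset count (see
#' [selection_rules()]); overrides are applied last, then the list is
#' truncated or padded to `n_bacterial_top` by bacterial mean FC.  Genes in
#' `exclude_genes` (typically the already-chosen VRGs) are never selected.
#'
#' @inheritParams select_vrgs
#' @param bacterial_dataset_ids Dataset ids of the bacterial-infection cohorts.
#' @param exclude_genes Genes barred from the list (default none).
#' @return Ordered character vector, with a `rule` attribute recording which
#'   rule admitted each gene (`high_fc`, `rescue`, `mid_fc`, `include`,
#'   `pad`).
#' @export
select_brgs <- function(ft, candidates, bacterial_dataset_ids,
                        rules = selection_rules(), exclude_genes = character()) {
  cand <- setdiff(candidates, c(exclude_genes, rules$exclude))
  if (!length(cand)) {
    warning("no candidates available for BRG selection")
    return(character())
  }
  mb <- mean_fc(ft, bacterial_dataset_ids, cand)
  ns <- ft$n_significant[match(cand, ft$genes)]
  r <- rules$bacterial_mid_fc_range

  rule_a <- cand[!is.na(mb) & mb > rules$bacterial_high_fc]
  rule_b <- cand[ns >= rules$rescue_min_datasets]
  rule_c <- cand[!is.na(mb) & mb >= r[1] & mb <= r[2] &
                   ns >= rules$mid_fc_min_datasets]

  sel <- union(rule_a, union(rule_b, rule_c))
  sel <- union(sel, intersect(rules$include, cand))
  rule_of <- function(g) {
    if (g %in% rule_a) "high_fc"
    else if (g %in% rule_b) "rescue"
    else if (g %in% rule_c) "mid_fc"
    else if (g %in% rules$include) "include"
    else "pad"
  }

  n_b <- rules$n_bacterial_top
  pinned <- intersect(rules$include, sel)
  if (length(sel) > n_b) {
    free <- setdiff(sel, pinned)
    free <- .order_by_mean_fc(ft, free, bacterial_dataset_ids)
    sel <- c(pinned, utils::head(free, n_b - length(pinned)))
  } else if (length(sel) < n_b) {
    pool <- setdiff(cand, sel)
    pool <- .order_by_mean_fc(ft, pool, bacterial_dataset_ids)
    sel <- c(sel, utils::head(pool, n_b - length(sel)))
  }
  if (length(sel) < n_b) {
    warning("fewer candidates (", length(sel), ") than requested BRGs (", n_b, ")")
  }
  out <- .order_by_mean_fc(ft, sel, bacterial_dataset_ids)
  attr(out, "rule") <- stats::setNames(vapply(out, rule_of, character(1L)), out)
  out
}

#' Run the full VRG/BRG panel-selection procedure
#'
#' Candidates by frequency, VRGs by viral mean fold change, BRGs by the
#' three-rule bacterial procedure with the VRG list barred (viral list wins;
#' the bacterial list is refilled from remaining candidates).
#'
#' @param ft A [frequency_table()].
#' @param viral_dataset_ids,bacterial_dataset_ids Dataset ids of the viral and
#'   bacterial discovery cohorts.
#' @param rules A [selection_rules()] object.
#' @return A [gene_panel()] whose `provenance` records, per selected gene, the
#'   panel, mean viral/bacterial fold changes, dataset counts and (for BRGs)
#'   the admitting rule.
#' @export
select_panel <- function(ft, viral_dataset_ids, bacterial_dataset_ids,
                         rules = selection_rules()) {
  candidates <- select_candidates(ft, rules)
  vrg <- select_vrgs(ft, candidates, viral_dataset_ids, rules)
  brg <- select_brgs(ft, candidates, bacterial_dataset_ids, rules,
                     exclude_genes = vrg)
  genes <- c(vrg, brg)
  prov <- data.frame(
    gene = genes,
    panel = rep(c("vrg", "brg"), c(length(vrg), length(brg))),
    mean_fc_viral = unname(mean_fc(ft, viral_dataset_ids, genes)),
    mean_fc_bacterial = unname(mean_fc(ft, bacterial_dataset_ids, genes)),
    n_significant = ft$n_significant[match(genes, ft$genes)],
    n_up = ft$n_up[match(genes, ft$genes)],
    n_down = ft$n_down[match(genes, ft$genes)],
    rule = c(rep("top_viral_fc", length(vrg)),
             unname(attr(brg, "rule") %||% rep(NA_character_, length(brg)))),
    row.names = NULL, stringsAsFactors = FALSE)
  gene_panel(vrg, as.character(brg), provenance = prov)
}

#' Screen for disease-specific genes
#'
#' Genes significantly dysregulated (at the frequency table's thresholds) in
#' *all* target datasets while significant in at most `max_background_count`
#' of the remaining (background) datasets.
#'
#' @param ft A [frequency_table()].
#' @param target_dataset_ids Dataset ids of the disease of interest; must be
#'   columns of `ft$fc`.
#' @param max_background_count Maximum tolerated background dataset count
#'   (default 0).
#' @return Character vector of gene symbols.
#' @export
find_specific_genes <- function(ft, target_dataset_ids,
                                max_background_count = 0) {
  stopifnot(inherits(ft, "frequency_table"))
  missing_ds <- setdiff(target_dataset_ids, colnames(ft$fc))
  if (length(missing_ds)) stop("unknown dataset ids: ", paste(missing_ds, collapse = ", "))
  sig <- (!is.na(ft$fc) & ft$fc > ft$thresholds$up) |
    (!is.na(ft$fc) & ft$fc < ft$thresholds$down)
  background <- setdiff(colnames(ft$fc), target_dataset_ids)
  in_all <- rowSums(sig[, target_dataset_ids, drop = FALSE]) ==
    length(target_dataset_ids)
  bg_count <- rowSums(sig[, background, drop = FALSE])
  ft$genes[in_all & bg_count <= max_background_count]
}
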