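#' Longitudinal panel profile for one subject
#'
#' Restricts a timepoint series to the panel genes, computes each gene's
#' baseline as the median over the designated healthy timepoints, and derives
#' a fold-versus-baseline series `2^(x_t - baseline)`.
#'
#' @param series Log2 expression matrix, genes x timepoints (already
#'   normalized; e.g. variance-stabilized RNA-seq values).
#' @param panel A [gene_panel()]; panel genes absent from the series are
#'   reported and dropped.
#' @param healthy_timepoints Timepoints (subset of `timepoints`) treated as
#'   the subject's healthy baseline; at least one is required.
#' @param timepoints Numeric day indices, strictly increasing (default: the
#'   column names of `series` parsed as numbers).
#' @param subject_id Identifier stored with the profile.
#' @return An object of class `longitudinal_profile`: list with `subject_id`,
#'   `timepoints`, `expr`, `fold`, `baseline` and the effective `panel`.
#' @export
build_profile <- function(series, panel, healthy_timepoints,
                          timepoints = NULL, subject_id = "subject") {
  assert_expr_matrix(series)
  stopifnot(inherits(panel, "gene_panel"))
  if (is.null(timepoints)) timepoints <- as.numeric(colnames(series))
  if (anyNA(timepoints)) stop("timepoints must be numeric (or numeric colnames)")
  if (length(timepoints) != ncol(series)) {
    stop("`timepoints` length must match the number of columns")
  }
  if (length(timepoints) < 2L) stop("need >= 2 timepoints")
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  if (!length(healthy_timepoints)) stop("no healthy timepoints designated")
  if (!all(healthy_timepoints %in% timepoints)) {
    stop("healthy timepoints must be a subset of the observed timepoints")
  }
  genes <- intersect(c(panel$vrg, panel$brg), rownames(series))
  absent <- setdiff(c(panel$vrg, panel$brg), rownames(series))
  if (length(absent)) {
    warning("panel genes absent from series dropped: ",
            paste(absent, collapse = ", "))
  }
  if (!length(genes)) stop("no panel genes present in the series")
  x <- series[genes, , drop = FALSE]
  baseline <- row_medians(x[, timepoints %in% healthy_timepoints, drop = FALSE])
  fold <- 2^sweep(x, 1L, baseline)
  structure(list(subject_id = subject_id, timepoints = timepoints,
                 expr = x, fold = fold, baseline = baseline,
                 panel = list(vrg = intersect(panel$vrg, genes),
                              brg = intersect(panel$brg, genes))),
            class = "longitudinal_profile")
}

#' @export
print.longitudinal_profile <- function(x, ...) {
  cat("Longitudinal profile for", x$subject_id, "—",
      length(x$timepoints), "timepoints,",
      length(x$panel$vrg), "VRGs /", length(x$panel$brg), "BRGs\n")
  invisible(x)
}

#' Flag candidate immune events in a longitudinal profile
#'
#' A timepoint is flagged when at least `min_genes` genes of either panel
#' exceed `fold_threshold`-fold induction over the subject's healthy
#' baseline.  The flag set is monotone non-increasing in both parameters.
#'
#' @param profile A [build_profile()] object.
#' @param fold_threshold Linear fold threshold (default 2.0, strict `>`).
#' @param min_genes Minimum number of elevated genes in one panel (default 3).
#' @return Data.frame with columns `timepoint`, `n_vrg_elevated`,
#'   `n_brg_elevated`, `flagged`.
#' @export
flag_events <- function(profile, fold_threshold = 2.0, min_genes = 3) {
  stopifnot(inherits(profile, "longitudinal_profile"))
  count_panel <- function(genes) {
    if (!length(genes)) return(rep(0L, length(profile$timepoints)))
    colSums(profile$fold[genes, , drop = FALSE] > fold_threshold, na.rm = TRUE)
  }
  nv <- count_panel(profile$panel$vrg)
  nb <- count_panel(profile$panel$brg)
  data.frame(timepoint = profile$timepoints,
             n_vrg_elevated = unname(nv), n_brg_elevated = unname(nb),
             flagged = unname(nv >= min_genes | nb >= min_genes),
             row.names = NULL)
}
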