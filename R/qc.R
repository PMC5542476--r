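#' Quality-control parameters
#'
#' The pipeline floors log2 intensities at `log2(floor_linear)` (default
#' `log2(100)`, the conventional background level for single-channel arrays)
#' and removes probes whose fraction of bad entries (missing or sub-floor)
#' exceeds `max_missing_fraction`.
#'
#' @param floor_linear Linear-scale intensity floor (default 100).
#' @param max_missing_fraction Maximum tolerated fraction of bad entries per
#'   probe, in `[0, 1]` (default 0.5).
#' @return An object of class `qc_params` with elements `floor` (log2 scale),
#'   `floor_linear` and `max_missing_fraction`.
#' @export
qc_params <- function(floor_linear = 100, max_missing_fraction = 0.5) {
  if (!is.numeric(floor_linear) || floor_linear <= 1) {
    stop("`floor_linear` must be > 1 so the log2 floor is positive")
  }
  if (!is.numeric(max_missing_fraction) ||
      max_missing_fraction < 0 || max_missing_fraction > 1) {
    stop("`max_missing_fraction` must be in [0, 1]")
  }
  structure(list(floor = log2(floor_linear), floor_linear = floor_linear,
                 max_missing_fraction = max_missing_fraction),
            class = "qc_params")
}

#' Filter low-quality probes
#'
#' A probe is removed when the fraction of its entries that are missing *or*
#' below the intensity floor exceeds `params$max_missing_fraction`.  The two
#' defect types are pooled into a single bad-entry fraction, which is monotone
#' in both.  Probe order is preserved.
#'
#' @param x Probe-level log2 matrix (probes x samples, `NA` = missing).
#' @param params A [qc_params()] object.
#' @return The surviving subset of `x`.
#' @export
filter_probes <- function(x, params = qc_params()) {
  assert_expr_matrix(x)
  stopifnot(inherits(params, "qc_params"))
  bad <- is.na(x) | x < params$floor   # NA entries are bad by the first term
  frac <- rowMeans(bad)
  keep <- frac <= params$max_missing_fraction
  if (!any(keep)) {
    stop("all probes removed by QC filtering; review `floor_linear` and ",
         "`max_missing_fraction`")
  }
  x[keep, , drop = FALSE]
}

#' Floor low log2 intensities
#'
#' Every non-missing value below the floor is replaced by the floor; values at
#' or above it are unchanged.  Idempotent.
#'
#' @inheritParams filter_probes
#' @return Matrix of the same shape with floored values.
#' @export
floor_values <- function(x, params = qc_params()) {
  assert_expr_matrix(x)
  stopifnot(inherits(params, "qc_params"))
  low <- !is.na(x) & x < params$floor
  x[low] <- params$floor
  x
}

#' Aggregate probe-level values to gene level
#'
#' The gene-level value is the mean log2 intensity over the gene's probes,
#' computed over non-missing entries only; a gene/sample entry is missing only
#' when all its probes are missing there.  Probes mapping to several genes
#' contribute to each mapped gene; probes with no mapping are excluded with a
#' message (not an error).
#'
#' @param x Probe-level log2 matrix (probes x samples).
#' @param probe_map Data.frame with columns `probe_id`, `gene_symbol`
#'   (see [read_probe_map()]); symbols are matched upper-case.
#' @return Gene-level log2 matrix (genes x samples), genes sorted
#'   alphabetically.
#' @export
aggregate_probes <- function(x, probe_map) {
  assert_expr_matrix(x)
  stopifnot(is.data.frame(probe_map),
            all(c("probe_id", "gene_symbol") %in% names(probe_map)))
  map <- probe_map[probe_map$probe_id %in% rownames(x), , drop = FALSE]
  unmapped <- setdiff(rownames(x), probe_map$probe_id)
  if (length(unmapped)) {
    message(length(unmapped), " probe(s) without gene mapping excluded from aggregation")
  }
  if (!nrow(map)) stop("no probes could be mapped to genes")
  m <- x[map$probe_id, , drop = FALSE]
  g <- toupper(map$gene_symbol)
  n_obs <- rowsum((!is.na(m)) * 1, g)
  sums <- rowsum(ifelse(is.na(m), 0, m), g)
  out <- sums / n_obs
  out[n_obs == 0] <- NA_real_
  out
}

#' Run the full quality-control pipeline
#'
#' Filter probes, floor intensities, aggregate to gene level — in that order,
#' so all non-missing gene-level values are at or above the floor.
#'
#' @inheritParams aggregate_probes
#' @param params A [qc_params()] object.
#' @return Gene-level log2 matrix.
#' @export
run_qc <- function(x, probe_map, params = qc_params()) {
  aggregate_probes(floor_values(filter_probes(x, params), params), probe_map)
}
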