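## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

## row-wise median ignoring missing entries; rows that are entirely missing
## give NA (callers treat that as "undefined, excluded downstream")
row_medians <- function(x) {
  apply(x, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  })
}

assert_expr_matrix <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix (features x samples)", arg),
         call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(sprintf("`%s` must have rownames (features) and colnames (samples)", arg),
         call. = FALSE)
  }
  invisible(x)
}

assert_samples_present <- function(x, ids, what = "sample") {
  missing <- setdiff(ids, colnames(x))
  if (length(missing)) {
    stop(sprintf("%s ids absent from expression matrix: %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

## run `expr` under a fixed seed when one is given, without touching the
## caller's RNG stream otherwise
with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(seed, expr, .rng_kind = "Mersenne-Twister",
                     .rng_normal_kind = "Inversion",
                     .rng_sample_kind = "Rejection")
  }
}
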