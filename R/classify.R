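## shared confusion computation; degenerate denominators give 0 by convention
.confusion <- function(tp, fn, fp, tn, positive_class = NA_character_) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  precision <- if ((tp + fp) == 0) 0 else tp / (tp + fp)
  recall <- if ((tp + fn) == 0) 0 else tp / (tp + fn)
  f1 <- if ((2 * tp + fp + fn) == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn,
                 precision = precision, recall = recall, f1 = f1,
                 positive_class = positive_class),
            class = "confusion_metrics")
}

#' Confusion-matrix metrics from predicted and true labels
#'
#' Precision `tp/(tp+fp)`, recall `tp/(tp+fn)` and
#' `F1 = 2*tp/(2*tp+fp+fn)` (the harmonic mean of precision and recall).
#' A degenerate denominator (no predicted positives / no true positives)
#' gives 0 for the affected measure.  Values are kept at full precision;
#' rounding to two decimals happens only when printing.
#'
#' @param predicted,truth Equal-length label vectors.
#' @param positive_class The label counted as positive.
#' @return An object of class `confusion_metrics` with elements `tp`, `fn`,
#'   `fp`, `tn`, `precision`, `recall`, `f1`.
#' @export
confusion_metrics <- function(predicted, truth, positive_class) {
  if (length(predicted) == 0L || length(predicted) != length(truth)) {
    stop("`predicted` and `truth` must be non-empty and of equal length")
  }
  pp <- predicted == positive_class
  tp_ <- truth == positive_class
  .confusion(tp = sum(pp & tp_), fn = sum(!pp & tp_),
             fp = sum(pp & !tp_), tn = sum(!pp & !tp_),
             positive_class = positive_class)
}

#' Confusion-matrix metrics from raw counts
#'
#' Same measures as [confusion_metrics()], computed directly from TP/FN/FP/TN
#' counts (e.g. counts printed in a publication).
#'
#' @param tp,fn,fp,tn Non-negative counts.
#' @return An object of class `confusion_metrics`.
#' @export
confusion_from_counts <- function(tp, fn, fp, tn) {
  .confusion(tp, fn, fp, tn)
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("TP=%d FN=%d FP=%d TN=%d | precision=%.2f recall=%.2f F1=%.2f\n",
              x$tp, x$fn, x$fp, x$tn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Two-cluster k-means discrimination on (NG_V, NG_B) scores
#'
#' Lloyd's algorithm with k = 2 on the raw (NG_V, NG_B) count vectors (both
#' axes share units, 0..panel size, so no standardization is applied), with
#' `n_start` restarts keeping the solution with the lowest within-cluster sum
#' of squares.  Initial centers are pairs of *distinct* score vectors
#' (duplicated count vectors are the norm); when there are few distinct
#' vectors, every distinct pair is tried, making the result deterministic on
#' small inputs.  The cluster whose
#' centroid has the larger `ng_v - ng_b` is labelled the viral-pattern class,
#' the other the bacterial-pattern class.
#'
#' @param scores Data.frame with columns `ng_v`, `ng_b` and (optionally)
#'   `sample_id` ([count_dysregulated()]).
#' @param seed Optional integer seed for the restarts.
#' @param n_start Number of random restarts (default 10).
#' @param iter_max Maximum Lloyd iterations per start (default 100).
#' @return An object of class `kmeans_fit`: list with `centroids` (2 x 2
#'   matrix), `cluster` (integer assignment), `labels` (named character
#'   vector, `"viral"`/`"bacterial"`), `label_map`, `tot_withinss`.
#' @export
kmeans_discriminate <- function(scores, seed = NULL, n_start = 10,
                                iter_max = 100) {
  stopifnot(is.data.frame(scores), all(c("ng_v", "ng_b") %in% names(scores)))
  x <- as.matrix(scores[, c("ng_v", "ng_b")])
  ids <- if ("sample_id" %in% names(scores)) scores$sample_id
         else as.character(seq_len(nrow(x)))
  rownames(x) <- ids
  ux <- unique(x)
  if (nrow(x) < 2L || nrow(ux) < 2L) {
    stop("degenerate clustering: need >= 2 samples with distinct score vectors")
  }
  n_pairs <- nrow(ux) * (nrow(ux) - 1L) / 2
  starts <- if (n_pairs <= max(n_start, 45L)) {
    idx <- utils::combn(nrow(ux), 2L)
    lapply(seq_len(ncol(idx)), function(j) idx[, j])
  } else NULL
  fit <- with_optional_seed(seed, {
    best <- NULL
    for (r in seq_len(if (is.null(starts)) n_start else length(starts))) {
      rows <- if (is.null(starts)) sample.int(nrow(ux), 2L) else starts[[r]]
      centers <- ux[rows, , drop = FALSE]
      km <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = centers,
                                       iter.max = iter_max,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(km) &&
          (is.null(best) || km$tot.withinss < best$tot.withinss - 1e-12)) {
        best <- km
      }
    }
    if (is.null(best)) stop("k-means failed to converge from any start")
    best
  })
  viral_cluster <- which.max(fit$centers[, "ng_v"] - fit$centers[, "ng_b"])
  label_map <- ifelse(seq_len(2L) == viral_cluster, "viral", "bacterial")
  labels <- stats::setNames(label_map[fit$cluster], ids)
  structure(list(centroids = fit$centers, cluster = fit$cluster,
                 labels = labels, label_map = label_map,
                 tot_withinss = fit$tot.withinss),
            class = "kmeans_fit")
}

#' @export
print.kmeans_fit <- function(x, ...) {
  cat("2-cluster k-means on (NG_V, NG_B); within-cluster SS =",
      format(x$tot_withinss, digits = 6), "\n")
  print(round(x$centroids, 2))
  invisible(x)
}

## Newton/IRLS for single-feature logistic regression with an optional ridge
## penalty on the slope (the intercept is never penalized, so the decision
## boundary of symmetric data stays put); step-halving guards against
## overshoot near separation
.logistic_irls <- function(x, y, lambda = 0, max_iter = 100, tol = 1e-10) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  pen <- c(0, lambda)
  neg_loglik <- function(b) {
    eta <- drop(X %*% b)
    # log(1+exp(eta)) computed stably for large |eta|
    lse <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
    -sum(y * eta - lse) + lambda / 2 * b[2L]^2
  }
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(X, X * w) + diag(pen, 2L)
    g <- drop(crossprod(X, y - p)) - pen * beta
    step <- drop(solve(H, g))
    f0 <- neg_loglik(beta)
    t_ <- 1
    while (neg_loglik(beta + t_ * step) > f0 + 1e-12 && t_ > 1e-6) t_ <- t_ / 2
    beta <- beta + t_ * step
    if (max(abs(t_ * step)) < tol) {
      converged <- TRUE
      break
    }
  }
  list(beta = unname(beta), converged = converged)
}

#' Fit a single-gene logistic classifier
#'
#' Maximum-likelihood fit of `F(x) = 1 / (1 + exp(-(a0 + a1 x)))` on one
#' feature (typically the fold-change value of a biomarker gene).  When the
#' training classes are perfectly separable the unpenalized likelihood has no
#' finite maximum, so the fit falls back to a small ridge penalty on the
#' slope (strength `1e-4`; the intercept is not penalized) that guarantees
#' finite coefficients.
#'
#' @param x Numeric feature vector (linear fold changes by default).
#' @param y Class labels: logical, 0/1 numeric, or a vector matched against
#'   `positive_class`.
#' @param positive_class Label treated as positive when `y` is not
#'   logical/0-1.
#' @param feature Optional feature (gene) name stored in the model.
#' @param feature_scale `"linear"` (default) to use `x` as is, `"log2"` to
#'   model `log2(x)`.
#' @param ridge Ridge strength for the separable fallback (default 1e-4).
#' @param decision_threshold Probability threshold for [predict_logistic()]
#'   (default 0.5).
#' @return An object of class `logistic_biomarker` with coefficients `a0`,
#'   `a1`, the feature transform, and a `separable` flag.
#' @export
fit_logistic <- function(x, y, positive_class = NULL, feature = NULL,
                         feature_scale = c("linear", "log2"), ridge = 1e-4,
                         decision_threshold = 0.5) {
  feature_scale <- match.arg(feature_scale)
  if (is.logical(y)) {
    y01 <- as.numeric(y)
  } else if (is.numeric(y) && all(y %in% c(0, 1))) {
    y01 <- as.numeric(y)
  } else {
    if (is.null(positive_class)) {
      stop("supply `positive_class` for non-logical labels")
    }
    y01 <- as.numeric(y == positive_class)
  }
  if (length(unique(y01)) < 2L) {
    stop("training data must contain both classes")
  }
  stopifnot(length(x) == length(y01), all(is.finite(x)))
  xx <- if (feature_scale == "log2") {
    if (any(x <= 0)) stop("log2 feature scale requires positive x")
    log2(x)
  } else x

  fit <- .logistic_irls(xx, y01, lambda = 0)
  separable <- !fit$converged || max(abs(fit$beta)) > 25
  if (separable) fit <- .logistic_irls(xx, y01, lambda = ridge)
  if (!all(is.finite(fit$beta))) stop("logistic fit failed to produce finite coefficients")
  structure(list(a0 = fit$beta[1L], a1 = fit$beta[2L], feature = feature,
                 feature_scale = feature_scale,
                 lambda = if (separable) ridge else 0,
                 separable = separable, converged = fit$converged,
                 decision_threshold = decision_threshold,
                 positive_class = positive_class),
            class = "logistic_biomarker")
}

#' @export
print.logistic_biomarker <- function(x, ...) {
  cat(sprintf("Logistic biomarker%s: F(x) = 1/(1+exp(-(%.4g + %.4g x))), %s scale%s\n",
              if (is.null(x$feature)) "" else paste0(" [", x$feature, "]"),
              x$a0, x$a1, x$feature_scale,
              if (x$separable) " (ridge-stabilized: separable training data)" else ""))
  invisible(x)
}

#' Predict with a fitted logistic biomarker
#'
#' @param model A [fit_logistic()] model.
#' @param x Feature values on the same scale the model was trained on
#'   (the model applies its own log2 transform when configured).
#' @param threshold Probability cutoff; a sample is called positive when
#'   `F(x) >= threshold` (default: the model's decision threshold).
#' @return Data.frame with columns `x`, `probability`, `positive`.
#' @export
predict_logistic <- function(model, x, threshold = model$decision_threshold) {
  stopifnot(inherits(model, "logistic_biomarker"))
  xx <- if (model$feature_scale == "log2") log2(x) else x
  p <- stats::plogis(model$a0 + model$a1 * xx)
  data.frame(x = x, probability = p, positive = p >= threshold)
}

#' Fold-threshold classification
#'
#' Calls a sample positive when its fold change (against the control-group
#' median, see [build_fc_matrix()]) strictly exceeds `fold_threshold` — e.g.
#' 2-fold induction of ISG15 for HIV-1 progressors, 3-fold ANXA3 for systemic
#' JIA.
#'
#' @param fc Numeric vector of linear fold changes.
#' @param fold_threshold Linear fold threshold (default 2.0).
#' @return Logical vector (`NA` preserved).
#' @export
threshold_classify <- function(fc, fold_threshold = 2.0) {
  stopifnot(is.numeric(fc), is.numeric(fold_threshold))
  fc > fold_threshold
}

#' Treatment-response calls from paired pre/post levels
#'
#' A patient responds when the reduction from their own pre-treatment level
#' reaches `fold_reduction`: `pre - post >= log2(fold_reduction)` (boundary
#' inclusive).  Patients present in only one of the two vectors are excluded
#' with a warning.
#'
#' @param pre,post Named log2 expression vectors (names = patient ids).
#' @param fold_reduction Linear fold-reduction threshold (default 2).
#' @return Named logical vector over the paired patients.
#' @export
treatment_response <- function(pre, post, fold_reduction = 2) {
  if (is.null(names(pre)) || is.null(names(post))) {
    stop("`pre` and `post` must be named by patient id")
  }
  ids <- intersect(names(pre), names(post))
  unpaired <- setdiff(union(names(pre), names(post)), ids)
  if (length(unpaired)) {
    warning("excluding unpaired patient(s): ", paste(unpaired, collapse = ", "))
  }
  if (!length(ids)) stop("no paired patients")
  (pre[ids] - post[ids]) >= log2(fold_reduction)
}
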