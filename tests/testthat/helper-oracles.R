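# independent oracles: brute force / enumeration / reference optimizers,
# deliberately written with plain loops so they share nothing with the
# package implementations they check

# minimum within-cluster sum of squares over all 2-partitions
brute_kmeans_wss <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    a <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    b <- setdiff(1:n, a)
    wss <- 0
    for (grp in list(a, b)) {
      ctr <- colMeans(x[grp, , drop = FALSE])
      wss <- wss + sum(sweep(x[grp, , drop = FALSE], 2, ctr)^2)
    }
    if (wss < best) best <- wss
  }
  best
}

# rank products by direct enumeration of every case x control comparison
rp_enumeration_oracle <- function(x, case_ids, control_ids) {
  pairs <- expand.grid(i = case_ids, j = control_ids,
                       stringsAsFactors = FALSE)
  up <- matrix(NA_real_, nrow(x), nrow(pairs))
  down <- matrix(NA_real_, nrow(x), nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    r <- x[, pairs$i[k]] - x[, pairs$j[k]]
    up[, k] <- rank(-r, ties.method = "average")
    down[, k] <- rank(r, ties.method = "average")
  }
  list(up = apply(up, 1, function(v) prod(v)^(1 / length(v))),
       down = apply(down, 1, function(v) prod(v)^(1 / length(v))))
}

# exhaustive pfp for an n-gene, K-comparison design: under the null every
# comparison assigns a uniform random permutation of ranks, so a gene's rank
# per comparison is uniform on 1..n and E[# null RPs <= x] is n * P(RP <= x)
exhaustive_pfp_oracle <- function(rp_obs, n_genes, n_comparisons) {
  grid <- as.matrix(do.call(expand.grid,
                            rep(list(seq_len(n_genes)), n_comparisons)))
  null_rp <- exp(rowMeans(log(grid)))
  e_fp <- n_genes * vapply(rp_obs,
                           function(x) mean(null_rp <= x + 1e-12), numeric(1))
  pos <- rank(rp_obs, ties.method = "max")
  pmin(e_fp / pos, 1)
}

# slope-ridge-penalized logistic likelihood optimum via BFGS with analytic
# gradient (the intercept is unpenalized, matching the fit's convention)
logistic_ridge_oracle <- function(x, y, lambda) {
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    lse <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
    -sum(y * eta - lse) + lambda / 2 * b[2]^2
  }
  grad <- function(b) {
    p <- plogis(b[1] + b[2] * x)
    c(-sum(y - p), -sum((y - p) * x) + lambda * b[2])
  }
  stats::optim(c(0, 0), nll, grad, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 10000))$par
}
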