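test_that("pearson matrix matches the textbook formula and basic identities", {
  m <- expr_mat(rbind(x = c(1, 2, 3, 4, 5),
                      y = c(2, 1, 4, 3, 6),
                      neg = c(5, 4, 3, 2, 1)),
                genes = c("x", "y", "neg"))
  r <- pearson_matrix(m)
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_identical(r, t(r))
  expect_equal(r["x", "neg"], -1)            # y = -x
  # direct covariance formula oracle
  xv <- m["x", ]; yv <- m["y", ]
  oracle <- sum((xv - mean(xv)) * (yv - mean(yv))) /
    sqrt(sum((xv - mean(xv))^2) * sum((yv - mean(yv))^2))
  expect_equal(r["x", "y"], oracle, tolerance = 1e-12)
})

test_that("zero-variance genes yield NA correlations, reported", {
  m <- expr_mat(rbind(a = c(1, 2, 3), flat = c(5, 5, 5)),
                genes = c("a", "flat"))
  expect_message(r <- pearson_matrix(m), "flat")
  expect_true(is.na(r["a", "flat"]))
  expect_error(pearson_matrix(m[, 1:2]), ">= 3 samples")
})

test_that("missing values are handled pairwise-complete", {
  set.seed(20)
  m <- expr_mat(matrix(rnorm(40), 4, 10))
  m[1, 3] <- NA
  r <- pearson_matrix(m)
  keep <- !is.na(m[1, ]) # pair (g1, g2) uses the 9 complete samples
  expect_equal(r[1, 2], cor(m[1, keep], m[2, keep]), tolerance = 1e-12)
})

test_that("network edges need correlation strictly above the cutoff", {
  pcc <- matrix(c(1, 0.4, 0.4, 1), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  net <- build_network(pcc, cutoff = 0.5)
  expect_equal(nrow(net$edges), 0L)
  expect_equal(net$n_components, 2L)          # all nodes become singletons
  # cutoff 1.0 admits nothing (strict inequality), even perfect correlation
  pcc2 <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(nrow(build_network(pcc2, cutoff = 1.0)$edges), 0L)
})

test_that("the edge set shrinks monotonically with the cutoff", {
  set.seed(21)
  m <- expr_mat(matrix(rnorm(200), 10, 20))
  r <- pearson_matrix(m)
  cuts <- c(0.1, 0.3, 0.5, 0.7)
  sizes <- sapply(cuts, function(ct) nrow(build_network(r, ct)$edges))
  expect_true(all(diff(sizes) <= 0))
  # and the stricter edge sets are nested in the looser ones
  e1 <- build_network(r, 0.3)$edges
  e2 <- build_network(r, 0.5)$edges
  expect_true(all(paste(e2$source, e2$target) %in% paste(e1$source, e1$target)))
})

test_that("planted latent-factor blocks come out as separate components", {
  spec <- cohort_spec(n_genes = 30, n_case = 100, n_control = 100,
                      baseline_mean_range = c(8, 12), noise_sd = 0.7,
                      coexpression_blocks = list(
                        list(genes = sprintf("G%04d", 1:10), loading = 1),
                        list(genes = sprintf("G%04d", 11:20), loading = 1)),
                      missing_rate = 0, probes_per_gene = 1,
                      probe_noise_sd = 0, sub_floor_rate = 0, seed = 99)
  co <- generate_cohort(spec)
  g <- run_qc(co$probes, co$probe_map)
  r <- pearson_matrix(g[sprintf("G%04d", 1:20), ])
  net <- build_network(r, cutoff = 0.5)
  blockA <- sprintf("G%04d", 1:10); blockB <- sprintf("G%04d", 11:20)
  # no edge bridges the two blocks
  cross <- (net$edges$source %in% blockA) != (net$edges$target %in% blockA)
  expect_false(any(cross))
  # within-block edges connect each block into one component
  expect_equal(length(unique(net$membership[blockA])), 1L)
  expect_equal(length(unique(net$membership[blockB])), 1L)
  expect_true(net$membership[blockA][1] != net$membership[blockB][1])
})

test_that("sex-stratified fold changes flag ratios above 1.4", {
  # construct male/female cases with a doubled female effect on gene GF
  genes <- c("GSAME", "GF")
  n <- 40
  sex <- rep(c("male", "female"), each = n / 2)
  group <- rep(rep(c("case", "control"), each = n / 4), 2)
  base <- matrix(8, 2, n, dimnames = list(genes, sprintf("s%d", 1:n)))
  base["GSAME", group == "case"] <- 9
  base["GF", group == "case" & sex == "male"] <- 9
  base["GF", group == "case" & sex == "female"] <- 10
  md <- toy_meta(colnames(base), group, sex = sex)
  rep_ <- sex_stratified_fc(base, md, genes)
  expect_equal(rep_$sex_ratio[rep_$gene == "GSAME"], 1)
  expect_false(rep_$flagged[rep_$gene == "GSAME"])
  expect_equal(rep_$sex_ratio[rep_$gene == "GF"], 2)
  expect_true(rep_$flagged[rep_$gene == "GF"])
})

test_that("an empty sex stratum gives NA, not an error", {
  m <- expr_mat(matrix(8, 1, 4), genes = "g")
  md <- toy_meta(colnames(m), c("case", "case", "control", "control"),
                 sex = c("male", "male", "male", "male"))
  rep_ <- sex_stratified_fc(m, md)
  expect_true(is.na(rep_$fc_female))
  expect_false(is.na(rep_$fc_male))
})

test_that("age correlation recovers a planted decline and ignores age units", {
  set.seed(22)
  n <- 500
  age <- runif(n, 20, 70)
  mk <- function() 8 - 0.01 * age + rnorm(n, 0, 0.35)
  m <- expr_mat(t(sapply(1:5, function(i) mk())),
                genes = sprintf("NL%d", 1:5), samples = sprintf("s%d", 1:n))
  md <- data.frame(sample_id = colnames(m), group = "case",
                   class_label = "x", age = age)
  r <- age_correlation(m, md)
  expect_true(all(r > -0.47 & r < -0.29))
  # affine rescaling of age units leaves the correlation unchanged
  md2 <- md; md2$age <- md$age * 12 + 3
  expect_equal(age_correlation(m, md2), r, tolerance = 1e-12)
  md3 <- md; md3$age <- 50
  expect_error(age_correlation(m, md3), "constant")
})

test_that("expression independent of age correlates near zero", {
  set.seed(23)
  n <- 400
  m <- expr_mat(matrix(rnorm(2 * n, 8), 2, n))
  md <- data.frame(sample_id = colnames(m), group = "case",
                   class_label = "x", age = runif(n, 20, 70))
  expect_true(all(abs(age_correlation(m, md)) < 0.15))
})
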