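test_that("median fold change follows the group medians", {
  m <- expr_mat(rbind(g1 = c(3, 3, 3, 3, 3),
                      g2 = c(4, 4, 4, 3, 3),
                      g3 = c(5, 6, 9, 4, 4.5)),
                genes = c("g1", "g2", "g3"),
                samples = c("c1", "c2", "c3", "h1", "h2"))
  fc <- median_fold_change(m, c("c1", "c2", "c3"), c("h1", "h2"))
  expect_equal(unname(fc["g1"]), 1.0)          # identical medians
  expect_equal(unname(fc["g2"]), 2.0)          # one log2 unit apart
  # hand-computed: case median 6, control median (4+4.5)/2 = 4.25
  expect_equal(unname(fc["g3"]), 2^(6 - 4.25), tolerance = 1e-12)

  # full worked example with uneven groups and an outlier control
  m2 <- expr_mat(rbind(g = c(5, 6, 9, 4, 4.5, 5, 20)),
                 genes = "g", samples = sprintf("s%d", 1:7))
  fc2 <- median_fold_change(m2, c("s1", "s2", "s3"), sprintf("s%d", 4:7))
  expect_equal(unname(fc2), 2^(6 - 4.75), tolerance = 1e-12)
})

test_that("fold change is a ratio: invariant to adding a constant", {
  set.seed(5)
  m <- expr_mat(matrix(rnorm(60, 8), 10, 6))
  cases <- colnames(m)[1:3]; ctrls <- colnames(m)[4:6]
  expect_equal(median_fold_change(m + 3.7, cases, ctrls),
               median_fold_change(m, cases, ctrls), tolerance = 1e-12)
})

test_that("genes entirely missing in a group get an undefined fold change", {
  m <- expr_mat(rbind(g1 = c(NA, NA, 5, 6), g2 = c(7, 8, 5, 6)),
                genes = c("g1", "g2"))
  fc <- median_fold_change(m, colnames(m)[1:2], colnames(m)[3:4])
  expect_true(is.na(fc["g1"]))
  expect_false(is.na(fc["g2"]))
  expect_error(median_fold_change(m, character(), colnames(m)[3:4]),
               "at least one sample")
})

test_that("single-pair rank products equal the ranks themselves", {
  m <- expr_mat(rbind(g1 = c(9, 5), g2 = c(7, 5), g3 = c(6, 5)),
                genes = c("g1", "g2", "g3"), samples = c("c1", "h1"))
  rp <- rank_product(m, "c1", "h1", n_perm = 10, seed = 1)
  expect_equal(rp$rp_up, c(1, 2, 3))
  expect_equal(rp$rp_down, c(3, 2, 1))
})

test_that("a gene most up-regulated in every pair has rank product 1", {
  set.seed(6)
  m <- expr_mat(rbind(top = c(14, 14.5, 15, 6, 6.2),
                      matrix(rnorm(15, 8, 0.3), 3, 5)),
                genes = c("top", "g2", "g3", "g4"))
  rp <- rank_product(m, colnames(m)[1:3], colnames(m)[4:5],
                     n_perm = 10, seed = 1)
  expect_equal(rp$rp_up[rp$gene == "top"], 1)
  # and no gene can lead both the up and the down ordering
  expect_false(which.min(rp$rp_up) == which.min(rp$rp_down))
})

test_that("rank product is rank-based: invariant to monotone rescaling", {
  set.seed(7)
  m <- expr_mat(matrix(rnorm(36, 8), 6, 6))
  cases <- colnames(m)[1:3]; ctrls <- colnames(m)[4:6]
  rp1 <- rank_product(m, cases, ctrls, n_perm = 5, seed = 9)
  # positive scaling of all values scales every pairwise ratio monotonically
  rp2 <- rank_product(2.5 * m, cases, ctrls, n_perm = 5, seed = 9)
  # per-sample constants shift every ratio of a comparison by a constant
  shifts <- matrix(rnorm(6), 6, 6, byrow = TRUE)
  rp3 <- rank_product(m + shifts, cases, ctrls, n_perm = 5, seed = 9)
  expect_equal(rp1$rp_up, rp2$rp_up)
  expect_equal(rp1$rp_down, rp2$rp_down)
  expect_equal(rp1$rp_up, rp3$rp_up)
})

test_that("rank product validates its inputs", {
  m <- expr_mat(matrix(rnorm(12, 8), 3, 4))
  expect_error(rank_product(m, colnames(m)[1:2], colnames(m)[3:4],
                            n_perm = 0), "n_perm")
  expect_error(rank_product(m, colnames(m)[1:2], character()),
               "at least one sample")
  expect_error(rank_product(m[1, , drop = FALSE], colnames(m)[1:2],
                            colnames(m)[3:4]), "2 genes")
})

test_that("DEG selection uses strict fold-change inequalities", {
  fc <- c(a = 2.0, b = 2.01, c = 0.5, d = 0.4, e = 1.0, f = NA)
  sel <- select_degs(fc)
  expect_equal(sel$up, "b")       # exactly 2.0 is excluded
  expect_equal(sel$down, "d")     # exactly 0.5 is excluded

  lenient <- select_degs(fc, thresholds = deg_thresholds("lenient"))
  expect_setequal(lenient$up, c("a", "b"))
  expect_setequal(lenient$down, c("c", "d"))
})

test_that("planted strong effects are exactly the selected up-set", {
  set.seed(8)
  fc <- stats::setNames(runif(93, 0.6, 1.8), sprintf("bg%02d", 1:93))
  planted <- stats::setNames(rep(4, 7), sprintf("pl%d", 1:7))
  sel <- select_degs(c(fc, planted))
  expect_setequal(sel$up, names(planted))
  expect_equal(sel$down, character())
})

test_that("rank-product ordering is carried into the selected sets", {
  fc <- c(g1 = 4, g2 = 3, g3 = 8)
  rp <- data.frame(gene = c("g1", "g2", "g3"), rp_up = c(2.5, 1.0, 4.0),
                   rp_down = c(3, 4, 1))
  sel <- select_degs(fc, rp)
  expect_equal(sel$up, c("g2", "g1", "g3"))
})

test_that("run_de labels directions at the requested thresholds", {
  set.seed(9)
  m <- expr_mat(rbind(up = c(10, 10.2, 9.8, 8, 8.1, 7.9),
                      dn = c(6, 6.1, 5.9, 8, 8.2, 7.8),
                      fl = c(8, 8.1, 7.9, 8, 8.1, 7.9)),
                genes = c("up", "dn", "fl"))
  md <- toy_meta(colnames(m), rep(c("case", "control"), each = 3))
  de <- run_de(m, md, n_perm = 20, seed = 3)
  expect_equal(de$direction, c("up", "down", "none"))
  expect_true(all(de$fc > 0))
  expect_true(all(de$rp_up >= 1 & de$rp_down >= 1))
  expect_true(all(de$pfp_up >= 0 & de$pfp_up <= 1))
})
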