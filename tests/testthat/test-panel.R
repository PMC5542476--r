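test_that("frequency counting is directional and per-dataset", {
  fc <- cbind(D1 = c(gA = 2.5, gB = 1.0, gC = 4.0),
              D2 = c(gA = 0.4, gB = 1.2, gC = 4.0),
              D3 = c(gA = 1.1, gB = 0.9, gC = 4.0))
  ft <- ft_from_matrix(fc)
  expect_equal(unname(ft$n_significant[ft$genes == "gA"]), 2)
  expect_equal(unname(ft$n_up[ft$genes == "gA"]), 1)
  expect_equal(unname(ft$n_down[ft$genes == "gA"]), 1)
  expect_equal(unname(ft$n_significant[ft$genes == "gB"]), 0)
  expect_equal(unname(ft$n_significant[ft$genes == "gC"]), 3)
})

test_that("genes absent from a dataset contribute no count there", {
  ft <- frequency_table(list(D1 = c(gA = 4, gB = 4), D2 = c(gA = 4)))
  expect_equal(unname(ft$n_significant[ft$genes == "gB"]), 1)
  expect_true(is.na(ft$fc["gB", "D2"]))
})

test_that("a gene planted in 12 of 20 datasets counts 12", {
  datasets <- sprintf("D%02d", 1:20)
  fc <- sapply(seq_along(datasets), function(j) {
    c(g = if (j <= 12) 4.0 else 1.0, other = 1.0)
  })
  colnames(fc) <- datasets
  ft <- ft_from_matrix(fc)
  expect_equal(unname(ft$n_significant[ft$genes == "g"]), 12)
})

test_that("frequency counting ignores dataset order", {
  set.seed(10)
  fc <- matrix(runif(60, 0.3, 5), 6, 10,
               dimnames = list(sprintf("g%d", 1:6), sprintf("D%d", 1:10)))
  ft1 <- ft_from_matrix(fc)
  ft2 <- ft_from_matrix(fc[, sample(10)])
  expect_equal(ft1$n_significant, ft2$n_significant)
  expect_equal(ft1$n_up, ft2$n_up)
})

test_that("candidate selection is an at-least rule", {
  datasets <- sprintf("D%02d", 1:20)
  fc <- rbind(AT8 = c(rep(4, 8), rep(1, 12)),
              AT7 = c(rep(4, 7), rep(1, 13)))
  colnames(fc) <- datasets
  ft <- ft_from_matrix(fc)
  expect_equal(select_candidates(ft), "AT8")
  expect_warning(
    out <- select_candidates(ft, selection_rules(min_datasets = 21)),
    "no candidate")
  expect_equal(out, character())
})

test_that("a design with exactly 55 qualifying genes gives 55 candidates", {
  datasets <- sprintf("D%02d", 1:20)
  qual <- t(sapply(1:55, function(i) c(rep(4, 8), rep(1, 12))))
  near <- t(sapply(1:45, function(i) c(rep(4, 7), rep(1, 13))))
  fc <- rbind(qual, near)
  dimnames(fc) <- list(sprintf("g%03d", 1:100), datasets)
  ft <- ft_from_matrix(fc)
  expect_length(select_candidates(ft), 55L)
})

test_that("VRGs are the top candidates by viral mean FC, ties broken stably", {
  datasets <- c("V1", "V2", "O1")
  fc <- rbind(GHI  = c(17.4, 17.0, 3),
              GMID = c(9.0, 9.2, 3),
              GT1  = c(5.0, 5.0, 3),    # tie on viral mean with GT2
              GT2  = c(5.0, 5.0, 1),    # lower n_significant
              GLO  = c(3.0, 3.0, 3))
  colnames(fc) <- datasets
  ft <- ft_from_matrix(fc)
  cand <- ft$genes
  rules <- selection_rules(min_datasets = 1, n_viral_top = 4)
  vrg <- select_vrgs(ft, cand, c("V1", "V2"), rules)
  expect_equal(vrg, c("GHI", "GMID", "GT1", "GT2"))
  # alphabetical as the last resort
  fc2 <- fc; rownames(fc2)[4] <- "GA2"; fc2["GA2", "O1"] <- 3
  ft2 <- ft_from_matrix(fc2)
  vrg2 <- select_vrgs(ft2, ft2$genes, c("V1", "V2"), rules)
  expect_equal(vrg2[3:4], c("GA2", "GT1"))
  expect_warning(select_vrgs(ft, cand, c("V1", "V2"),
                             selection_rules(min_datasets = 1,
                                             n_viral_top = 99)),
                 "fewer candidates")
})

## fixture mirroring the published bacterial selection: 5 genes with mean
## FC > 8, one rescue gene significant in 13/20, five mid-range genes with
## >= 10/20 (two of them close-ranked, one manually deselected), plus one
## mid-range gene at only 9/20 that must not be selected
brg_fixture <- function() {
  datasets <- c(sprintf("V%d", 1:4), sprintf("B%d", 1:4), sprintf("M%02d", 1:12))
  gene_row <- function(bact_fc, n_mixed) {
    c(rep(1, 4), rep(bact_fc, 4), rep(3, n_mixed), rep(1, 12 - n_mixed))
  }
  fc <- rbind(H1 = gene_row(12, 6), H2 = gene_row(11, 6), H3 = gene_row(10, 6),
              H4 = gene_row(9.5, 6), H5 = gene_row(9.1, 6),
              RS1 = gene_row(2.5, 9),            # 13/20, bacterial mean < 5
              M1 = gene_row(7.5, 6), M2 = gene_row(7.0, 6),
              M3 = gene_row(6.5, 6),
              TL5 = gene_row(5.3, 6), GY1 = gene_row(5.2, 6),
              MX = gene_row(6.0, 5))             # mid FC but only 9/20
  colnames(fc) <- datasets
  ft_from_matrix(fc)
}

test_that("bacterial selection applies the three rules and overrides", {
  ft <- brg_fixture()
  cand <- select_candidates(ft)
  expect_true(all(c("H1", "RS1", "TL5", "GY1", "MX") %in% cand))

  rules <- selection_rules(exclude = "GY1")
  brg <- select_brgs(ft, cand, sprintf("B%d", 1:4), rules)
  expect_length(brg, 10L)
  expect_true("TL5" %in% brg)          # kept over the deselected GY1
  expect_false("GY1" %in% brg)
  expect_false("MX" %in% brg)          # mid-range needs >= 10 of 20
  expect_true(all(sprintf("H%d", 1:5) %in% brg))
  expect_true("RS1" %in% brg)          # rescued by 13/20 despite low mean FC
  rule <- attr(brg, "rule")
  expect_equal(unname(rule["RS1"]), "rescue")
  expect_equal(unname(rule["H1"]), "high_fc")
  expect_equal(unname(rule["TL5"]), "mid_fc")
})

test_that("without the override, 11 qualifiers are truncated by bacterial FC", {
  # mechanical truncation drops the gene with the lowest bacterial mean —
  # here the rescue gene, which is precisely why the published deselection
  # step is encoded as an explicit override rather than a ranking rule
  ft <- brg_fixture()
  cand <- select_candidates(ft)
  brg <- select_brgs(ft, cand, sprintf("B%d", 1:4), selection_rules())
  expect_length(brg, 10L)
  expect_false("RS1" %in% brg)
  expect_true(all(c("TL5", "GY1") %in% brg))
})

test_that("viral and bacterial panels stay disjoint, viral list winning", {
  datasets <- c(sprintf("V%d", 1:4), sprintf("B%d", 1:4), sprintf("M%02d", 1:12))
  both_row <- c(rep(12, 4), rep(12, 4), rep(3, 6), rep(1, 6))
  v_rows <- t(sapply(1:10, function(i) c(rep(10 - i / 2, 4), rep(1, 4),
                                         rep(3, 6), rep(1, 6))))
  b_rows <- t(sapply(1:10, function(i) c(rep(1, 4), rep(10 - i / 2, 4),
                                         rep(3, 6), rep(1, 6))))
  fc <- rbind(BOTH = both_row, v_rows, b_rows)
  rownames(fc) <- c("BOTH", sprintf("V%02d", 1:10), sprintf("B%02d", 1:10))
  colnames(fc) <- datasets
  ft <- ft_from_matrix(fc)
  pn <- select_panel(ft, sprintf("V%d", 1:4), sprintf("B%d", 1:4))
  expect_true("BOTH" %in% pn$vrg)
  expect_false("BOTH" %in% pn$brg)
  expect_length(intersect(pn$vrg, pn$brg), 0L)
  expect_length(pn$brg, 10L)
  # panels are subsets of the candidate pool
  cand <- select_candidates(ft)
  expect_true(all(c(pn$vrg, pn$brg) %in% cand))
  expect_equal(pn$provenance$panel,
               rep(c("vrg", "brg"), each = 10L))
})

test_that("disease-specific screening needs all targets and a quiet background", {
  datasets <- c("T1", "T2", "T3", sprintf("D%02d", 1:20))
  fc <- rbind(SPEC = c(4, 4, 4, rep(1, 20)),
              PART = c(4, 4, 1, rep(1, 20)),
              COMM = c(4, 4, 4, rep(4, 20)))
  colnames(fc) <- datasets
  ft <- ft_from_matrix(fc)
  expect_equal(find_specific_genes(ft, c("T1", "T2", "T3")), "SPEC")
  expect_setequal(find_specific_genes(ft, c("T1", "T2", "T3"),
                                      max_background_count = 20),
                  c("SPEC", "COMM"))
  expect_error(find_specific_genes(ft, "missing_ds"), "unknown dataset")
})
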