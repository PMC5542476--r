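test_that("identical specs with the same seed give bit-identical cohorts", {
  spec <- cohort_spec(n_genes = 50, n_case = 5, n_control = 5, seed = 123)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$probes, b$probes)
  expect_identical(a$metadata, b$metadata)
  c_ <- generate_cohort(cohort_spec(n_genes = 50, n_case = 5, n_control = 5,
                                    seed = 124))
  expect_false(identical(a$probes, c_$probes))
})

test_that("a fixed master seed reproduces the whole study and series", {
  s1 <- generate_study(n_viral = 1, n_bacterial = 1, n_mixed = 1,
                       n_genes = 100, n_case = 4, n_control = 4, seed = 7)
  s2 <- generate_study(n_viral = 1, n_bacterial = 1, n_mixed = 1,
                       n_genes = 100, n_case = 4, n_control = 4, seed = 7)
  expect_identical(lapply(s1$cohorts, `[[`, "probes"),
                   lapply(s2$cohorts, `[[`, "probes"))
  l1 <- generate_longitudinal(seed = 5)
  l2 <- generate_longitudinal(seed = 5)
  expect_identical(l1$series, l2$series)
})

test_that("a zero-cohort design gives an empty study", {
  st <- generate_study(n_viral = 0, n_bacterial = 0, n_mixed = 0, seed = 1)
  expect_length(st$cohorts, 0L)
})

test_that("unplanted cohorts have fold changes near 1", {
  spec <- cohort_spec(n_genes = 200, n_case = 30, n_control = 30,
                      baseline_mean_range = c(8, 12), missing_rate = 0,
                      probes_per_gene = 1, probe_noise_sd = 0,
                      sub_floor_rate = 0, seed = 31)
  co <- generate_cohort(spec)
  md <- co$metadata
  fc <- median_fold_change(co$probes, md$sample_id[md$group == "case"],
                           md$sample_id[md$group == "control"])
  expect_lt(max(abs(log2(fc))), 0.75)
})

test_that("planted fold changes are recovered without bias", {
  # planted FC 8, noise sd 0.5, 30 vs 30: estimate lands in [6, 10]
  # for at least 95% of seeds
  planted <- stats::setNames(rep(8, 10), sprintf("G%04d", 1:10))
  hits <- vapply(1:200, function(s) {
    spec <- cohort_spec(n_genes = 50, n_case = 30, n_control = 30,
                        baseline_mean_range = c(8, 12), noise_sd = 0.5,
                        planted_effects = planted, missing_rate = 0,
                        probes_per_gene = 1, probe_noise_sd = 0,
                        sub_floor_rate = 0, seed = s)
    co <- generate_cohort(spec)
    g <- aggregate_probes(co$probes, co$probe_map)
    md <- co$metadata
    fc <- median_fold_change(g, md$sample_id[md$group == "case"],
                             md$sample_id[md$group == "control"])
    mean(fc[names(planted)] >= 6 & fc[names(planted)] <= 10)
  }, numeric(1))
  # fraction of per-gene estimates inside the band, pooled over seeds
  expect_gte(mean(hits), 0.95)
})

test_that("stringent DEG selection recovers planted 8-fold genes", {
  planted <- stats::setNames(rep(8, 10), sprintf("G%04d", 1:10))
  rec <- vapply(1:30, function(s) {
    spec <- cohort_spec(n_genes = 1000, n_case = 20, n_control = 20,
                        baseline_mean_range = c(8, 12), noise_sd = 0.7,
                        planted_effects = planted, missing_rate = 0,
                        probes_per_gene = 1, probe_noise_sd = 0,
                        sub_floor_rate = 0, seed = 1000 + s)
    co <- generate_cohort(spec)
    g <- aggregate_probes(co$probes, co$probe_map)
    md <- co$metadata
    fc <- median_fold_change(g, md$sample_id[md$group == "case"],
                             md$sample_id[md$group == "control"])
    sum(names(planted) %in% select_degs(fc)$up)
  }, numeric(1))
  expect_gte(mean(rec >= 9), 0.95)
})

test_that("injected missing values match the requested rate", {
  spec <- cohort_spec(n_genes = 1000, n_case = 20, n_control = 20,
                      missing_rate = 0.02, probes_per_gene = 1,
                      sub_floor_rate = 0, seed = 55)
  co <- generate_cohort(spec)
  expect_lt(abs(mean(is.na(co$probes)) - 0.02), 0.01)
})

test_that("sub-floor injection and probe replication feed the QC path", {
  spec <- cohort_spec(n_genes = 100, n_case = 5, n_control = 5,
                      probes_per_gene = 1:3, sub_floor_rate = 0.05,
                      missing_rate = 0, seed = 66)
  co <- generate_cohort(spec)
  expect_true(any(co$probes < log2(100), na.rm = TRUE))
  expect_gt(nrow(co$probes), 100)
  expect_equal(nrow(co$probe_map), nrow(co$probes))
  expect_equal(sort(unique(co$probe_map$gene_symbol)),
               sort(sprintf("G%04d", 1:100)))
})

test_that("invalid planted genes and event windows are rejected", {
  expect_error(generate_cohort(
    cohort_spec(n_genes = 10, n_case = 2, n_control = 2,
                planted_effects = c(NOPE = 4), seed = 1)),
    "NOPE")
  expect_error(cohort_spec(planted_effects = c(G0001 = -2)), "> 0")
  expect_error(cohort_spec(missing_rate = 2), "rates")
  expect_error(generate_longitudinal(events = list(
    list(start = 10, duration = 20, panel = "vrg", fold = 4),
    list(start = 20, duration = 20, panel = "vrg", fold = 4)), seed = 1),
    "overlapping")
})

test_that("study cohorts plant panel effects with the declared structure", {
  st <- generate_study(n_genes = 100, n_case = 4, n_control = 4, seed = 11)
  expect_length(st$cohorts, 20L)
  expect_equal(length(st$design$viral_ids), 4L)
  expect_equal(length(st$design$bacterial_ids), 4L)
  # viral cohorts plant every VRG, at fold changes within plausible bounds
  for (id in st$design$viral_ids) {
    eff <- st$truth$planted_by_cohort[[id]]
    expect_true(all(st$truth$vrg %in% names(eff)))
    expect_false(any(st$truth$brg %in% names(eff)))
  }
  for (id in st$design$bacterial_ids) {
    eff <- st$truth$planted_by_cohort[[id]]
    expect_true(all(st$truth$brg %in% names(eff)))
  }
  # per-gene panel means stay inside the configured ranges
  expect_true(all(st$truth$mean_fc_vrg >= 4.97 & st$truth$mean_fc_vrg <= 17.42))
  expect_true(all(st$truth$mean_fc_brg >= 4.90 & st$truth$mean_fc_brg <= 15.91))
  # mixed cohorts cycle viral / bacterial / dual patterns
  cls <- vapply(st$cohorts[st$design$mixed_ids],
                function(co) co$metadata$class_label[1], character(1))
  expect_equal(unname(cls[1:3]),
               c("mixed_viral", "mixed_bacterial", "mixed_both"))
})
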