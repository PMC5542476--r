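#!/usr/bin/env Rscript

# Step 1 — simulate the discovery study.
#
# Generates the 20-cohort synthetic discovery design the rest of the analysis
# consumes: 4 viral-infection cohorts planting the 10 virus-response genes
# (VRG01..VRG10), 4 bacterial cohorts planting the 10 bacteria-response genes
# (BRG01..BRG10), and 12 further disease cohorts cycling viral-like,
# bacterial-like and dual dysregulation patterns, plus a pool of 35 common
# immune-response genes. Cohorts are regenerated deterministically from the
# master seed by every later script, so nothing large needs to be stored.

library(bloodsig)

MASTER_SEED <- 42
dir.create("results", showWarnings = FALSE)

st <- generate_study(seed = MASTER_SEED)

summary_tab <- do.call(rbind, lapply(names(st$cohorts), function(id) {
  co <- st$cohorts[[id]]
  eff <- st$truth$planted_by_cohort[[id]]
  data.frame(cohort = id,
             class = co$metadata$class_label[1],
             n_case = sum(co$metadata$group == "case"),
             n_control = sum(co$metadata$group == "control"),
             n_probes = nrow(co$probes),
             n_planted_vrg = sum(names(eff) %in% st$truth$vrg),
             n_planted_brg = sum(names(eff) %in% st$truth$brg),
             n_planted_common = sum(names(eff) %in% st$truth$common),
             missing_frac = round(mean(is.na(co$probes)), 4))
}))
write.table(summary_tab, "results/01_study_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Simulated", length(st$cohorts), "cohorts (master seed", MASTER_SEED, ")\n")
cat("Viral cohorts:    ", paste(st$design$viral_ids, collapse = ", "), "\n")
cat("Bacterial cohorts:", paste(st$design$bacterial_ids, collapse = ", "), "\n")
cat("Per-gene planted mean FCs span",
    sprintf("%.2f-%.2f (VRG) and %.2f-%.2f (BRG)\n",
            min(st$truth$mean_fc_vrg), max(st$truth$mean_fc_vrg),
            min(st$truth$mean_fc_brg), max(st$truth$mean_fc_brg)))
cat("Wrote results/01_study_summary.tsv\n")
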