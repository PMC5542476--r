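#!/usr/bin/env Rscript

# Step 3 — cross-dataset frequency ranking and panel selection.
#
# Runs QC + median fold change on all 20 cohorts, builds the dysregulation
# frequency table, and executes the full selection procedure: candidates
# significant in >= 8 of 20 datasets; the 10 VRGs by viral mean fold change;
# the 10 BRGs by the three bacterial rules (mean FC > 8; rescue at >= 13/20;
# mean FC in [5,8] with >= 10/20) with truncation/padding by bacterial mean.
# The selected panel is compared against the planted truth and serialized.

library(bloodsig)

MASTER_SEED <- 42
dir.create("results", showWarnings = FALSE)

st <- generate_study(seed = MASTER_SEED)

fc_list <- lapply(st$cohorts, function(co) {
  expr <- run_qc(co$probes, co$probe_map)
  meta <- co$metadata
  median_fold_change(expr, meta$sample_id[meta$group == "case"],
                     meta$sample_id[meta$group == "control"])
})
ft <- frequency_table(fc_list)
cand <- select_candidates(ft)
cat("Candidate pool (>= 8 of 20 datasets):", length(cand), "genes\n")

panel <- select_panel(ft, st$design$viral_ids, st$design$bacterial_ids)
print(panel)
cat("\nRecovered", length(intersect(panel$vrg, st$truth$vrg)), "of 10 planted VRGs and",
    length(intersect(panel$brg, st$truth$brg)), "of 10 planted BRGs\n")

write_panel(panel, "results/03_panel.json")
write.table(panel$provenance, "results/03_panel_provenance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
freq <- as.data.frame(ft)
freq <- freq[order(-freq$n_significant), ]
write.table(head(freq, 80), "results/03_frequency_top80.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Wrote results/03_panel.json, 03_panel_provenance.tsv, 03_frequency_top80.tsv\n")
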