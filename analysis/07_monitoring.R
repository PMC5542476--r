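#!/usr/bin/env Rscript

# Step 7 — longitudinal health monitoring with the 20-gene panel.
#
# Simulates ~400 days of biweekly panel expression for one subject with two
# strong respiratory-infection events and one weak sub-threshold event,
# builds the fold-versus-healthy-baseline profile, and flags timepoints
# where at least 3 genes of either panel exceed 2-fold induction. The two
# strong events should be flagged; the weak one should not.

library(bloodsig)

MASTER_SEED <- 42
dir.create("results", showWarnings = FALSE)

lg <- generate_longitudinal(seed = MASTER_SEED)
profile <- build_profile(lg$series, lg$panel, lg$healthy_timepoints,
                         subject_id = "subject01")
print(profile)

flags <- flag_events(profile)
cat("\nFlagged timepoints:",
    paste(flags$timepoint[flags$flagged], collapse = ", "), "\n")
for (ev in lg$truth$events) {
  cat(sprintf("Planted %s event (fold %.1f) at day(s) %s -> %s\n",
              ev$panel, ev$fold, paste(ev$timepoints, collapse = ","),
              if (any(ev$timepoints %in% flags$timepoint[flags$flagged]))
                "flagged" else "not flagged"))
}

write.table(flags, "results/07_event_flags.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
long <- data.frame(gene = rep(rownames(profile$fold), ncol(profile$fold)),
                   timepoint = rep(profile$timepoints,
                                   each = nrow(profile$fold)),
                   fold = as.vector(profile$fold))
write.table(long, "results/07_profile_long.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Wrote results/07_event_flags.tsv, 07_profile_long.tsv\n")
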