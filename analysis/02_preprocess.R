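#!/usr/bin/env Rscript
# Stage 2: gains, group-level Tukey fences, participant exclusion.
#
# Reads the cohort written by stage 1, computes per-trial gains
# (target/self-motion for move-to-target, adjusted/self-motion for
# adjust-target), flags outliers per task x direction x speed x distance
# cell at Q1 - 1.5 IQR / Q3 + 1.5 IQR pooling across participants, and
# drops participants with more than a quarter of a task's trials flagged.

library(odoleak)

dataset <- read_trials("results/synthetic_trials.csv")
pre <- preprocess(dataset)

write_trials(pre$dataset, "results/trials_preprocessed.csv")
utils::write.csv(pre$report$by_cell, "results/outlier_fences_by_cell.csv",
                 row.names = FALSE)
utils::write.csv(pre$report$by_participant,
                 "results/outlier_counts_by_participant.csv",
                 row.names = FALSE)

n_flag <- sum(pre$dataset$trials$flagged_outlier)
cat("flagged", n_flag, "of", nrow(dataset$trials), "trials (",
    round(100 * n_flag / nrow(dataset$trials), 2), "% )\n")
cat("participants excluded:", nrow(pre$dataset$exclusion_log), "\n")
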