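#!/usr/bin/env Rscript
# Stage 2 — probe quality filtering and control matching. Reproduces the
# standard exclusion cascade (failed detections, sex chromosomes,
# SNP-affected and cross-reactive probes, boundary betas, top 1% most
# variable) and selects 2 age/sex/batch-matched controls per case from
# the 64-control pool.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))

ref <- load_reference()

write_report(ref$filtered$report, file.path(RESULTS, "filter_report.json"))
utils::write.table(data.frame(control_id = ref$ctrl_ids),
                   file.path(RESULTS, "matched_controls.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("Filter cascade:\n")
print(as.data.frame(ref$filtered$report), row.names = FALSE)
cat(sprintf("\nMatched %d controls to %d cases (ratio %d).\n",
            length(ref$ctrl_ids), nrow(ref$cases), ref$cfg$match_ratio))
surv <- mean(ref$study$truth$planted %in% rownames(ref$filtered$beta))
cat(sprintf("Planted probes surviving the cascade: %.1f%%.\n", 100 * surv))
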