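#!/usr/bin/env Rscript
# Stage 5 — cross-cohort comparative epigenomics: per-cohort top-500 DMP
# sets (index episignature vs the two other-disorder cohorts, each
# contrasted against the same matched controls), the asymmetric DMP
# overlap matrix, global mean methylation differences, and the
# average-linkage cohort tree.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))

ref <- load_reference()

cohort_dmps <- function(label, name) {
  sh <- as.data.frame(ref$study$sheet)
  keep <- sh$cohort_label %in% c(label, "control") &
    (sh$cohort_label != "control" | sh$sample_id %in% ref$ctrl_ids)
  sh <- sh[keep, ]
  sh$cohort_label[sh$cohort_label == label] <- "case"
  sh <- sample_sheet(sh)
  bb <- beta_matrix(unclass(ref$filtered$beta)[, sh$sample_id, drop = FALSE])
  mm <- m_matrix(unclass(ref$m)[, sh$sample_id, drop = FALSE])
  top_n_dmps(run_dmp(bb, mm, sh, ref$cfg), ref$cfg$top_n_dmps, name,
             sig_alpha = ref$cfg$dmp_sig_alpha)
}

sigs <- list(cohort_dmps("case", "index"),
             cohort_dmps("other_disorder:nd01", "nd01"),
             cohort_dmps("other_disorder:nd02", "nd02"))

ov <- overlap_matrix(sigs)
utils::write.table(data.frame(cohort = rownames(ov), ov),
                   file.path(RESULTS, "dmp_overlap_matrix.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("Top-500 DMP overlap (% of row cohort's DMPs shared with column):\n")
print(round(ov, 1))

gmd <- sapply(sigs, global_mean_diff)
cat(sprintf("\nGlobal mean methylation differences: index %.4f, nd01 %.4f, nd02 %.4f\n",
            gmd[1], gmd[2], gmd[3]))
cat(sprintf("Index cohort is predominantly hypomethylated: %s.\n", gmd[1] < 0))

tr <- cohort_tree(sigs)
writeLines(tr$newick, file.path(RESULTS, "cohort_tree.nwk"))
write_report(tr$metadata, file.path(RESULTS, "cohort_tree_metadata.json"))
cat("Cohort tree:", tr$newick, "\n")
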