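#!/usr/bin/env Rscript
# Stage 4 — train the MVP classifier on the signature probes (positive
# class: the 16 index cases; negative class: 75% of controls plus 75% of
# each other-disorder cohort), evaluate the held-out 25%, and reclassify
# the two VUS stand-ins.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))

ref <- load_reference()
sig <- discovery_signature(ref)
model <- train_mvp_model(ref$m, ref$study$sheet, sig, ref$cfg)

write_report(list(probes = model$probes, platt = model$platt,
                  weights = unname(model$w), bias = model$b,
                  composition = model$composition),
             file.path(RESULTS, "mvp_model.json"))

score_ids <- c(ref$cases$sample_id, model$composition$heldout_negatives)
sc <- score_samples(model, m_matrix(unclass(ref$m)[, score_ids, drop = FALSE]))
utils::write.table(sc, file.path(RESULTS, "mvp_scores.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Training cases: MVP in [%.3f, %.3f] (all called positive: %s).\n",
            min(sc$mvp[1:16]), max(sc$mvp[1:16]),
            all(sc$call[1:16] == "positive")))
held <- sc[-(1:16), ]
cat(sprintf("Held-out negatives (n = %d): %.0f%% score <= 0.1; max MVP %.3f.\n",
            nrow(held), 100 * mean(held$mvp <= 0.1), max(held$mvp)))

vus <- reclassify_vus(model, ref$m, c("vus_carrier_01", "vus_null_01"))
utils::write.table(vus, file.path(RESULTS, "vus_reclassification.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("VUS reclassification:\n")
print(vus, row.names = FALSE)
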