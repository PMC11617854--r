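#!/usr/bin/env Rscript
# Stage 3 — episignature discovery on the 16 cases vs their 32 matched
# controls: moderated differential methylation, the product/AUC/pruning
# cascade, the unsupervised views (Ward dendrogram, MDS), and
# leave-one-out cross-validation. Reports recovery against the planted
# ground truth.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))

ref <- load_reference()
sig <- discovery_signature(ref)

utils::write.table(sig$probes, file.path(RESULTS, "signature_probes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

planted <- ref$study$truth$planted
tp <- sum(sig$probes$probe_id %in% planted)
cat(sprintf("Signature: %d probes; precision %.3f, recall %.3f vs ground truth.\n",
            nrow(sig$probes), tp / nrow(sig$probes), tp / length(planted)))
cat(sprintf("Hypomethylated signature probes: %d of %d.\n",
            sum(sig$probes$delta_beta < 0), nrow(sig$probes)))

sig_m <- m_matrix(unclass(ref$m)[sig$probes$probe_id, ref$disc_ids,
                                 drop = FALSE])
hc <- ward_cluster(sig_m)
ape::write.tree(ape::as.phylo(hc$samples),
                file.path(RESULTS, "sample_dendrogram.nwk"))
top2 <- stats::cutree(hc$samples, 2)
is_case <- ref$disc_sheet$cohort_label[match(names(top2),
                                             ref$disc_sheet$sample_id)] == "case"
cat(sprintf("Top dendrogram split separates cases from controls: %s.\n",
            length(unique(top2[is_case])) == 1 &&
              length(unique(top2[!is_case])) == 1))

mds <- mds_embed(sig_m)
utils::write.table(data.frame(sample_id = rownames(mds),
                              dim1 = mds[, 1], dim2 = mds[, 2]),
                   file.path(RESULTS, "mds_coordinates.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cv <- loocv(beta_matrix(unclass(ref$filtered$beta)[, ref$disc_ids, drop = FALSE]),
            m_matrix(unclass(ref$m)[, ref$disc_ids, drop = FALSE]),
            ref$disc_sheet, ref$cfg)
write_report(cv, file.path(RESULTS, "loocv.json"))
cat(sprintf("LOOCV: %d rounds; %d/%d held-out cases clustered with cases; min MVP %.3f.\n",
            nrow(cv), sum(cv$cluster == "case", na.rm = TRUE), nrow(cv),
            min(cv$mvp, na.rm = TRUE)))
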