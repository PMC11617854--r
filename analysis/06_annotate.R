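#!/usr/bin/env Rscript
# Stage 6 — genomic-context annotation and DMR calling. Synthetic CGI
# and gene tracks are generated alongside the manifest (the real study
# uses hg19 annotation tracks; here the tracks are simulated on the same
# coordinate system so the category logic and the enrichment test run
# end to end). DMPs are the signature probes; the background is all
# analysed probes.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))

ref <- load_reference()
sig <- discovery_signature(ref)
mani <- ref$manifest

# synthetic annotation tracks on the manifest's coordinate span: CGIs of
# 0.5-2 kb placed uniformly per chromosome, genes of 10-100 kb
set.seed(SEED + 10L)
make_tracks <- function(manifest) {
  cg <- list(); gn <- list()
  for (ch in unique(manifest$chrom)) {
    span <- range(manifest$pos[manifest$chrom == ch])
    n_cgi <- max(3L, round(diff(span) / 50000))
    s <- sort(sample(seq(span[1], span[2]), n_cgi))
    cg[[ch]] <- data.frame(chrom = ch, start = s,
                           end = s + sample(500:2000, n_cgi, TRUE))
    n_gene <- max(2L, round(diff(span) / 150000))
    gs <- sort(sample(seq(span[1], span[2]), n_gene))
    gn[[ch]] <- data.frame(chrom = ch, start = gs,
                           end = gs + sample(10000:100000, n_gene, TRUE),
                           name = paste0(ch, "_g", seq_len(n_gene)),
                           strand = sample(c("+", "-"), n_gene, TRUE))
  }
  list(cgis = genomic_intervals(do.call(rbind, cg)),
       genes = genomic_intervals(do.call(rbind, gn)))
}
tracks <- make_tracks(mani)

keep <- mani$probe_id %in% rownames(ref$filtered$beta)
bg_mani <- probe_manifest(as.data.frame(mani[keep, ]))
cgi_cat <- annotate_cgi(bg_mani, tracks$cgis)
gene_cat <- annotate_genes(bg_mani, tracks$genes)
is_dmp <- bg_mani$probe_id %in% sig$probes$probe_id

enr <- list(
  cgi = enrichment_chisq(table(cgi_cat[is_dmp]),
                         prop.table(table(cgi_cat))),
  genes = enrichment_chisq(table(gene_cat[is_dmp]),
                           prop.table(table(gene_cat))))
write_report(enr, file.path(RESULTS, "annotation_enrichment.json"))

cat("Signature-probe CGI context (%):\n")
print(round(100 * prop.table(table(cgi_cat[is_dmp])), 1))
cat(sprintf("CGI chi-squared = %.2f (df %d), p = %.3g\n",
            enr$cgi$statistic, enr$cgi$df, enr$cgi$p_value))
cat("Gene context (%):\n")
print(round(100 * prop.table(table(gene_cat[is_dmp])), 1))
cat(sprintf("Gene chi-squared = %.2f (df %d), p = %.3g\n",
            enr$genes$statistic, enr$genes$df, enr$genes$p_value))

# DMRs: runs of >= 5 consecutive significant probes within 1 kb
dmps <- run_dmp(beta_matrix(unclass(ref$filtered$beta)[, ref$disc_ids, drop = FALSE]),
                m_matrix(unclass(ref$m)[, ref$disc_ids, drop = FALSE]),
                ref$disc_sheet, ref$cfg)
sig_flag <- dmps$p_adjusted < ref$cfg$dmp_sig_alpha
dmrs <- call_dmrs(bg_mani, sig_flag, ref$cfg)
write_dmrs_bed(dmrs, file.path(RESULTS, "dmrs.bed"))
cat(sprintf("\nSignificant probes (BH < %.2f): %d; DMRs called: %d.\n",
            ref$cfg$dmp_sig_alpha, sum(sig_flag), nrow(dmrs)))
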