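test_that("CGI categories follow the shore/shelf distance bands", {
  # one CGI at [10000, 11000) (0-based half-open)
  cgi <- genomic_intervals(data.frame(chrom = "chr1", start = 10000,
                                      end = 11000))
  probes <- tiny_manifest(sprintf("cg%d", 1:5), chrom = "chr1",
                          pos = c(10500,          # inside -> island
                                  11000 + 1500,   # 1.5 kb away -> shore
                                  11000 + 3000,   # 3 kb -> shelf
                                  11000 + 10000,  # 10 kb -> inter-CGI
                                  10001 - 2000))  # 2 kb upstream edge -> shore
  cat <- annotate_cgi(probes, cgi)
  expect_equal(as.character(cat),
               c("island", "shore", "shelf", "inter_cgi", "shore"))
})

test_that("a probe between two CGIs gets one category by precedence", {
  cgis <- genomic_intervals(data.frame(chrom = "chr1",
                                       start = c(1000, 5000),
                                       end = c(2000, 6000)))
  # 1 kb from both edges: shore, counted once
  p <- tiny_manifest("cg1", chrom = "chr1", pos = 3000)
  expect_equal(as.character(annotate_cgi(p, cgis)), "shore")
  # category assignment partitions the probe set
  set.seed(24)
  many <- tiny_manifest(sprintf("cg%03d", 1:200), chrom = "chr1",
                        pos = sort(sample(1:50000, 200)))
  cat <- annotate_cgi(many, cgis)
  expect_equal(sum(table(cat)), 200)
  expect_false(any(is.na(cat)))
})

test_that("gene categories are strand-aware with stated precedence", {
  genes <- genomic_intervals(data.frame(
    chrom = "chr1", start = 20000, end = 30000, name = "g1", strand = "+"))
  probes <- tiny_manifest(sprintf("cg%d", 1:5), chrom = "chr1",
                          pos = c(20001 - 500,    # 500 bp upstream -> promoter
                                  20001 - 3000,   # 3 kb upstream -> promoter+
                                  25000,          # inside -> gene body
                                  120000,         # far away -> intergenic
                                  20001 - 1000))  # 1 kb boundary -> promoter
  cat <- annotate_genes(probes, genes)
  expect_equal(as.character(cat),
               c("promoter", "promoter_plus", "gene_body", "intergenic",
                 "promoter"))
  # minus strand: promoter is downstream in coordinates
  genes_m <- genomic_intervals(data.frame(
    chrom = "chr1", start = 20000, end = 30000, name = "g1", strand = "-"))
  p_m <- tiny_manifest("cg1", chrom = "chr1", pos = 30000 + 500)
  expect_equal(as.character(annotate_genes(p_m, genes_m)), "promoter")
  genes_ns <- genomic_intervals(data.frame(
    chrom = "chr1", start = 20000, end = 30000, name = "g1", strand = "."))
  expect_error(annotate_genes(probes, genes_ns), "strand")
})

test_that("chi-squared enrichment equals the textbook statistic", {
  r0 <- enrichment_chisq(c(25, 25, 25, 25), rep(0.25, 4))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  r <- enrichment_chisq(c(30, 20, 25, 25), rep(0.25, 4))
  expect_equal(r$statistic, 2.0, tolerance = 1e-12)
  expect_equal(r$df, 3)
  expect_equal(r$p_value, pchisq(2, 3, lower.tail = FALSE), tolerance = 1e-12)
  # matches stats::chisq.test on an arbitrary fixture
  obs <- c(12, 40, 8, 25)
  pr <- c(0.1, 0.4, 0.15, 0.35)
  r2 <- enrichment_chisq(obs, pr)
  ct <- suppressWarnings(chisq.test(obs, p = pr))
  expect_equal(r2$statistic, unname(ct$statistic), tolerance = 1e-12)
  expect_equal(r2$p_value, ct$p.value, tolerance = 1e-12)
  expect_error(enrichment_chisq(c(5, 5), c(1, 0)), "merge")
})

test_that("DMR calling matches the fixture walk-throughs", {
  cfg <- episig_config()
  m1 <- tiny_manifest(sprintf("cg%d", 1:5), chrom = "chr1",
                      pos = c(100, 200, 300, 400, 500))
  d1 <- call_dmrs(m1, rep(TRUE, 5), cfg)
  expect_equal(nrow(d1), 1)
  expect_equal(d1$end - d1$start - 1, 400)   # first-to-last span
  expect_equal(d1$n_probes, 5)
  # 5 significant probes spanning 1.5 kb: no DMR under the span rule
  m2 <- tiny_manifest(sprintf("cg%d", 1:5), chrom = "chr1",
                      pos = c(100, 400, 800, 1200, 1600))
  expect_equal(nrow(call_dmrs(m2, rep(TRUE, 5), cfg)), 0)
  # a non-significant probe inside the run breaks consecutiveness
  m3 <- tiny_manifest(sprintf("cg%d", 1:7), chrom = "chr1",
                      pos = c(100, 200, 300, 350, 400, 500, 600))
  sig3 <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  expect_equal(nrow(call_dmrs(m3, sig3, cfg)), 0)
})

test_that("DMR output is sorted, non-overlapping, order-invariant", {
  set.seed(25)
  mani <- tiny_manifest(sprintf("cg%02d", 1:30), chrom = rep(c("chr1", "chr2"), 15),
                        pos = rep(seq(100, by = 150, length.out = 15), each = 2))
  sig <- runif(30) < 0.7
  cfg <- episig_config(dmr_min_probes = 3)
  d <- call_dmrs(mani, sig, cfg)
  perm <- sample(30)
  d2 <- call_dmrs(mani[perm, ], sig[perm], cfg)
  expect_equal(d, d2, ignore_attr = TRUE)
  if (nrow(d) > 1) {
    by_chr <- split(d, d$chrom)
    for (x in by_chr)
      if (nrow(x) > 1) expect_true(all(x$start[-1] >= x$end[-nrow(x)]))
  }
})

test_that("the gap rule accepts long runs with tight spacing", {
  # 6 probes, gaps of 300 bp: span 1.5 kb fails the span rule but every
  # gap is within 1 kb, so the gap rule calls one region
  mani <- tiny_manifest(sprintf("cg%d", 1:6), chrom = "chr1",
                        pos = seq(100, by = 300, length.out = 6))
  span_cfg <- episig_config(dmr_rule = "span")
  gap_cfg <- episig_config(dmr_rule = "gap")
  expect_equal(nrow(call_dmrs(mani, rep(TRUE, 6), span_cfg)), 0)
  g <- call_dmrs(mani, rep(TRUE, 6), gap_cfg)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_probes, 6)
})

test_that("BED round trip preserves interval semantics", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tcgi1", "chr1\t500\t800\tcgi2",
               "chr2\t10\t50\tcgi3"), path)
  iv <- read_bed(path)
  expect_equal(nrow(iv), 3)
  expect_equal(iv$end - iv$start, c(100, 300, 40))
  expect_error(genomic_intervals(data.frame(chrom = "chr1", start = 5,
                                            end = 5)), "malformed")
})
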