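# Genomic-context annotation of probes (CpG-island and gene categories),
# chi-squared enrichment against a background distribution, and DMR
# calling on runs of consecutive significant probes.

#' Read a BED file of intervals
#'
#' Minimal BED reader (>= 3 columns; name in column 4, strand in column
#' 6). Coordinates stay 0-based half-open as on disk.
#'
#' @param path BED file path.
#' @return data.frame `chrom`, `start`, `end`, `name`, `strand`, sorted by
#'   chromosome then start, classed `genomic_intervals`.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#")
  if (ncol(df) < 3) stop("BED needs >= 3 columns", call. = FALSE)
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    name = if (ncol(df) >= 4) as.character(df[[4]]) else
                      NA_character_,
                    strand = if (ncol(df) >= 6) as.character(df[[6]]) else
                      NA_character_,
                    stringsAsFactors = FALSE)
  genomic_intervals(out)
}

#' Validate a set of genomic intervals
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open)
#'   and optionally `name`, `strand`.
#' @return the data.frame sorted per chromosome, classed
#'   `genomic_intervals`.
#' @export
genomic_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (any(df$start >= df$end))
    stop("malformed interval(s): start must be < end", call. = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

probes_gr <- function(manifest) {
  # 1-based probe point -> 0-based half-open single base == IRanges(pos, pos)
  GenomicRanges::GRanges(manifest$chrom,
                         IRanges::IRanges(manifest$pos, manifest$pos))
}

intervals_gr <- function(iv, strand = FALSE) {
  GenomicRanges::GRanges(
    iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end),
    strand = if (strand) iv$strand else "*")
}

#' CpG-island context of each probe
#'
#' island: the probe lies in a CGI; shore: within 2 kb of a CGI edge;
#' shelf: 2-4 kb from an edge; inter_cgi: beyond. Precedence island >
#' shore > shelf when several CGIs compete.
#'
#' @param manifest a `probe_manifest`.
#' @param cgis `genomic_intervals` of CpG islands.
#' @return factor (levels island, shore, shelf, inter_cgi), one per probe.
#' @export
annotate_cgi <- function(manifest, cgis) {
  pr <- probes_gr(manifest)
  cg <- intervals_gr(cgis)
  cat <- rep("inter_cgi", nrow(manifest))
  hit <- GenomicRanges::distanceToNearest(pr, cg)
  idx <- S4Vectors::queryHits(hit)
  d <- S4Vectors::mcols(hit)$distance  # 0 = overlapping or abutting
  ov <- GenomicRanges::countOverlaps(pr, cg) > 0
  # gap of g bases between probe and edge: distance = g - 1 for g >= 1
  cat[idx[d <= 3999]] <- "shelf"
  cat[idx[d <= 1999]] <- "shore"
  cat[ov] <- "island"
  factor(cat, levels = c("island", "shore", "shelf", "inter_cgi"))
}

#' Gene context of each probe
#'
#' promoter: up to 1 kb upstream of a TSS (strand-aware); promoter_plus:
#' 1-5 kb upstream; gene_body: within the gene span (UTRs, exons, introns
#' and their boundaries consolidated); intergenic otherwise. Precedence
#' promoter > promoter_plus > gene_body.
#'
#' @param manifest a `probe_manifest`.
#' @param genes `genomic_intervals` with a strand column (`+`/`-`).
#' @return factor (levels promoter, promoter_plus, gene_body, intergenic).
#' @export
annotate_genes <- function(manifest, genes) {
  if (is.null(genes$strand) || any(is.na(genes$strand)) ||
      !all(genes$strand %in% c("+", "-")))
    stop("gene intervals must carry strand (+/-)", call. = FALSE)
  pr <- probes_gr(manifest)
  body <- intervals_gr(genes)
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$start + 1L, genes$end)  # 1-based TSS
  prom <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(ifelse(plus, pmax(tss - 1000L, 1L), tss + 1L),
                     ifelse(plus, tss - 1L, tss + 1000L)))
  promp <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(ifelse(plus, pmax(tss - 5000L, 1L), tss + 1001L),
                     ifelse(plus, tss - 1001L, tss + 5000L)))
  cat <- rep("intergenic", nrow(manifest))
  cat[GenomicRanges::countOverlaps(pr, body) > 0] <- "gene_body"
  cat[GenomicRanges::countOverlaps(pr, promp) > 0] <- "promoter_plus"
  cat[GenomicRanges::countOverlaps(pr, prom) > 0] <- "promoter"
  factor(cat, levels = c("promoter", "promoter_plus", "gene_body",
                         "intergenic"))
}

#' Chi-squared goodness-of-fit enrichment test
#'
#' Compares observed DMP category counts against expected counts from a
#' background category distribution: `chisq = sum (obs - exp)^2 / exp`,
#' `df = categories - 1`, upper-tail p.
#'
#' @param observed named vector of observed category counts.
#' @param background_props background proportions (same categories, summing
#'   to 1; renormalised).
#' @return list `observed`, `expected`, `statistic`, `df`, `p_value`.
#' @export
enrichment_chisq <- function(observed, background_props) {
  stopifnot(length(observed) == length(background_props))
  observed <- c(observed)             # tables -> plain named vectors
  background_props <- c(background_props)
  p <- background_props / sum(background_props)
  expd <- p * sum(observed)
  if (any(expd <= 0))
    stop("zero expected count; merge sparse categories before testing",
         call. = FALSE)
  stat <- sum((observed - expd)^2 / expd)
  df <- length(observed) - 1
  list(observed = observed, expected = expd, statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Call differentially methylated regions
#'
#' Probes are sorted genomically per chromosome; a DMR is a maximal run of
#' consecutive significant probes (no intervening analysed non-significant
#' probe) of at least `dmr_min_probes` probes whose first-to-last span is
#' at most `dmr_max_span_bp` (the default "span" rule). The "gap" rule
#' instead splits significant runs where an adjacent gap exceeds
#' `dmr_max_span_bp` and applies only the run-length condition.
#'
#' @param manifest `probe_manifest` rows for all analysed probes.
#' @param significant logical vector aligned with `manifest` (caller
#'   defines significance, e.g. adjusted p below a cutoff).
#' @param cfg an [episig_config()].
#' @return data.frame `chrom`, `start` (0-based), `end`, `n_probes` (BED
#'   convention), possibly empty; regions never overlap.
#' @export
call_dmrs <- function(manifest, significant, cfg = episig_config()) {
  stopifnot(length(significant) == nrow(manifest))
  ord <- order(manifest$chrom, manifest$pos)
  chrom <- manifest$chrom[ord]
  pos <- manifest$pos[ord]
  sig <- significant[ord]
  out <- list()
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    r <- rle(sig[i])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      run_pos <- pos[i[starts[k]:ends[k]]]
      if (cfg$dmr_rule == "span") {
        if (length(run_pos) >= cfg$dmr_min_probes &&
            max(run_pos) - min(run_pos) <= cfg$dmr_max_span_bp)
          out[[length(out) + 1]] <- data.frame(
            chrom = ch, start = min(run_pos) - 1L, end = max(run_pos),
            n_probes = length(run_pos))
      } else {
        splits <- c(0, which(diff(run_pos) > cfg$dmr_max_span_bp),
                    length(run_pos))
        for (s in seq_len(length(splits) - 1)) {
          seg <- run_pos[(splits[s] + 1):splits[s + 1]]
          if (length(seg) >= cfg$dmr_min_probes)
            out[[length(out) + 1]] <- data.frame(
              chrom = ch, start = min(seg) - 1L, end = max(seg),
              n_probes = length(seg))
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Write DMRs as BED
#' @param dmrs output of [call_dmrs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dmrs_bed <- function(dmrs, path) {
  if (nrow(dmrs) == 0) {
    file.create(path)
    return(invisible(path))
  }
  utils::write.table(
    data.frame(dmrs$chrom, dmrs$start, dmrs$end,
               paste0("dmr_", seq_len(nrow(dmrs))), dmrs$n_probes),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
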