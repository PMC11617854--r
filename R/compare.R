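# Cross-cohort comparative epigenomics: per-cohort top-N DMP sets,
# asymmetric overlap percentages, and an average-linkage cohort tree.

#' Build a cohort signature from a DMP table
#'
#' The top `n` probes by ascending p-value (ties by larger |delta beta|,
#' then probe id) with their beta-scale effects — the fixed-size DMP set
#' used for unbiased cross-cohort comparison. `total_dmp_count` is the
#' number of probes significant at `sig_alpha` (adjusted p).
#'
#' @param dmps a `dmp_result`.
#' @param n DMPs to keep (all, when fewer are available).
#' @param name cohort name.
#' @param sig_alpha adjusted-p cutoff for the total DMP count.
#' @return object of class `cohort_signature`: list with `name`,
#'   `dmp_ids`, `effect` (named delta-beta vector), `global_mean_diff`,
#'   `total_dmp_count`.
#' @export
top_n_dmps <- function(dmps, n, name = "cohort", sig_alpha = 0.05) {
  stopifnot(n >= 1)
  ord <- order(dmps$p_value, -abs(dmps$delta_beta), dmps$probe_id)
  take <- ord[seq_len(min(n, nrow(dmps)))]
  eff <- stats::setNames(dmps$delta_beta[take], dmps$probe_id[take])
  structure(list(name = name,
                 dmp_ids = dmps$probe_id[take],
                 effect = eff,
                 global_mean_diff = mean(eff),
                 total_dmp_count = if ("p_adjusted" %in% names(dmps))
                   sum(dmps$p_adjusted < sig_alpha) else NA_integer_),
            class = "cohort_signature")
}

#' Asymmetric DMP overlap matrix
#'
#' Entry (A, B) is the percentage of cohort A's DMPs also present in
#' cohort B's: `100 * |A intersect B| / |A|`. Rows index the reference
#' cohort A (the denominator), columns the compared cohort B; the diagonal
#' is 100. Cohorts with an empty DMP set yield missing entries.
#'
#' @param signatures list of `cohort_signature` objects.
#' @return numeric matrix (cohorts x cohorts) of percentages.
#' @export
overlap_matrix <- function(signatures) {
  stopifnot(length(signatures) >= 2)
  nm <- vapply(signatures, `[[`, "", "name")
  k <- length(signatures)
  out <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    a <- signatures[[i]]$dmp_ids
    if (length(a) == 0) next
    out[i, j] <- 100 * length(intersect(a, signatures[[j]]$dmp_ids)) /
      length(a)
  }
  out
}

#' Global mean methylation difference of a cohort signature
#'
#' Arithmetic mean of the signed delta-beta effects over the cohort's DMP
#' set; negative for predominantly hypomethylated signatures.
#'
#' @param signature a `cohort_signature`.
#' @return signed mean in [-1, 1].
#' @export
global_mean_diff <- function(signature) {
  if (length(signature$effect) == 0)
    stop("empty DMP set", call. = FALSE)
  mean(signature$effect)
}

#' Cohort similarity tree
#'
#' Each cohort is represented by its delta-beta vector over the union of
#' all cohorts' DMP sets (zero where a probe is not among the cohort's
#' DMPs); cohorts are clustered by average-linkage agglomeration on
#' Euclidean distances. Cohorts are sorted by name before clustering so
#' the result is input-order invariant; branch lengths are the merge
#' heights.
#'
#' @param signatures list of >= 3 `cohort_signature` objects.
#' @return list with `phylo` (an [ape::phylo] tree), `newick` (string),
#'   and `metadata` (per-cohort DMP count, total DMP count and global mean
#'   difference).
#' @export
cohort_tree <- function(signatures) {
  stopifnot(length(signatures) >= 3)
  nm <- vapply(signatures, `[[`, "", "name")
  signatures <- signatures[order(nm)]
  nm <- sort(nm)
  union_ids <- sort(unique(unlist(lapply(signatures, `[[`, "dmp_ids"))))
  v <- sapply(signatures, function(s) {
    x <- stats::setNames(numeric(length(union_ids)), union_ids)
    x[s$dmp_ids] <- s$effect
    x
  })
  colnames(v) <- nm
  hc <- stats::hclust(stats::dist(t(v)), method = "average")
  ph <- ape::as.phylo(hc)
  meta <- data.frame(
    cohort = nm,
    n_dmps = vapply(signatures, function(s) length(s$dmp_ids), 1L),
    total_dmp_count = vapply(signatures, function(s)
      as.integer(s$total_dmp_count %||% NA_integer_), 1L),
    global_mean_diff = vapply(signatures, `[[`, 1, "global_mean_diff"),
    stringsAsFactors = FALSE)
  list(phylo = ph, newick = ape::write.tree(ph), metadata = meta)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a
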