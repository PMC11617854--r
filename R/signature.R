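# Multi-stage probe selection: effect x significance product ranking,
# per-probe ROC AUC retention, greedy correlation pruning; plus the
# unsupervised views (Ward clustering, classical MDS) and LOOCV.

#' Rank probes by the effect-significance product
#'
#' Score = `|delta_beta| * (-log10 p)`; descending, ties broken by smaller
#' p then probe id. Returns the top `k` rows (all rows with a warning when
#' `k` exceeds the supply).
#'
#' @param dmps a `dmp_result` (or data.frame with `probe_id`,
#'   `delta_beta`, `p_value`).
#' @param k number of probes to retain.
#' @return data.frame `probe_id`, `delta_beta`, `p_value`,
#'   `product_score`, in rank order.
#' @export
rank_by_product <- function(dmps, k) {
  stopifnot(k >= 1)
  score <- abs(dmps$delta_beta) * (-log10(dmps$p_value))
  ord <- order(-score, dmps$p_value, dmps$probe_id)
  if (k > nrow(dmps)) {
    warning("k = ", k, " exceeds available probes (", nrow(dmps),
            "); returning all")
    k <- nrow(dmps)
  }
  out <- dmps[ord[seq_len(k)], c("probe_id", "delta_beta", "p_value")]
  out$product_score <- score[ord[seq_len(k)]]
  rownames(out) <- NULL
  out
}

#' Per-probe ROC AUC
#'
#' Mann-Whitney formulation: AUC = (concordant pairs + 0.5 ties) /
#' (n_case * n_control), orientation-free (`max(a, 1 - a)` is reported so
#' hypo- and hypermethylated probes score alike).
#'
#' @param values per-sample measurements for one probe.
#' @param is_case logical vector, same length.
#' @return AUC in [0.5, 1].
#' @export
probe_auc <- function(values, is_case) {
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) stop("both classes must be non-empty", call. = FALSE)
  r <- rank(values)
  a <- (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  max(a, 1 - a)
}

# Vectorised over probes (rows of m).
probe_auc_matrix <- function(m, is_case) {
  n1 <- sum(is_case); n0 <- sum(!is_case)
  r <- t(apply(m, 1, rank))
  a <- (rowSums(r[, is_case, drop = FALSE]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pmax(a, 1 - a)
}

#' Greedy correlation pruning
#'
#' Scans candidates in ranking order and keeps a probe iff its absolute
#' Pearson correlation (across samples) with every already-kept probe is
#' at most `r_max` — the strongest member of each correlated clique
#' survives.
#'
#' @param m an `m_matrix` containing (at least) the candidate probes.
#' @param ranking candidate probe ids in rank order.
#' @param r_max correlation threshold.
#' @return retained probe ids (subset of `ranking`, order preserved).
#' @export
prune_correlated <- function(m, ranking, r_max) {
  if (length(ranking) <= 1) return(ranking)
  x <- t(unclass(m)[ranking, , drop = FALSE])
  cc <- abs(suppressWarnings(stats::cor(x)))
  cc[is.na(cc)] <- 0   # zero-variance probes correlate with nothing
  keep <- integer(0)
  for (i in seq_along(ranking)) {
    if (all(cc[i, keep] <= r_max)) keep <- c(keep, i)
  }
  ranking[keep]
}

#' Select an episignature probe set
#'
#' The full selection cascade on preprocessed data: differential
#' methylation fit, product ranking (top `product_rank_k`), AUC retention
#' (`auc >= auc_min`, computed on M-values), greedy correlation pruning at
#' `corr_prune_r`. Pruning correlations are computed across the control
#' samples only: pruning exists to remove co-methylation redundancy
#' between probes, and including the cases would let the disease effect
#' itself correlate every true signature probe with every other.
#' Deterministic for fixed input and config.
#'
#' @param beta filtered `beta_matrix`.
#' @param m matching `m_matrix`.
#' @param sheet a `sample_sheet` (case/control rows are used).
#' @param cfg an [episig_config()].
#' @return object of class `signature_set`: list with `probes` (data.frame
#'   `probe_id`, `delta_beta`, `p_value`, `auc`, in rank order), `config`,
#'   and a `cohort_hash` provenance string.
#' @export
select_signature <- function(beta, m, sheet, cfg = episig_config()) {
  dmps <- run_dmp(beta, m, sheet, cfg)
  cand <- rank_by_product(dmps, min(cfg$product_rank_k, nrow(dmps)))
  used <- sheet$cohort_label %in% c("case", "control")
  ids_used <- sheet$sample_id[used]
  is_case <- sheet$cohort_label[used] == "case"
  sub <- unclass(m)[cand$probe_id, ids_used, drop = FALSE]
  cand$auc <- probe_auc_matrix(sub, is_case)
  cand <- cand[cand$auc >= cfg$auc_min, , drop = FALSE]
  ctrl_m <- m_matrix(sub[, !is_case, drop = FALSE])
  kept <- prune_correlated(ctrl_m, cand$probe_id, cfg$corr_prune_r)
  probes <- cand[match(kept, cand$probe_id),
                 c("probe_id", "delta_beta", "p_value", "auc")]
  rownames(probes) <- NULL
  if (nrow(probes) == 0)
    stop("empty signature: relax auc_min / corr_prune_r / product_rank_k",
         call. = FALSE)
  structure(list(probes = probes, config = cfg,
                 cohort_hash = cohort_hash(ids_used, is_case)),
            class = "signature_set")
}

cohort_hash <- function(ids, is_case) {
  paste0("n_case=", sum(is_case), ";n_ctrl=", sum(!is_case), ";ids=",
         format(sum(utf8ToInt(paste(ids, collapse = "|"))), scientific = FALSE))
}

#' Ward hierarchical clustering of samples (and probes)
#'
#' Agglomerative clustering with Ward's criterion on Euclidean distances
#' (`hclust` method `ward.D2`, i.e. on the distances themselves), the
#' standard two-way ordering behind episignature heatmaps.
#'
#' @param m an `m_matrix` restricted to the signature probes.
#' @return list with `samples` and `probes` (`hclust` objects; `probes`
#'   is NULL for a single-probe signature).
#' @export
ward_cluster <- function(m) {
  x <- unclass(m)
  stopifnot(ncol(x) >= 2)
  list(samples = stats::hclust(stats::dist(t(x)), method = "ward.D2"),
       probes = if (nrow(x) >= 2)
         stats::hclust(stats::dist(x), method = "ward.D2") else NULL)
}

#' Classical multidimensional scaling of samples
#'
#' Torgerson MDS of the pairwise Euclidean distance matrix, centred.
#' Orientation convention: each axis is flipped so the coordinate of
#' largest magnitude on that axis is positive.
#'
#' @param m an `m_matrix` restricted to the signature probes.
#' @param dims embedding dimension (default 2).
#' @return matrix (samples x dims) of coordinates.
#' @export
mds_embed <- function(m, dims = 2) {
  x <- t(unclass(m))
  stopifnot(nrow(x) >= 3)
  d <- stats::dist(x)
  if (all(d < 1e-12))
    return(matrix(0, nrow(x), dims, dimnames = list(rownames(x), NULL)))
  y <- stats::cmdscale(d, k = dims)
  if (ncol(y) < dims)  # degenerate rank: pad with zero coordinates
    y <- cbind(y, matrix(0, nrow(y), dims - ncol(y)))
  for (j in seq_len(ncol(y))) {
    i <- which.max(abs(y[, j]))
    if (y[i, j] < 0) y[, j] <- -y[, j]
  }
  y
}

#' Leave-one-out cross-validation of the episignature
#'
#' One round per case sample: the held-out case is removed, the signature
#' is re-selected and the classifier re-trained on the remainder, and the
#' held-out sample is (a) assigned to the nearer of the case/control
#' centroids in signature M-space and (b) scored by the refit MVP model.
#' Round failures are recorded, not fatal.
#'
#' @param beta filtered `beta_matrix` over all samples.
#' @param m matching `m_matrix`.
#' @param sheet a `sample_sheet` (cases, controls, optionally
#'   other-disorder samples for classifier training).
#' @param cfg an [episig_config()].
#' @return data.frame with one row per case: `sample_id`, `cluster`
#'   (`"case"`/`"control"`), `mvp`, `n_signature_probes`, `error`
#'   (NA when the round succeeded).
#' @export
loocv <- function(beta, m, sheet, cfg = episig_config()) {
  case_ids <- sheet$sample_id[sheet$cohort_label == "case"]
  if (length(case_ids) < 3) stop("need >= 3 cases for LOOCV", call. = FALSE)
  rounds <- lapply(case_ids, function(held) {
    out <- data.frame(sample_id = held, cluster = NA_character_,
                      mvp = NA_real_, n_signature_probes = NA_integer_,
                      error = NA_character_, stringsAsFactors = FALSE)
    tryCatch({
      tr_sheet <- sheet[sheet$sample_id != held, , drop = FALSE]
      tr_beta <- beta_matrix(unclass(beta)[, tr_sheet$sample_id, drop = FALSE])
      tr_m <- m_matrix(unclass(m)[, tr_sheet$sample_id, drop = FALSE])
      sig <- select_signature(tr_beta, tr_m, tr_sheet, cfg)
      probes <- sig$probes$probe_id
      tr_case <- tr_sheet$sample_id[tr_sheet$cohort_label == "case"]
      tr_ctrl <- tr_sheet$sample_id[tr_sheet$cohort_label == "control"]
      cen_case <- rowMeans(unclass(m)[probes, tr_case, drop = FALSE])
      cen_ctrl <- rowMeans(unclass(m)[probes, tr_ctrl, drop = FALSE])
      v <- unclass(m)[probes, held]
      out$cluster <- if (sum((v - cen_case)^2) <= sum((v - cen_ctrl)^2))
        "case" else "control"
      model <- train_mvp_model(tr_m, tr_sheet, sig, cfg)
      out$mvp <- score_samples(model,
                               m_matrix(unclass(m)[probes, held,
                                                   drop = FALSE]))$mvp
      out$n_signature_probes <- length(probes)
      out
    }, error = function(e) {
      out$error <- conditionMessage(e)
      out
    })
  })
  do.call(rbind, rounds)
}
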