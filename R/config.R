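#' Analysis configuration
#'
#' Collects every tunable of the pipeline in one validated object. Defaults
#' follow the published episignature workflow where the workflow states a
#' value (detection p cutoff 0.1, top 1\% most variable probes, 75\% training
#' fraction, top 500 DMPs per cohort, DMRs of >= 5 probes within 1 kb) and
#' documented package choices elsewhere (see the methods vignette).
#'
#' @param detection_p_max detection p-value above which a probe measurement
#'   is considered failed; a probe failing in any sample is excluded.
#' @param beta_clip_eps beta values within this distance of 0 or 1 are
#'   treated as boundary values (probe excluded); also the clipping bound of
#'   the logit transform.
#' @param top_variable_fraction fraction of (remaining) probes removed as
#'   most variable (by across-sample SD), ceiling rule.
#' @param match_ratio controls selected per case by greedy matching.
#' @param match_weight_sex,match_weight_batch unit penalties added to the
#'   matching distance on sex / batch mismatch.
#' @param product_rank_k number of probes retained by the
#'   effect-significance product ranking stage.
#' @param auc_min minimum per-probe ROC AUC retained.
#' @param corr_prune_r maximum absolute pairwise Pearson correlation allowed
#'   between retained probes (greedy prune in rank order).
#' @param svm_C linear SVM cost.
#' @param train_fraction fraction of controls (and of each other-disorder
#'   cohort) drawn into the SVM training set.
#' @param mvp_threshold MVP score at or above which a sample is called
#'   signature-positive.
#' @param top_n_dmps DMPs per cohort (smallest p) used for cross-cohort
#'   comparison.
#' @param dmp_sig_alpha adjusted-p cutoff defining a significant DMP (DMR
#'   calling, total DMP counts).
#' @param dmr_min_probes minimum run of consecutive significant probes.
#' @param dmr_max_span_bp maximum first-to-last span of the run ("span"
#'   rule) or maximum adjacent gap ("gap" rule).
#' @param dmr_rule "span" (default, stricter) or "gap".
#' @param p_adjust_method multiplicity correction, see [stats::p.adjust()].
#' @param moderate logical; FALSE disables empirical-Bayes moderation
#'   (ordinary t-statistics are used), for oracle comparisons.
#' @param rng_seed integer seed used by every stochastic step.
#'
#' @return An object of class `episig_config` (a validated named list).
#' @export
episig_config <- function(detection_p_max = 0.1,
                          beta_clip_eps = 1e-6,
                          top_variable_fraction = 0.01,
                          match_ratio = 2,
                          match_weight_sex = 1,
                          match_weight_batch = 1,
                          product_rank_k = 1000,
                          auc_min = 0.75,
                          corr_prune_r = 0.85,
                          svm_C = 1.0,
                          train_fraction = 0.75,
                          mvp_threshold = 0.5,
                          top_n_dmps = 500,
                          dmp_sig_alpha = 0.05,
                          dmr_min_probes = 5,
                          dmr_max_span_bp = 1000,
                          dmr_rule = c("span", "gap"),
                          p_adjust_method = "BH",
                          moderate = TRUE,
                          rng_seed = 1L) {
  cfg <- list(
    detection_p_max = detection_p_max,
    beta_clip_eps = beta_clip_eps,
    top_variable_fraction = top_variable_fraction,
    match_ratio = as.integer(match_ratio),
    match_weight_sex = match_weight_sex,
    match_weight_batch = match_weight_batch,
    product_rank_k = as.integer(product_rank_k),
    auc_min = auc_min,
    corr_prune_r = corr_prune_r,
    svm_C = svm_C,
    train_fraction = train_fraction,
    mvp_threshold = mvp_threshold,
    top_n_dmps = as.integer(top_n_dmps),
    dmp_sig_alpha = dmp_sig_alpha,
    dmr_min_probes = as.integer(dmr_min_probes),
    dmr_max_span_bp = dmr_max_span_bp,
    dmr_rule = match.arg(dmr_rule),
    p_adjust_method = p_adjust_method,
    moderate = isTRUE(moderate),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "episig_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "episig_config"))
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg, call. = FALSE)
  chk(cfg$detection_p_max > 0 && cfg$detection_p_max <= 1,
      "detection_p_max must be in (0, 1]")
  chk(cfg$beta_clip_eps > 0 && cfg$beta_clip_eps < 0.5,
      "beta_clip_eps must be in (0, 0.5)")
  chk(cfg$top_variable_fraction >= 0 && cfg$top_variable_fraction < 1,
      "top_variable_fraction must be in [0, 1)")
  chk(cfg$match_ratio >= 1, "match_ratio must be >= 1")
  chk(cfg$product_rank_k >= 1, "product_rank_k must be >= 1")
  chk(cfg$auc_min >= 0.5 && cfg$auc_min <= 1, "auc_min must be in [0.5, 1]")
  chk(cfg$corr_prune_r > 0 && cfg$corr_prune_r <= 1,
      "corr_prune_r must be in (0, 1]")
  chk(cfg$svm_C > 0, "svm_C must be positive")
  chk(cfg$train_fraction > 0 && cfg$train_fraction <= 1,
      "train_fraction must be in (0, 1]")
  chk(cfg$mvp_threshold >= 0 && cfg$mvp_threshold <= 1,
      "mvp_threshold must be in [0, 1]")
  chk(cfg$top_n_dmps >= 1, "top_n_dmps must be >= 1")
  chk(cfg$dmp_sig_alpha > 0 && cfg$dmp_sig_alpha <= 1,
      "dmp_sig_alpha must be in (0, 1]")
  chk(cfg$dmr_min_probes >= 2, "dmr_min_probes must be >= 2")
  chk(cfg$dmr_max_span_bp > 0, "dmr_max_span_bp must be positive")
  chk(cfg$p_adjust_method %in% stats::p.adjust.methods,
      "unknown p_adjust_method")
  invisible(cfg)
}

#' Read / write an analysis configuration as YAML
#'
#' The round trip is lossless: every field of [episig_config()] is written
#' as a flat key-value document and restored with identical values.
#'
#' @param path file path.
#' @param cfg an `episig_config`.
#' @return `read_config()` returns an `episig_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(episig_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
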