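#' Probe quality filter cascade
#'
#' Applies, in this fixed order, the standard exclusion cascade of blood
#' episignature studies: (1) probes with a failed detection (detection
#' p > `detection_p_max`, or a missing beta, in any sample); (2) probes on
#' chrX/chrY; (3) SNP-affected probes; (4) cross-reactive probes;
#' (5) probes with any beta at the 0/1 boundary (within `beta_clip_eps`,
#' where the logit is infinite); (6) the top `top_variable_fraction` of the
#' remaining probes ranked by across-sample standard deviation (ceiling
#' count, ties broken by probe id).
#'
#' @param beta a `beta_matrix`.
#' @param detp detection-p matrix of the same shape, or `NULL`.
#' @param manifest a `probe_manifest` covering all probes in `beta`.
#' @param cfg an [episig_config()].
#' @return list with `beta` (filtered, complete — no missing values) and
#'   `report`, a `filter_report` data.frame of
#'   (criterion, removed, remaining) rows.
#' @export
filter_probes <- function(beta, detp = NULL, manifest, cfg = episig_config()) {
  stopifnot(inherits(beta, "beta_matrix"), inherits(manifest, "probe_manifest"))
  if (!all(rownames(beta) %in% manifest$probe_id))
    stop("beta matrix contains probes absent from the manifest", call. = FALSE)
  if (!is.null(detp) && !identical(dim(detp), dim(unclass(beta))))
    stop("detection-p matrix shape differs from beta matrix", call. = FALSE)
  mani <- manifest[match(rownames(beta), manifest$probe_id), ]
  steps <- character(0); removed <- integer(0); remaining <- integer(0)
  drop_step <- function(name, bad) {
    steps <<- c(steps, name)
    removed <<- c(removed, sum(bad))
    beta <<- beta[!bad, , drop = FALSE]
    mani <<- mani[!bad, , drop = FALSE]
    if (!is.null(detp)) detp <<- detp[!bad, , drop = FALSE]
    remaining <<- c(remaining, nrow(beta))
  }
  fail <- if (is.null(detp)) rep(FALSE, nrow(beta)) else
    apply(detp > cfg$detection_p_max, 1, any)
  drop_step("detection_p", fail | apply(is.na(beta), 1, any))
  drop_step("sex_chromosomes", mani$chrom %in% c("chrX", "chrY"))
  drop_step("snp_affected", mani$snp_affected)
  drop_step("cross_reactive", mani$cross_reactive)
  eps <- cfg$beta_clip_eps
  drop_step("boundary_beta",
            apply(beta <= eps | beta >= 1 - eps, 1, any))
  n_var <- ceiling(cfg$top_variable_fraction * nrow(beta))
  if (n_var > 0 && nrow(beta) > 0) {
    sds <- apply(beta, 1, stats::sd)
    ord <- order(-sds, rownames(beta))
    bad <- rownames(beta) %in% rownames(beta)[ord[seq_len(n_var)]]
  } else bad <- rep(FALSE, nrow(beta))
  drop_step("top_variable", bad)
  if (nrow(beta) == 0)
    stop("no probes remain after filtering", call. = FALSE)
  report <- data.frame(criterion = steps, removed = removed,
                       remaining = remaining, stringsAsFactors = FALSE)
  class(report) <- c("filter_report", "data.frame")
  list(beta = beta_matrix(unclass(beta)), report = report)
}

#' Greedy nearest-neighbour control matching
#'
#' For each case, in input order, selects `match_ratio` controls from the
#' pool (without replacement) minimising
#' `|age difference| / pool age range + w_sex * sex mismatch +
#' w_batch * batch mismatch`; ties are broken by preferring sex
#' concordance, then pool order. This plays the
#' role of the age/sex/array matching step of the reference workflow; the
#' weights are package choices (the workflow delegates to a matching
#' package without stating them) and are config-exposed.
#'
#' @param cases `sample_sheet` rows for the cases.
#' @param pool `sample_sheet` rows for candidate controls.
#' @param cfg an [episig_config()].
#' @return character vector of exactly `match_ratio * nrow(cases)` control
#'   sample ids (no duplicates).
#' @export
match_controls <- function(cases, pool, cfg = episig_config()) {
  r <- cfg$match_ratio
  if (nrow(pool) < r * nrow(cases))
    stop(sprintf("control pool too small: need %d, have %d (short by %d)",
                 r * nrow(cases), nrow(pool), r * nrow(cases) - nrow(pool)),
         call. = FALSE)
  age_range <- diff(range(pool$age))
  avail <- rep(TRUE, nrow(pool))
  sel <- character(0)
  for (i in seq_len(nrow(cases))) {
    d <- (if (age_range > 0)
      abs(cases$age[i] - pool$age) / age_range else 0) +
      cfg$match_weight_sex * (cases$sex[i] != pool$sex) +
      cfg$match_weight_batch * (cases$batch[i] != pool$batch)
    d[!avail] <- Inf
    pick <- order(d, cases$sex[i] != pool$sex)[seq_len(r)]
    avail[pick] <- FALSE
    sel <- c(sel, pool$sample_id[pick])
  }
  sel
}

#' Logit (M-value) transform
#'
#' Betas are clipped to `[eps, 1 - eps]` then mapped to
#' `M = log2(beta / (1 - beta))`; strictly increasing and antisymmetric
#' about beta = 0.5.
#'
#' @param beta a `beta_matrix` (complete).
#' @param cfg an [episig_config()] (provides `beta_clip_eps`).
#' @return an `m_matrix`.
#' @export
beta_to_m <- function(beta, cfg = episig_config()) {
  eps <- cfg$beta_clip_eps
  b <- pmin(pmax(unclass(beta), eps), 1 - eps)
  m_matrix(log2(b / (1 - b)))
}
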