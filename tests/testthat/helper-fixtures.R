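# Shared fixture builders. Everything is generated in code; the only
# on-disk fixture is the bundled cohort variant table.

tiny_beta <- function(n_probes = 6, n_samples = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n_probes * n_samples, 0.05, 0.95), n_probes, n_samples,
              dimnames = list(sprintf("cg%06d", seq_len(n_probes)),
                              sprintf("s%02d", seq_len(n_samples))))
  beta_matrix(m)
}

tiny_sheet <- function(labels, sexes = NULL, ages = NULL, batches = NULL) {
  n <- length(labels)
  df <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    cohort_label = labels,
    sex = sexes %||% rep(c("M", "F"), length.out = n),
    age = ages %||% rep(10, n),
    batch = batches %||% rep("b1", n),
    stringsAsFactors = FALSE)
  df[episig:::CELL_FRACTION_COLS] <- rep(1 / 6, 6)
  sample_sheet(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_manifest <- function(probe_ids, chrom = "chr1", pos = NULL,
                          snp = FALSE, cross = FALSE) {
  n <- length(probe_ids)
  probe_manifest(data.frame(
    probe_id = probe_ids,
    chrom = rep(chrom, length.out = n),
    pos = pos %||% seq(1000, by = 1000, length.out = n),
    snp_affected = rep(snp, length.out = n),
    cross_reactive = rep(cross, length.out = n),
    stringsAsFactors = FALSE))
}

# The reference planted-signature study (computed once per test run).
ref_cache <- new.env(parent = emptyenv())

reference_study <- function(seed, other = FALSE) {
  key <- paste0("s", seed, if (other) "_other")
  if (!is.null(ref_cache[[key]])) return(ref_cache[[key]])
  des <- sim_design(
    n_probes = 20000, n_cases = 16, n_controls = 64,
    n_vus_carrier = if (other) 1 else 0, n_vus_null = if (other) 1 else 0,
    other_cohort_sizes = if (other) c(16, 16) else integer(0),
    signature_size = 300, effect_delta = 0.15, hypo_fraction = 0.9,
    rng_seed = seed)
  mani <- generate_manifest(des)
  st <- generate_study(des, mani)
  cfg <- episig_config(rng_seed = seed)
  cases <- st$sheet[st$sheet$cohort_label == "case", ]
  pool <- st$sheet[st$sheet$cohort_label == "control", ]
  ctrl_ids <- match_controls(cases, pool, cfg)
  f <- filter_probes(st$beta, st$detp, mani, cfg)
  m <- beta_to_m(f$beta, cfg)
  disc_ids <- c(cases$sample_id, ctrl_ids)
  disc_sheet <- st$sheet[st$sheet$sample_id %in% disc_ids, ]
  sig <- select_signature(
    beta_matrix(unclass(f$beta)[, disc_ids, drop = FALSE]),
    m_matrix(unclass(m)[, disc_ids, drop = FALSE]), disc_sheet, cfg)
  res <- list(design = des, manifest = mani, study = st, cfg = cfg,
              filtered = f, m = m, disc_ids = disc_ids,
              disc_sheet = disc_sheet, signature = sig)
  ref_cache[[key]] <- res
  res
}
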