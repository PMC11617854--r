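# Shared setup for the analysis drivers: the reference study design and
# the deterministic preprocessing chain. Every numbered script sources
# this file; everything is recomputed from the seed, so no intermediate
# binaries are stored.
suppressPackageStartupMessages(library(episig))

SEED <- 1L
RESULTS <- "results"
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

reference_design <- function() {
  sim_design(n_probes = 20000, n_cases = 16, n_controls = 64,
             n_vus_carrier = 1, n_vus_null = 1,
             other_cohort_sizes = c(16, 16),
             signature_size = 300, effect_delta = 0.15,
             hypo_fraction = 0.9, rng_seed = SEED)
}

reference_config <- function() episig_config(rng_seed = SEED)

# Simulation -> matching -> filtering -> M-values, in one deterministic
# chain used by every stage.
load_reference <- function() {
  des <- reference_design()
  mani <- generate_manifest(des)
  st <- generate_study(des, mani)
  cfg <- reference_config()
  cases <- st$sheet[st$sheet$cohort_label == "case", ]
  pool <- st$sheet[st$sheet$cohort_label == "control", ]
  ctrl_ids <- match_controls(cases, pool, cfg)
  f <- filter_probes(st$beta, st$detp, mani, cfg)
  m <- beta_to_m(f$beta, cfg)
  disc_ids <- c(cases$sample_id, ctrl_ids)
  list(design = des, manifest = mani, study = st, cfg = cfg,
       filtered = f, m = m, cases = cases, ctrl_ids = ctrl_ids,
       disc_ids = disc_ids,
       disc_sheet = st$sheet[st$sheet$sample_id %in% disc_ids, ])
}

discovery_signature <- function(ref) {
  select_signature(
    beta_matrix(unclass(ref$filtered$beta)[, ref$disc_ids, drop = FALSE]),
    m_matrix(unclass(ref$m)[, ref$disc_ids, drop = FALSE]),
    ref$disc_sheet, ref$cfg)
}
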