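#' Simulation design for synthetic EPIC-like cohorts
#'
#' Defines the study conditions under which the pipeline is exercised: a
#' probe universe, a case series with a planted, predominantly
#' hypomethylated episignature, matched-control candidates, optional
#' other-disorder cohorts with a controllable planted-probe overlap,
#' cell-composition confounding, batch effects, heteroscedastic probe
#' noise and sporadic detection failures.
#'
#' @param n_probes probe universe size (>= 100).
#' @param n_cases number of case samples.
#' @param n_controls number of control-pool samples.
#' @param n_vus_carrier,n_vus_null extra `test`-labelled samples carrying /
#'   not carrying the planted effect (variant-of-uncertain-significance
#'   stand-ins).
#' @param other_cohort_sizes integer vector; one other-disorder cohort per
#'   entry (may be empty).
#' @param signature_size planted probes per cohort.
#' @param effect_delta mean absolute beta shift of planted probes, in
#'   (0, 0.5).
#' @param hypo_fraction fraction of planted probes shifted downwards
#'   (default 0.9: real signatures of this kind are predominantly
#'   hypomethylated).
#' @param overlap_fraction fraction of planted probes shared between any
#'   two cohorts (a common core construction).
#' @param confound_scale magnitude of cell-fraction-dependent probe
#'   effects.
#' @param batch_scale SD of per-probe batch offsets.
#' @param noise_sd typical per-probe between-sample SD (measurement plus
#'   inter-individual biological variation; per-probe SDs are
#'   gamma-distributed around it).
#' @param hypervar_fraction fraction of probes that are hypervariable
#'   (mQTL-like bimodal population mixtures, SD 0.1-0.25) — the class that
#'   dominates the top-variability tail of real arrays.
#' @param detection_fail_rate per-measurement probability of a detection
#'   failure (detection p > 0.1, beta missing).
#' @param sex_chrom_fraction,snp_fraction,crossreactive_fraction manifest
#'   composition fractions.
#' @param rng_seed integer seed; all outputs are deterministic given it.
#'
#' @return an object of class `sim_design`.
#' @export
sim_design <- function(n_probes = 20000,
                       n_cases = 16,
                       n_controls = 64,
                       n_vus_carrier = 0,
                       n_vus_null = 0,
                       other_cohort_sizes = integer(0),
                       signature_size = 300,
                       effect_delta = 0.15,
                       hypo_fraction = 0.9,
                       overlap_fraction = 0.2,
                       confound_scale = 0.05,
                       batch_scale = 0.01,
                       noise_sd = 0.03,
                       hypervar_fraction = 0.025,
                       detection_fail_rate = 1e-4,
                       sex_chrom_fraction = 0.04,
                       snp_fraction = 0.02,
                       crossreactive_fraction = 0.02,
                       rng_seed = 1L) {
  d <- list(n_probes = as.integer(n_probes), n_cases = as.integer(n_cases),
            n_controls = as.integer(n_controls),
            n_vus_carrier = as.integer(n_vus_carrier),
            n_vus_null = as.integer(n_vus_null),
            other_cohort_sizes = as.integer(other_cohort_sizes),
            signature_size = as.integer(signature_size),
            effect_delta = effect_delta, hypo_fraction = hypo_fraction,
            overlap_fraction = overlap_fraction,
            confound_scale = confound_scale, batch_scale = batch_scale,
            noise_sd = noise_sd, hypervar_fraction = hypervar_fraction,
            detection_fail_rate = detection_fail_rate,
            sex_chrom_fraction = sex_chrom_fraction,
            snp_fraction = snp_fraction,
            crossreactive_fraction = crossreactive_fraction,
            rng_seed = as.integer(rng_seed))
  stopifnot(d$n_probes >= 100,
            d$signature_size <= d$n_probes,
            d$hypo_fraction >= 0, d$hypo_fraction <= 1,
            d$effect_delta >= 0, d$effect_delta < 0.5,
            d$overlap_fraction >= 0, d$overlap_fraction <= 1,
            d$hypervar_fraction >= 0, d$hypervar_fraction < 0.5,
            d$detection_fail_rate >= 0, d$detection_fail_rate < 1)
  class(d) <- "sim_design"
  d
}

#' Generate a synthetic probe manifest
#'
#' Probes are spread over chr1-22 (plus a configurable fraction on
#' chrX/chrY), sorted within chromosome. Inter-probe gaps are drawn from a
#' mixture of tight (CpG-island-like, 30-200 bp) and long spacings so that
#' runs compatible with DMR calling exist. SNP-affected and cross-reactive
#' flags are assigned independently at the design fractions.
#'
#' @param design a [sim_design()].
#' @return a `probe_manifest`.
#' @export
generate_manifest <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$rng_seed)
  n <- design$n_probes
  n_sex <- round(design$sex_chrom_fraction * n)
  chroms <- c(sample(paste0("chr", 1:22), n - n_sex, replace = TRUE),
              sample(c("chrX", "chrY"), n_sex, replace = TRUE,
                     prob = c(0.8, 0.2)))
  tight <- stats::runif(n) < 0.3
  gaps <- ifelse(tight,
                 sample(30:200, n, replace = TRUE),
                 round(stats::rexp(n, rate = 1 / 3000)) + 200)
  ord <- order(factor(chroms, levels = ALLOWED_CHROMS))
  chroms <- chroms[ord]
  pos <- stats::ave(gaps[ord], chroms, FUN = cumsum) + 10000
  mani <- data.frame(
    probe_id = sprintf("cg%08d", seq_len(n)),
    chrom = chroms,
    pos = as.integer(pos),
    snp_affected = stats::runif(n) < design$snp_fraction,
    cross_reactive = stats::runif(n) < design$crossreactive_fraction,
    stringsAsFactors = FALSE
  )
  probe_manifest(mani)
}

# Per-probe baseline methylation: three-mode marginal typical of blood
# arrays (unmethylated ~0.1, intermediate ~0.5, methylated ~0.85).
draw_baselines <- function(n) {
  mode <- sample.int(3L, n, replace = TRUE, prob = c(0.45, 0.15, 0.40))
  mu <- c(0.10, 0.50, 0.85)[mode]
  conc <- c(60, 25, 60)[mode]
  stats::rbeta(n, mu * conc, (1 - mu) * conc)
}

# Candidate probes for planting: autosomal, unflagged, mid-range baseline
# so the shifted mean stays inside (0,1) and survives the boundary filter.
plantable <- function(manifest, baseline, hv_idx = integer(0)) {
  cand <- which(!manifest$snp_affected & !manifest$cross_reactive &
                  !(manifest$chrom %in% c("chrX", "chrY")) &
                  baseline > 0.2 & baseline < 0.8)
  setdiff(cand, hv_idx)
}

# Hypervariable (mQTL-like) probes: per-sample two-component mixture with
# probe-specific minor-mode frequency and separation.
draw_hypervar <- function(n_probes, hypervar_fraction) {
  n_hv <- round(hypervar_fraction * n_probes)
  list(idx = sample.int(n_probes, n_hv),
       q = stats::runif(n_hv, 0.2, 0.8),
       delta = stats::runif(n_hv, 0.3, 0.5))
}

# Signed planted effects: magnitudes spread around effect_delta,
# hypo_fraction of them negative (count rounded).
draw_effects <- function(n, effect_delta, hypo_fraction) {
  mag <- abs(stats::rnorm(n, effect_delta, effect_delta / 5))
  n_hypo <- round(hypo_fraction * n)
  sign <- rep(1, n)
  if (n_hypo > 0) sign[sample.int(n, n_hypo)] <- -1
  mag * sign
}

simulate_samples <- function(ids, labels, world, planted_idx, effects,
                             carrier, design) {
  n_probes <- length(world$baseline)
  n_samp <- length(ids)
  k <- length(CELL_FRACTION_COLS)
  # blood composition: granulocyte-dominant Dirichlet
  alpha <- c(cd8t = 2, cd4t = 3, nk = 1, bcell = 1.5, mono = 2, gran = 12)
  g <- matrix(stats::rgamma(n_samp * k, shape = rep(alpha, each = n_samp)),
              nrow = n_samp)
  fr <- g / rowSums(g)
  colnames(fr) <- CELL_FRACTION_COLS
  batch <- sample(c("b1", "b2"), n_samp, replace = TRUE)
  mu <- matrix(world$baseline, n_probes, n_samp)
  if (length(planted_idx) > 0 && any(carrier))
    mu[planted_idx, carrier] <- mu[planted_idx, carrier] + effects
  # cell-composition confounding on a random probe subset, centred so it
  # perturbs rather than shifts globally
  frc <- sweep(fr, 2, colMeans(fr))
  mu[world$confound_idx, ] <- mu[world$confound_idx, ] +
    design$confound_scale * (world$confound_coef %*% t(frc))
  mu[, batch == "b2"] <- mu[, batch == "b2"] + world$batch_coef
  hv <- world$hv
  if (length(hv$idx) > 0) {
    z <- matrix(stats::runif(length(hv$idx) * n_samp) < hv$q,
                length(hv$idx), n_samp)
    mu[hv$idx, ] <- mu[hv$idx, ] + hv$delta * (z - hv$q)
  }
  noise <- matrix(stats::rnorm(n_probes * n_samp, sd = world$probe_sd),
                  n_probes, n_samp)
  # Illumina-style betas are intensity ratios and never reach 0 or 1
  beta <- pmin(pmax(mu + noise, 1e-3), 1 - 1e-3)
  detp <- matrix(stats::runif(n_probes * n_samp, 0, 0.01),
                 n_probes, n_samp)
  fail <- matrix(stats::runif(n_probes * n_samp) < design$detection_fail_rate,
                 n_probes, n_samp)
  detp[fail] <- stats::runif(sum(fail), 0.1 + 1e-9, 1)
  beta[fail] <- NA_real_
  dimnames(beta) <- dimnames(detp) <- list(NULL, ids)
  sheet <- data.frame(
    sample_id = ids, cohort_label = labels,
    sex = sample(c("M", "F"), n_samp, replace = TRUE),
    age = round(stats::runif(n_samp, 2, 18), 1),
    batch = batch, fr, stringsAsFactors = FALSE)
  list(beta = beta, detp = detp, sheet = sheet)
}

# Allocate planted sets with an exact pairwise overlap: a common core of
# round(overlap * size) probes shared by all cohorts plus disjoint remainders.
allocate_planted_sets <- function(pool, sizes, overlap_fraction) {
  n_core <- round(overlap_fraction * min(sizes))
  need <- n_core + sum(sizes - n_core)
  if (need > length(pool))
    stop(sprintf(
      "overlap_fraction %.2f infeasible: need %d plantable probes, have %d",
      overlap_fraction, need, length(pool)), call. = FALSE)
  core <- pool[seq_len(n_core)]
  rest <- pool[-seq_len(n_core)]
  out <- vector("list", length(sizes))
  off <- 0L
  for (i in seq_along(sizes)) {
    n_uniq <- sizes[i] - n_core
    out[[i]] <- c(core, rest[off + seq_len(n_uniq)])
    off <- off + n_uniq
  }
  out
}

# The shared "array world": everything probe-level that must be common to
# every sample of a study — baselines, the hypervariable class, per-probe
# noise SDs, confounding structure, batch offsets, and the planted probe
# allocation for the index cohort and each other-disorder cohort.
# Deterministic given (design, manifest).
sim_world <- function(design, manifest) {
  if (nrow(manifest) != design$n_probes)
    stop("manifest does not match design: ", nrow(manifest), " probes vs ",
         design$n_probes, call. = FALSE)
  set.seed(design$rng_seed + 1L)
  n_probes <- design$n_probes
  baseline <- draw_baselines(n_probes)
  hv <- draw_hypervar(n_probes, design$hypervar_fraction)
  cand <- plantable(manifest, baseline, hv$idx)
  n_coh <- 1L + length(design$other_cohort_sizes)
  sizes <- rep(design$signature_size, n_coh)
  if (length(cand) < max(sizes))
    stop("not enough plantable probes for signature_size", call. = FALSE)
  sets <- allocate_planted_sets(sample(cand), sizes, design$overlap_fraction)
  sets <- lapply(sets, sort)
  effects <- lapply(sets, function(s)
    draw_effects(length(s), design$effect_delta, design$hypo_fraction))
  list(baseline = baseline, hv = hv,
       probe_sd = design$noise_sd / 2 +
         stats::rgamma(n_probes, 2, scale = design$noise_sd / 4),
       confound_idx = sample.int(n_probes, round(0.2 * n_probes)),
       confound_coef = matrix(
         stats::rnorm(round(0.2 * n_probes) * length(CELL_FRACTION_COLS)),
         nrow = round(0.2 * n_probes)),
       batch_coef = stats::rnorm(n_probes, 0, design$batch_scale),
       planted = sets, effects = effects)
}

# Simulate every sample group of the study on one shared world and one RNG
# stream: index cases, controls, VUS stand-ins, then other-disorder cohorts.
generate_all <- function(design, manifest) {
  world <- sim_world(design, manifest)
  set.seed(design$rng_seed + 2L)
  groups <- list()
  sim_group <- function(ids, labels, set_i, carrier) {
    s <- simulate_samples(ids, labels, world, world$planted[[set_i]],
                          world$effects[[set_i]], carrier, design)
    rownames(s$beta) <- rownames(s$detp) <- manifest$probe_id
    s
  }
  groups$case <- sim_group(sprintf("case_%02d", seq_len(design$n_cases)),
                           rep("case", design$n_cases), 1L,
                           rep(TRUE, design$n_cases))
  groups$control <- sim_group(sprintf("ctrl_%02d", seq_len(design$n_controls)),
                              rep("control", design$n_controls), 1L,
                              rep(FALSE, design$n_controls))
  if (design$n_vus_carrier > 0)
    groups$vus_carrier <- sim_group(
      sprintf("vus_carrier_%02d", seq_len(design$n_vus_carrier)),
      rep("test", design$n_vus_carrier), 1L,
      rep(TRUE, design$n_vus_carrier))
  if (design$n_vus_null > 0)
    groups$vus_null <- sim_group(
      sprintf("vus_null_%02d", seq_len(design$n_vus_null)),
      rep("test", design$n_vus_null), 1L,
      rep(FALSE, design$n_vus_null))
  other <- list()
  for (i in seq_along(design$other_cohort_sizes)) {
    nm <- sprintf("nd%02d", i)
    other[[nm]] <- sim_group(
      sprintf("%s_%02d", nm, seq_len(design$other_cohort_sizes[i])),
      rep(paste0("other_disorder:", nm), design$other_cohort_sizes[i]),
      i + 1L, rep(TRUE, design$other_cohort_sizes[i]))
  }
  list(world = world, groups = groups, other = other,
       probe_ids = manifest$probe_id)
}

group_truth <- function(world, probe_ids, set_i) {
  idx <- world$planted[[set_i]]
  list(planted = probe_ids[idx],
       effect = stats::setNames(world$effects[[set_i]], probe_ids[idx]))
}

bind_groups <- function(gs) {
  list(beta = do.call(cbind, lapply(gs, `[[`, "beta")),
       detp = do.call(cbind, lapply(gs, `[[`, "detp")),
       sheet = do.call(rbind, lapply(gs, `[[`, "sheet")))
}

#' Generate one synthetic case/control cohort
#'
#' Draws per-probe baselines from a three-mode methylation distribution,
#' plants a signed episignature of `signature_size` probes in the case
#' samples (and optional carrier VUS samples), adds cell-composition
#' confounding, batch offsets, mQTL-like hypervariable probes and
#' heteroscedastic noise, keeps betas strictly inside (0, 1) as intensity
#' ratios are, and injects detection failures (beta missing, detection
#' p > 0.1). Deterministic given the design seed, and consistent with
#' [generate_multi_cohort()] / [generate_study()] for the same design.
#'
#' @param design a [sim_design()].
#' @param manifest the matching [generate_manifest()] output.
#' @return list with `beta` (a `beta_matrix`), `sheet` (a `sample_sheet`),
#'   `detp` (detection-p matrix), and `truth` (planted probe ids, signed
#'   effects, per-sample carrier status).
#' @export
generate_cohort <- function(design, manifest) {
  stopifnot(inherits(design, "sim_design"), inherits(manifest, "probe_manifest"))
  all <- generate_all(design, manifest)
  b <- bind_groups(all$groups)
  truth <- group_truth(all$world, all$probe_ids, 1L)
  truth$carrier <- stats::setNames(
    grepl("^case_|^vus_carrier_", b$sheet$sample_id), b$sheet$sample_id)
  list(beta = beta_matrix(b$beta), sheet = sample_sheet(b$sheet),
       detp = b$detp, truth = truth)
}

#' Generate multiple disorder cohorts with controlled signature overlap
#'
#' The first cohort returned is the index (`case`-labelled) cohort, the
#' rest are `other_disorder:<name>` cohorts; each has its own planted
#' probe set, and any two sets share a common core of
#' `round(overlap_fraction * signature_size)` probes, so the pairwise
#' shared fraction equals `overlap_fraction` up to rounding. All cohorts
#' live on the same manifest and the same array world (so they can be
#' column-bound with [generate_cohort()] controls of the same design for
#' classifier training); sample ids are prefixed with the cohort name.
#'
#' @param design a [sim_design()] with at least one `other_cohort_sizes`
#'   entry.
#' @param manifest matching manifest.
#' @return list of cohorts, each a list `(name, beta, sheet, detp, truth)`.
#' @export
generate_multi_cohort <- function(design, manifest) {
  stopifnot(inherits(design, "sim_design"))
  if (length(design$other_cohort_sizes) < 1)
    stop("need n_other_cohorts >= 1 (other_cohort_sizes non-empty)",
         call. = FALSE)
  all <- generate_all(design, manifest)
  gs <- c(list(index = all$groups$case), all$other)
  names_coh <- names(gs)
  lapply(seq_along(gs), function(i) {
    list(name = names_coh[i],
         beta = beta_matrix(gs[[i]]$beta),
         sheet = sample_sheet(gs[[i]]$sheet),
         detp = gs[[i]]$detp,
         truth = group_truth(all$world, all$probe_ids, i))
  })
}

#' Generate a full synthetic study
#'
#' Everything [generate_cohort()] and [generate_multi_cohort()] produce,
#' combined on one array world: index cases, the control pool, optional
#' VUS stand-ins, and the other-disorder cohorts, as one beta matrix, one
#' sample sheet and one detection-p matrix.
#'
#' @param design a [sim_design()].
#' @param manifest matching manifest.
#' @return list with `beta`, `sheet`, `detp`, `truth` (index-cohort planted
#'   set, effects, per-sample carrier status) and `other_truth` (one truth
#'   per other-disorder cohort).
#' @export
generate_study <- function(design, manifest) {
  stopifnot(inherits(design, "sim_design"), inherits(manifest, "probe_manifest"))
  all <- generate_all(design, manifest)
  b <- bind_groups(c(all$groups, all$other))
  truth <- group_truth(all$world, all$probe_ids, 1L)
  truth$carrier <- stats::setNames(
    grepl("^case_|^vus_carrier_", b$sheet$sample_id), b$sheet$sample_id)
  other_truth <- NULL
  if (length(all$other) > 0) {
    other_truth <- lapply(seq_along(all$other), function(i)
      group_truth(all$world, all$probe_ids, i + 1L))
    names(other_truth) <- names(all$other)
  }
  list(beta = beta_matrix(b$beta), sheet = sample_sheet(b$sheet),
       detp = b$detp, truth = truth, other_truth = other_truth)
}

#' Column-bind cohorts that share a manifest
#'
#' @param cohorts list as returned by [generate_cohort()] /
#'   [generate_multi_cohort()] elements.
#' @return list with combined `beta`, `sheet`, `detp`.
#' @export
bind_cohorts <- function(cohorts) {
  beta <- do.call(cbind, lapply(cohorts, function(x) unclass(x$beta)))
  detp <- do.call(cbind, lapply(cohorts, function(x) x$detp))
  sheet <- do.call(rbind, lapply(cohorts, function(x) as.data.frame(x$sheet)))
  list(beta = beta_matrix(beta), sheet = sample_sheet(sheet), detp = detp)
}
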