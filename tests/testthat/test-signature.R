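test_that("product ranking orders by |delta| x -log10(p) with stated ties", {
  d <- data.frame(probe_id = c("A", "B", "C"),
                  delta_beta = c(0.2, 0.05, 0.1),
                  p_value = c(1e-2, 1e-10, 1e-5))
  r <- rank_by_product(d, 3)
  expect_equal(r$product_score, c(0.5, 0.5, 0.4), tolerance = 1e-12)
  expect_equal(r$probe_id, c("B", "C", "A"))  # tie 0.5/0.5 -> smaller p first
  # all p = 1: all scores zero, ordered by probe id
  d1 <- data.frame(probe_id = c("z", "a", "m"), delta_beta = c(0.3, 0.2, 0.1),
                   p_value = c(1, 1, 1))
  expect_equal(rank_by_product(d1, 3)$probe_id, c("a", "m", "z"))
  expect_warning(rank_by_product(d, 10), "exceeds")
})

test_that("probe AUC equals pair enumeration on all small fixtures", {
  expect_equal(probe_auc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(probe_auc(c(0.5, 0.5), c(TRUE, FALSE)), 0.5)
  expect_equal(probe_auc(c(0.9, 0.3, 0.5, 0.1),
                         c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_error(probe_auc(c(1, 2), c(TRUE, TRUE)), "non-empty")
  # oracle identity: AUC = U / (n1 n0) by explicit pair enumeration
  enum_auc <- function(v, is_case) {
    cs <- v[is_case]; ct <- v[!is_case]
    u <- 0
    for (a in cs) for (b in ct) u <- u + (a > b) + 0.5 * (a == b)
    a1 <- u / (length(cs) * length(ct))
    max(a1, 1 - a1)
  }
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(4:20, 1)
    v <- round(runif(n), 2)           # ties likely
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(lab) || all(lab)) next
    expect_equal(probe_auc(v, lab), enum_auc(v, lab), tolerance = 1e-12)
  }
})

test_that("correlation pruning matches a brute-force greedy oracle", {
  ids <- paste0("p", 1:2)
  m <- m_matrix(matrix(c(1, 2, 3, 4, 2, 4, 6, 8), 2, 4, byrow = TRUE,
                       dimnames = list(ids, paste0("s", 1:4))))
  expect_equal(prune_correlated(m, ids, 0.85), "p1")  # identical probes
  set.seed(14)
  v <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("p", 1:5), paste0("s", 1:10)))
  v[2, ] <- v[1, ] + rnorm(10, sd = 0.1)
  v[4, ] <- -v[3, ] + rnorm(10, sd = 0.1)
  mm <- m_matrix(v)
  greedy_oracle <- function(cc, ids, r_max) {
    kept <- character(0)
    for (id in ids)
      if (all(abs(cc[id, kept]) <= r_max)) kept <- c(kept, id)
    kept
  }
  cc <- cor(t(v))
  for (r_max in c(0.5, 0.85, 0.99))
    expect_equal(prune_correlated(mm, rownames(v), r_max),
                 greedy_oracle(cc, rownames(v), r_max))
  # all pairwise |r| below threshold: everything kept
  expect_equal(prune_correlated(mm, rownames(v), 1), rownames(v))
})

test_that("signature selection recovers a planted episignature", {
  ref <- reference_study(1)
  sig <- ref$signature
  planted <- ref$study$truth$planted
  tp <- sum(sig$probes$probe_id %in% planted)
  expect_gte(tp / nrow(sig$probes), 0.8)   # precision
  expect_gte(tp / length(planted), 0.5)    # recall
  expect_true(all(sig$probes$auc >= ref$cfg$auc_min))
  expect_equal(anyDuplicated(sig$probes$probe_id), 0)
  # determinism: re-selection yields the identical probe set
  sig2 <- select_signature(
    beta_matrix(unclass(ref$filtered$beta)[, ref$disc_ids]),
    m_matrix(unclass(ref$m)[, ref$disc_ids]), ref$disc_sheet, ref$cfg)
  expect_identical(sig2$probes, sig$probes)
})

test_that("raising the AUC floor can only shrink the signature", {
  ref <- reference_study(1)
  beta <- beta_matrix(unclass(ref$filtered$beta)[, ref$disc_ids])
  m <- m_matrix(unclass(ref$m)[, ref$disc_ids])
  sizes <- sapply(c(0.75, 0.85, 0.95), function(a) {
    cfg <- episig_config(auc_min = a, rng_seed = 1)
    nrow(select_signature(beta, m, ref$disc_sheet, cfg)$probes)
  })
  expect_true(all(diff(sizes) <= 0))
})

test_that("a null cohort yields chance-level AUCs if anything at all", {
  des <- sim_design(n_probes = 4000, n_cases = 12, n_controls = 12,
                    signature_size = 50, effect_delta = 0,
                    rng_seed = 15)
  mani <- generate_manifest(des)
  coh <- generate_cohort(des, mani)
  cfg <- episig_config(rng_seed = 15)
  f <- filter_probes(coh$beta, coh$detp, mani, cfg)
  m <- beta_to_m(f$beta, cfg)
  dmps <- run_dmp(f$beta, m, coh$sheet, cfg)
  # nothing reaches genome-wide significance under the null
  expect_gte(min(dmps$p_adjusted), 0.05)
  sel <- tryCatch(
    select_signature(f$beta, m, coh$sheet, cfg),
    error = function(e) NULL)
  if (!is.null(sel)) {
    # whatever survives is chance: planted probes are not enriched
    expect_lte(mean(sel$probes$probe_id %in% coh$truth$planted), 0.05)
  }
})

test_that("LOOCV runs one round per case and recovers held-out cases", {
  des <- sim_design(n_probes = 2000, n_cases = 6, n_controls = 12,
                    signature_size = 100, effect_delta = 0.2,
                    rng_seed = 16)
  mani <- generate_manifest(des)
  coh <- generate_cohort(des, mani)
  cfg <- episig_config(product_rank_k = 200, rng_seed = 16)
  f <- filter_probes(coh$beta, coh$detp, mani, cfg)
  m <- beta_to_m(f$beta, cfg)
  cv <- loocv(f$beta, m, coh$sheet, cfg)
  expect_equal(nrow(cv), 6)
  expect_true(all(is.na(cv$error)))
  expect_true(all(cv$cluster == "case"))
  expect_true(all(cv$mvp >= cfg$mvp_threshold))
  expect_error(loocv(f$beta, m,
                     coh$sheet[-(1:4), , drop = FALSE], cfg), ">= 3")
})

test_that("Ward clustering separates planted groups and is monotone", {
  des <- sim_design(n_probes = 500, n_cases = 8, n_controls = 8,
                    signature_size = 60, effect_delta = 0.25,
                    rng_seed = 17)
  mani <- generate_manifest(des)
  coh <- generate_cohort(des, mani)
  m <- beta_to_m(coh$beta, episig_config())
  sub <- m_matrix(unclass(m)[coh$truth$planted, ])
  hc <- ward_cluster(sub)
  expect_true(!is.unsorted(hc$samples$height))  # Ward heights non-decreasing
  top2 <- cutree(hc$samples, 2)
  expect_equal(length(unique(top2[coh$sheet$cohort_label == "case"])), 1)
  expect_equal(length(unique(top2[coh$sheet$cohort_label == "control"])), 1)
  # identical samples merge at height zero
  same <- m_matrix(matrix(1, 4, 3, dimnames = list(paste0("p", 1:4),
                                                   paste0("s", 1:3))))
  expect_equal(max(ward_cluster(same)$samples$height), 0)
})

test_that("classical MDS reproduces exact low-rank geometry", {
  # three samples at equal mutual distance -> equilateral triangle
  v <- matrix(c(0, 0, 1, 0, 0.5, sqrt(3) / 2), nrow = 2,
              dimnames = list(c("p1", "p2"), c("a", "b", "c")))
  y <- mds_embed(m_matrix(v))
  dd <- as.matrix(dist(y))
  expect_equal(dd[lower.tri(dd)], rep(1, 3), tolerance = 1e-10)
  # degenerate input: all-zero embedding
  same <- m_matrix(matrix(2, 3, 4, dimnames = list(paste0("p", 1:3),
                                                   paste0("s", 1:4))))
  expect_equal(mds_embed(same), matrix(0, 4, 2,
                                       dimnames = list(paste0("s", 1:4), NULL)))
  # planted two-cluster data separates on dimension 1
  des <- sim_design(n_probes = 500, n_cases = 8, n_controls = 8,
                    signature_size = 60, effect_delta = 0.2, rng_seed = 18)
  coh <- generate_cohort(des, generate_manifest(des))
  m <- beta_to_m(coh$beta, episig_config())
  y2 <- mds_embed(m_matrix(unclass(m)[coh$truth$planted, ]))
  case1 <- y2[coh$sheet$cohort_label == "case", 1]
  ctrl1 <- y2[coh$sheet$cohort_label == "control", 1]
  expect_true(max(ctrl1) < min(case1) || max(case1) < min(ctrl1))
})
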