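make_m <- function(values, ids) {
  m_matrix(matrix(values, nrow = length(values) / length(ids), byrow = TRUE,
                  dimnames = list(paste0("p", seq_len(length(values) / length(ids))),
                                  ids)))
}

test_that("with constant covariates the fit reduces to a mean difference", {
  sheet <- tiny_sheet(c(rep("case", 4), rep("control", 4)))
  set.seed(5)
  v <- matrix(rnorm(80), 10, 8,
              dimnames = list(paste0("p", 1:10), sheet$sample_id))
  fit <- fit_probe_lm(m_matrix(v), sheet)
  md <- rowMeans(v[, 1:4]) - rowMeans(v[, 5:8])
  expect_equal(fit$coef_m, unname(md), tolerance = 1e-10)
  # zero noise, planted shift of 2.0 -> coefficient exactly 2.0
  v2 <- matrix(rep(c(3, 3, 3, 3, 1, 1, 1, 1), 3), 3, 8, byrow = TRUE,
               dimnames = list(paste0("q", 1:3), sheet$sample_id))
  expect_equal(fit_probe_lm(m_matrix(v2), sheet)$coef_m, rep(2, 3),
               tolerance = 1e-12)
})

test_that("coefficients match an independent normal-equations solve", {
  set.seed(6)
  sheet <- as.data.frame(tiny_sheet(c(rep("case", 4), rep("control", 4))))
  fr <- matrix(rgamma(48, 2), 8, 6)
  fr <- fr / rowSums(fr)
  sheet[episig:::CELL_FRACTION_COLS] <- fr
  sheet <- sample_sheet(sheet)
  v <- matrix(rnorm(160), 20, 8,
              dimnames = list(paste0("p", 1:20), sheet$sample_id))
  fit <- fit_probe_lm(m_matrix(v), sheet)
  # oracle: explicit (X'X)^-1 X'y per probe
  X <- cbind(1, as.numeric(sheet$cohort_label == "case"),
             fr[, -1])
  for (i in c(1, 7, 20)) {
    bhat <- solve(t(X) %*% X, t(X) %*% v[i, ])
    expect_equal(fit$coef_m[i], bhat[2], tolerance = 1e-10)
    res <- v[i, ] - X %*% bhat
    s2 <- sum(res^2) / (8 - ncol(X))
    expect_equal(fit$s2[i], s2, tolerance = 1e-10)
    se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
    expect_equal(fit$t_ordinary[i], bhat[2] / se, tolerance = 1e-10)
  }
  expect_equal(fit$df_residual, rep(8 - 7, 20))
})

test_that("rank deficiency is reported with the collinear column", {
  sheet <- as.data.frame(tiny_sheet(c(rep("case", 4), rep("control", 4))))
  set.seed(12)
  fr <- matrix(rgamma(48, 2), 8, 6)
  fr[, 3] <- fr[, 4]  # two identical modelled fraction columns (nk, bcell)
  sheet[episig:::CELL_FRACTION_COLS] <- fr / rowSums(fr)
  sheet <- suppressWarnings(sample_sheet(sheet))
  v <- matrix(rnorm(80), 10, 8,
              dimnames = list(paste0("p", 1:10), sheet$sample_id))
  expect_error(fit_probe_lm(m_matrix(v), sheet), "collinear")
})

test_that("moderation collapses to the ordinary statistics when degenerate", {
  s2 <- rep(0.5, 50)
  mod <- ebayes_moderate(s2, rep(10, 50))
  expect_true(is.infinite(mod$d0))
  expect_equal(mod$s2_post, rep(0.5, 50), tolerance = 1e-12)
  # d0 forced to 0: no shrinkage at all
  set.seed(7)
  s2r <- rchisq(50, 5) / 5
  mod0 <- ebayes_moderate(s2r, rep(10, 50), d0_override = 0)
  expect_equal(mod0$s2_post, s2r)
})

test_that("the moment estimator recovers a scaled inverse-chi-square prior", {
  d0_hat <- s0_hat <- numeric(10)
  for (s in 1:10) {
    set.seed(100 + s)
    s2 <- 4 * 0.04 / rchisq(5000, df = 4)
    mod <- ebayes_moderate(s2, rep(40, 5000))
    d0_hat[s] <- mod$d0
    s0_hat[s] <- mod$s0_sq
  }
  expect_true(all(d0_hat >= 2.5 & d0_hat <= 6))
  expect_true(all(s0_hat >= 0.03 & s0_hat <= 0.055))
})

test_that("moderated statistics agree with the limma implementation", {
  skip_if_not_installed("limma")
  set.seed(8)
  sheet <- tiny_sheet(c(rep("case", 5), rep("control", 5)))
  v <- matrix(rnorm(5000, sd = rep(sqrt(0.04 * 4 / rchisq(500, 4)), 10)),
              500, 10, dimnames = list(paste0("p", 1:500), sheet$sample_id))
  fit <- fit_probe_lm(m_matrix(v), sheet)
  mod <- ebayes_moderate(fit$s2, fit$df_residual)
  X <- cbind(1, as.numeric(sheet$cohort_label == "case"))
  lf <- limma::eBayes(limma::lmFit(v, X))
  expect_equal(fit$coef_m, unname(lf$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(mod$d0, lf$df.prior, tolerance = 0.05)
  expect_equal(mod$s0_sq, lf$s2.prior, tolerance = 1e-3)
  expect_equal(mod$s2_post, unname(lf$s2.post), tolerance = 1e-6)
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(adjust_pvalues(0.05), 0.05)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  expect_error(adjust_pvalues(c(0.5, 0)), "p >")
})

test_that("mean beta difference matches a two-loop oracle", {
  sheet <- tiny_sheet(c(rep("case", 3), rep("control", 3)))
  b <- tiny_beta(5, 6, seed = 9)
  colnames_b <- colnames(b)
  d <- mean_beta_diff(beta_matrix(structure(unclass(b),
    dimnames = list(rownames(b), sheet$sample_id))), sheet)
  v <- unclass(b)
  for (i in 1:5) {
    expect_equal(unname(d[i]), mean(v[i, 1:3]) - mean(v[i, 4:6]),
                 tolerance = 1e-12)
  }
  # identical groups -> zero; constant shift -> exact difference
  same <- matrix(0.4, 2, 6, dimnames = list(c("a", "b"), sheet$sample_id))
  expect_equal(unname(mean_beta_diff(beta_matrix(same), sheet)), c(0, 0))
  shifted <- same; shifted[, 1:3] <- 0.3; shifted[, 4:6] <- 0.5
  expect_equal(unname(mean_beta_diff(beta_matrix(shifted), sheet)),
               c(-0.2, -0.2), tolerance = 1e-12)
})

test_that("statistics are invariant to a global M-value shift", {
  sheet <- tiny_sheet(c(rep("case", 4), rep("control", 4)))
  set.seed(10)
  v <- matrix(rnorm(160), 20, 8,
              dimnames = list(paste0("p", 1:20), sheet$sample_id))
  f1 <- fit_probe_lm(m_matrix(v), sheet)
  f2 <- fit_probe_lm(m_matrix(v + 5), sheet)
  expect_equal(f1$coef_m, f2$coef_m, tolerance = 1e-10)
  expect_equal(f1$t_ordinary, f2$t_ordinary, tolerance = 1e-10)
})

test_that("moderated t interpolates between ordinary and pooled t", {
  set.seed(11)
  s2 <- rchisq(100, 5) / 5
  coef <- rnorm(100)
  su <- 0.5
  df <- rep(8, 100)
  t_ord <- coef / (sqrt(s2) * su)
  pooled <- exp(mean(log(s2)))  # d0 -> Inf limit of the moment prior
  for (d0 in c(0.5, 2, 8, 50)) {
    mod <- ebayes_moderate(s2, df, d0_override = d0)
    t_mod <- coef / (sqrt(mod$s2_post) * su)
    # moderated t lies between the ordinary and fully pooled statistic
    t_pool <- coef / (sqrt(mod$s0_sq) * su)
    lo <- pmin(t_ord, t_pool); hi <- pmax(t_ord, t_pool)
    expect_true(all(t_mod >= lo - 1e-9 & t_mod <= hi + 1e-9))
  }
})

test_that("type-I error is calibrated under the global null", {
  des <- sim_design(n_probes = 10000, n_cases = 16, n_controls = 32,
                    signature_size = 100, effect_delta = 0, rng_seed = 5)
  mani <- generate_manifest(des)
  coh <- generate_cohort(des, mani)
  cfg <- episig_config(rng_seed = 5)
  f <- filter_probes(coh$beta, coh$detp, mani, cfg)
  m <- beta_to_m(f$beta, cfg)
  d <- run_dmp(f$beta, m, coh$sheet, cfg)
  frac <- mean(d$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(d))
  expect_lte(abs(frac - 0.05), 3 * se)
  expect_true(all(d$p_adjusted >= d$p_value))
  expect_equal(sign(d$t_moderated), sign(d$coef_m))
})
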