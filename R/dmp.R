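# Per-probe linear modelling with cell-composition covariates and
# empirical-Bayes variance moderation (scaled inverse-chi-square prior,
# moment estimation on log variances).

# Design matrix: intercept, case indicator, five cell fractions (cd8t is
# dropped to break the sum-to-one collinearity; documented choice).
dmp_design <- function(sheet, case_label = "case", control_label = "control") {
  keep <- sheet$cohort_label %in% c(case_label, control_label)
  sheet <- sheet[keep, , drop = FALSE]
  if (sum(sheet$cohort_label == case_label) == 0 ||
      sum(sheet$cohort_label == control_label) == 0)
    stop("need at least one case and one control sample", call. = FALSE)
  fr <- as.matrix(sheet[, setdiff(CELL_FRACTION_COLS, "cd8t")])
  # constant covariates carry no information and are absorbed by the
  # intercept (e.g. identical fractions on every sample)
  fr <- fr[, apply(fr, 2, stats::sd) > 0, drop = FALSE]
  X <- cbind(intercept = 1,
             group = as.numeric(sheet$cohort_label == case_label),
             fr)
  rownames(X) <- sheet$sample_id
  X
}

#' Per-probe ordinary least squares fit
#'
#' Fits, for every probe, `M ~ group + cell fractions` (intercept, a
#' case/control indicator, and five of the six blood-cell fractions — one
#' is dropped for identifiability). Returns the group coefficient, its
#' unscaled standard error, residual variance and degrees of freedom, and
#' the ordinary t-statistic.
#'
#' @param m an `m_matrix` (probes x samples).
#' @param sheet a `sample_sheet` with `case` and `control` rows covering
#'   the samples used (other labels are ignored).
#' @return data.frame with columns `probe_id`, `coef_m`, `stdev_unscaled`,
#'   `s2`, `df_residual`, `t_ordinary`.
#' @export
fit_probe_lm <- function(m, sheet) {
  stopifnot(inherits(m, "m_matrix"))
  X <- dmp_design(sheet)
  miss <- setdiff(rownames(X), colnames(m))
  if (length(miss) > 0)
    stop("samples in sheet but not in matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  Y <- unclass(m)[, rownames(X), drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (nrow(X) <= ncol(X))
    stop("need more samples than design columns", call. = FALSE)
  coefs <- qr.coef(qrX, t(Y))           # p x n_probes
  resid <- t(Y) - X %*% coefs
  df <- nrow(X) - ncol(X)
  s2 <- colSums(resid^2) / df
  XtXinv <- chol2inv(qr.R(qrX))         # in pivoted order; unpivot
  unscaled <- sqrt(diag(XtXinv))[order(qrX$pivot)]
  names(unscaled) <- colnames(X)
  su <- unscaled["group"]
  cf <- coefs["group", ]
  t_ord <- cf / (sqrt(s2) * su)
  data.frame(probe_id = rownames(m), coef_m = unname(cf),
             stdev_unscaled = unname(su), s2 = unname(s2),
             df_residual = df, t_ordinary = unname(t_ord),
             stringsAsFactors = FALSE)
}

# Newton solve of trigamma(x) = y (monotone decreasing, convex); the
# standard iteration on 1/x for stability.
trigamma_inverse <- function(y) {
  sapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (iter in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif / x) < 1e-8) break
    }
    x
  })
}

#' Empirical-Bayes variance moderation
#'
#' Estimates a scaled inverse-chi-square prior (d0 prior degrees of
#' freedom, s0^2 prior variance) for the per-probe residual variances by
#' the method of moments on log variances: with
#' `e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2)`, the prior satisfies
#' `E[e] = log(s0^2) + digamma(d0/2) - log(d0/2)` and
#' `Var[e] = trigamma(d_g/2) + trigamma(d0/2)`, solved with a Newton
#' inversion of the trigamma function. Posterior (moderated) variances are
#' `(d0 s0^2 + d_g s2_g) / (d0 + d_g)`.
#'
#' When the excess variance of `e` is non-positive (e.g. all variances
#' equal), d0 is the `Inf` sentinel and s0^2 the common variance, so every
#' moderated variance equals s0^2.
#'
#' @param s2 per-probe residual variances.
#' @param df per-probe residual degrees of freedom.
#' @param d0_override optional forced d0 (0 disables shrinkage, `Inf`
#'   fully pools).
#' @return list with `d0`, `s0_sq`, and `s2_post` (moderated variances).
#' @export
ebayes_moderate <- function(s2, df, d0_override = NULL) {
  ok <- df > 0 & is.finite(s2) & s2 > 0
  if (sum(ok) < 10) stop("need >= 10 probes with positive df", call. = FALSE)
  if (is.null(d0_override)) {
    z <- log(s2[ok])
    dfo <- df[ok]
    e <- z - digamma(dfo / 2) + log(dfo / 2)
    emean <- mean(e)
    n <- length(e)
    evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(dfo / 2))
    if (stats::var(z) == 0) {        # all variances identical
      d0 <- Inf
      s0_sq <- s2[ok][1]
    } else if (evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_sq <- exp(emean)
    }
  } else {
    d0 <- d0_override
    s0_sq <- if (is.finite(d0) && d0 > 0) exp(mean(log(s2[ok]))) else
      mean(s2[ok])
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    if (d0 == 0) s2 else (d0 * s0_sq + df * s2) / (d0 + df)
  list(d0 = d0, s0_sq = s0_sq, s2_post = s2_post)
}

#' Benjamini-Hochberg (or other) p-value adjustment
#'
#' Thin wrapper over [stats::p.adjust()] kept as the pipeline's single
#' multiplicity-correction entry point.
#'
#' @param p p-values in (0, 1].
#' @param method adjustment method (default BH step-up).
#' @return adjusted p-values (monotone, bounded by 1).
#' @export
adjust_pvalues <- function(p, method = "BH") {
  stopifnot(all(p > 0 & p <= 1))
  stats::p.adjust(p, method = method)
}

#' Per-probe case-control mean beta difference
#'
#' @param beta a `beta_matrix`.
#' @param sheet a `sample_sheet`.
#' @return named vector: mean beta of cases minus mean beta of controls.
#' @export
mean_beta_diff <- function(beta, sheet) {
  cs <- sheet$sample_id[sheet$cohort_label == "case"]
  ct <- sheet$sample_id[sheet$cohort_label == "control"]
  if (length(cs) == 0 || length(ct) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  rowMeans(unclass(beta)[, cs, drop = FALSE]) -
    rowMeans(unclass(beta)[, ct, drop = FALSE])
}

#' Differential methylation analysis
#'
#' Runs the per-probe linear model on M-values, moderates the variances
#' empirically (unless `cfg$moderate` is FALSE), computes two-sided
#' p-values from a t distribution on `d0 + df` degrees of freedom, adjusts
#' them, and attaches the beta-scale group difference.
#'
#' @param beta filtered `beta_matrix` (for the delta-beta column).
#' @param m matching `m_matrix`.
#' @param sheet a `sample_sheet`.
#' @param cfg an [episig_config()].
#' @return object of class `dmp_result`: a data.frame with columns
#'   `probe_id`, `delta_beta`, `coef_m`, `t_ordinary`, `t_moderated`,
#'   `p_value`, `p_adjusted`, `df_residual`, `s2`; moderation parameters in
#'   `attr(, "moderation")`.
#' @export
run_dmp <- function(beta, m, sheet, cfg = episig_config()) {
  fit <- fit_probe_lm(m, sheet)
  if (cfg$moderate) {
    mod <- ebayes_moderate(fit$s2, fit$df_residual)
    df_total <- ifelse(is.infinite(mod$d0), Inf,
                       mod$d0 + fit$df_residual)
  } else {
    mod <- list(d0 = 0, s0_sq = NA_real_, s2_post = fit$s2)
    df_total <- fit$df_residual
  }
  t_mod <- fit$coef_m / (sqrt(mod$s2_post) * fit$stdev_unscaled)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1]
  res <- data.frame(
    probe_id = fit$probe_id,
    delta_beta = unname(mean_beta_diff(beta, sheet)[fit$probe_id]),
    coef_m = fit$coef_m,
    t_ordinary = fit$t_ordinary,
    t_moderated = t_mod,
    p_value = p,
    p_adjusted = adjust_pvalues(p, cfg$p_adjust_method),
    df_residual = fit$df_residual,
    s2 = fit$s2,
    stringsAsFactors = FALSE)
  attr(res, "moderation") <- list(d0 = mod$d0, s0_sq = mod$s0_sq)
  class(res) <- c("dmp_result", "data.frame")
  res
}
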