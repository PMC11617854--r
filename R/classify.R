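# Linear SVM on signature-probe M-values with Platt-scaled decision
# values as the 0-1 methylation variant pathogenicity (MVP) score.

# Platt's sigmoid fit: P(y=1|d) = 1/(1+exp(A d + B)), maximum likelihood
# with the regularised targets (N+ + 1)/(N+ + 2) and 1/(N- + 2) so the fit
# is well-defined even on separable data.
platt_fit <- function(decision, is_pos) {
  np <- sum(is_pos); nn <- sum(!is_pos)
  t_target <- ifelse(is_pos, (np + 1) / (np + 2), 1 / (nn + 2))
  # cross-entropy of target t against p = 1/(1+exp(eta))
  nll <- function(par) {
    eta <- par[1] * decision + par[2]
    logp <- -log1p(exp(eta))       # log p,   p = 1/(1+exp(eta))
    log1mp <- -log1p(exp(-eta))    # log(1-p)
    -sum(t_target * logp + (1 - t_target) * log1mp)
  }
  fit <- stats::optim(c(A = -1, B = 0), nll, method = "BFGS")
  list(A = unname(fit$par[1]), B = unname(fit$par[2]))
}

platt_apply <- function(decision, platt) {
  1 / (1 + exp(platt$A * decision + platt$B))
}

#' Train the MVP classifier
#'
#' Positive class: all `case` samples. Negative class: a seeded random
#' `train_fraction` draw of the controls plus `train_fraction` of each
#' other-disorder cohort (the held-out remainder is recorded for
#' specificity evaluation). Signature-probe M-values are standardised by
#' training mean/SD, a linear SVM (cost `svm_C`) is fitted, and a Platt
#' sigmoid is calibrated on the training decision values, mapping them to
#' MVP scores in (0, 1).
#'
#' @param m an `m_matrix` covering all training samples.
#' @param sheet a `sample_sheet` (cases, controls, optional
#'   `other_disorder:*` rows).
#' @param signature a `signature_set` (or character vector of probe ids).
#' @param cfg an [episig_config()].
#' @return object of class `mvp_model`: signature probes, standardisation
#'   vectors, SVM weight vector and bias, Platt `A`/`B`, threshold, and
#'   the training/held-out composition.
#' @export
train_mvp_model <- function(m, sheet, signature, cfg = episig_config()) {
  probes <- if (inherits(signature, "signature_set"))
    signature$probes$probe_id else as.character(signature)
  if (length(probes) == 0) stop("empty signature", call. = FALSE)
  pos_ids <- sheet$sample_id[sheet$cohort_label == "case"]
  ctrl_ids <- sheet$sample_id[sheet$cohort_label == "control"]
  other <- sheet[startsWith(sheet$cohort_label, "other_disorder:"), ,
                 drop = FALSE]
  draw <- function(ids) {
    n <- floor(cfg$train_fraction * length(ids))
    sort(sample(ids, n))
  }
  set.seed(cfg$rng_seed)
  neg_train <- draw(ctrl_ids)
  for (co in unique(other$cohort_label))
    neg_train <- c(neg_train, draw(other$sample_id[other$cohort_label == co]))
  neg_heldout <- setdiff(c(ctrl_ids, other$sample_id), neg_train)
  if (length(pos_ids) < 2 || length(neg_train) < 2)
    stop("need >= 2 training samples per class", call. = FALSE)
  train_ids <- c(pos_ids, neg_train)
  x <- t(unclass(m)[probes, train_ids, drop = FALSE])
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ < 1e-12] <- 1
  xs <- scale(x, center, scale_)
  y <- factor(ifelse(rownames(xs) %in% pos_ids, "pos", "neg"),
              levels = c("neg", "pos"))
  fit <- e1071::svm(xs, y, kernel = "linear", cost = cfg$svm_C,
                    scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  d <- drop(xs %*% w) + b
  # orient so cases sit on the positive side
  if (mean(d[y == "pos"]) < mean(d[y == "neg"])) { w <- -w; b <- -b; d <- -d }
  platt <- platt_fit(d, y == "pos")
  structure(list(probes = probes, center = center, scale = scale_,
                 w = w, b = b, platt = platt,
                 mvp_threshold = cfg$mvp_threshold,
                 composition = list(train_cases = pos_ids,
                                    train_negatives = sort(neg_train),
                                    heldout_negatives = sort(neg_heldout),
                                    train_fraction = cfg$train_fraction,
                                    seed = cfg$rng_seed)),
            class = "mvp_model")
}

#' Score samples with an MVP model
#'
#' Deterministic: standardises the signature-probe M-values with the
#' stored training statistics, evaluates the linear decision function and
#' the Platt sigmoid. All signature probes must be present.
#'
#' @param model an `mvp_model`.
#' @param m an `m_matrix` containing the samples to score.
#' @return data.frame `sample_id`, `mvp`, `call`
#'   (`"positive"` iff `mvp >= mvp_threshold`, else `"negative"`).
#' @export
score_samples <- function(model, m) {
  stopifnot(inherits(model, "mvp_model"))
  miss <- setdiff(model$probes, rownames(m))
  if (length(miss) > 0)
    stop("matrix lacks signature probe(s): ",
         paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) " ...", call. = FALSE)
  x <- t(unclass(m)[model$probes, , drop = FALSE])
  xs <- scale(x, model$center, model$scale)
  d <- drop(xs %*% model$w) + model$b
  mvp <- platt_apply(d, model$platt)
  data.frame(sample_id = colnames(m), mvp = unname(mvp),
             call = ifelse(mvp >= model$mvp_threshold,
                           "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Reclassify variants of uncertain significance
#'
#' Scores VUS samples that were never part of training (a structural
#' leakage guard errors otherwise) and returns a signature-positive /
#' -negative verdict per sample, flagging borderline scores within 0.1 of
#' the decision threshold.
#'
#' @param model an `mvp_model`.
#' @param m an `m_matrix` containing the VUS samples.
#' @param vus_ids sample ids to reclassify.
#' @return data.frame `sample_id`, `mvp`, `call`, `verdict`, `borderline`.
#' @export
reclassify_vus <- function(model, m, vus_ids) {
  trained <- c(model$composition$train_cases,
               model$composition$train_negatives)
  leak <- intersect(vus_ids, trained)
  if (length(leak) > 0)
    stop("VUS sample(s) present in training composition: ",
         paste(leak, collapse = ", "), call. = FALSE)
  res <- score_samples(model, m_matrix(unclass(m)[, vus_ids, drop = FALSE]))
  res$verdict <- ifelse(res$call == "positive",
                        "signature-positive", "signature-negative")
  res$borderline <- abs(res$mvp - model$mvp_threshold) <= 0.1
  res
}
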