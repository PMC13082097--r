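#' Feature dissimilarity matrix (RDM) container
#'
#' @param mat square symmetric numeric matrix with zero diagonal.
#' @param labels feature labels in matrix order.
#' @param zscored whether off-diagonal upper-triangle entries have been
#'   z-scored (mean 0, unit variance).
#' @return A `feature_rdm` object.
#' @export
feature_rdm <- function(mat, labels = rownames(mat), zscored = FALSE) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("RDM must be square")
  if (max(abs(mat - t(mat))) > 1e-8) stop("RDM must be symmetric")
  if (max(abs(diag(mat))) > 1e-8) stop("RDM diagonal must be zero")
  if (is.null(labels)) labels <- as.character(seq_len(nrow(mat)) - 1L)
  dimnames(mat) <- list(labels, labels)
  structure(list(mat = mat, labels = as.character(labels),
                 zscored = isTRUE(zscored)),
            class = "feature_rdm")
}

#' @export
print.feature_rdm <- function(x, ...) {
  cat(sprintf("feature_rdm: %d x %d%s%s\n", nrow(x$mat), ncol(x$mat),
              if (x$zscored) ", z-scored" else "",
              if (isTRUE(attr(x, "degenerate"))) ", DEGENERATE" else ""))
  invisible(x)
}

rdm_mat <- function(x) if (inherits(x, "feature_rdm")) x$mat else as.matrix(x)

#' Dissimilarity matrix from 2-D feature arrangement coordinates
#'
#' Computes pairwise Euclidean distances between arranged features and
#' z-scores them within participant over the 55 off-diagonal
#' upper-triangle entries, the standard normalization for arrangement-task
#' dissimilarities.
#'
#' @param coords matrix with one row per feature and 2 columns (x, y).
#'   Row names, if present, become feature labels.
#' @return A z-scored `feature_rdm`. If the coordinates are degenerate
#'   (all pairwise distances identical, e.g. every feature dropped on one
#'   spot), the result carries attribute `degenerate = TRUE` and its
#'   entries are `NA`; aggregation functions drop such participants.
#' @export
rdm_from_coords <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, all(is.finite(coords)))
  d <- as.matrix(dist(coords))
  v <- zscore(upper_tri_vec(d))
  degenerate <- anyNA(v)
  out <- matrix(0, nrow(d), ncol(d))
  if (!degenerate) {
    out[upper.tri(out)] <- v
    out <- out + t(out)
  }
  r <- feature_rdm(out, labels = rownames(coords), zscored = TRUE)
  if (degenerate) r$mat[row(r$mat) != col(r$mat)] <- NA_real_
  attr(r, "degenerate") <- degenerate
  r
}

# correlation between the upper triangles of two RDMs, with optional
# masking-out of entries involving core features
rdm_correlation <- function(a, b, mask_core = FALSE, core_ids = NULL) {
  ma <- rdm_mat(a); mb <- rdm_mat(b)
  keep <- upper.tri(ma)
  if (mask_core) {
    if (is.null(core_ids)) stop("core_ids required when mask_core = TRUE")
    ci <- match(as.character(core_ids), rownames(ma) %||% as.character(core_ids))
    if (anyNA(ci)) ci <- as.integer(core_ids) + 1L
    core_mask <- outer(seq_len(nrow(ma)) %in% ci, seq_len(ncol(ma)) %in% ci, "|")
    keep <- keep & !core_mask
  }
  cor(ma[keep], mb[keep])
}

drop_degenerate <- function(rdms) {
  bad <- vapply(rdms, function(r) isTRUE(attr(r, "degenerate")) ||
                  anyNA(rdm_mat(r)), TRUE)
  if (any(bad))
    message(sum(bad), " degenerate RDM(s) excluded from aggregation")
  rdms[!bad]
}

#' Group-level structure-match test with permutation null and bootstrap
#'
#' Averages participants' dissimilarity matrices element-wise and
#' correlates the mean matrix with the ground-truth structure matrix
#' (Pearson r over the upper triangle). Significance is assessed against a
#' permuted null: feature labels of the *true* matrix are randomly permuted
#' (simultaneous row/column permutation) before correlating with the group
#' mean, and the significance threshold is the 95th percentile of the null
#' distribution. A bootstrap (participants resampled with replacement,
#' group size preserved) provides a confidence interval for the group
#' correlation.
#'
#' @param rdms list of participant `feature_rdm`s (all z-scored the same
#'   way); degenerate entries are dropped.
#' @param true the ground-truth `feature_rdm` (see [true_rdm()]).
#' @param n_perm number of label permutations (default 1000). Ignored when
#'   `exact = TRUE`.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @param exact if `TRUE`, enumerate all label permutations (only for
#'   matrices with at most 9 features).
#' @param mask_core,core_ids optionally exclude entries involving core
#'   features from all correlations.
#' @param ci_level bootstrap interval coverage (default 0.95).
#' @return A `group_structure_result`: list with `group_r`,
#'   `null_threshold` (95th percentile), `null` (the null draws),
#'   `bootstrap_ci`, `boot` (bootstrap draws), `n_participants`,
#'   `n_iterations`, `significant`.
#' @export
group_structure_test <- function(rdms, true, n_perm = 1000, n_boot = 1000,
                                 seed = NULL, exact = FALSE,
                                 mask_core = FALSE, core_ids = NULL,
                                 ci_level = 0.95) {
  rdms <- drop_degenerate(rdms)
  if (length(rdms) < 2) stop("need at least 2 participants")
  stopifnot(n_perm >= 1, n_boot >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  tmat <- rdm_mat(true)
  n_feat <- nrow(tmat)
  mats <- lapply(rdms, rdm_mat)
  mean_mat <- Reduce(`+`, mats) / length(mats)

  corr <- function(tm) rdm_correlation(tm, mean_mat, mask_core, core_ids)
  group_r <- corr(tmat)

  if (exact) {
    perms <- all_permutations(n_feat)
  } else {
    perms <- t(vapply(seq_len(n_perm), function(i) sample(n_feat), integer(n_feat)))
  }
  null <- apply(perms, 1, function(p) {
    pm <- tmat[p, p]
    dimnames(pm) <- dimnames(tmat)
    corr(pm)
  })
  null_threshold <- unname(quantile(null, 0.95))

  tri <- vapply(mats, upper_tri_vec, numeric(sum(upper.tri(tmat))))
  tvec <- upper_tri_vec(tmat)
  keepmask <- rep(TRUE, length(tvec))
  if (mask_core) {
    ci <- as.integer(core_ids) + 1L
    core_mask <- outer(seq_len(n_feat) %in% ci, seq_len(n_feat) %in% ci, "|")
    keepmask <- !core_mask[upper.tri(core_mask)]
  }
  boot <- vapply(seq_len(n_boot), function(i) {
    idx <- sample(length(mats), replace = TRUE)
    bm <- rowMeans(tri[, idx, drop = FALSE])
    cor(bm[keepmask], tvec[keepmask])
  }, 0)
  alpha <- (1 - ci_level) / 2
  bootstrap_ci <- unname(quantile(boot, c(alpha, 1 - alpha)))

  structure(list(group_r = group_r, null_threshold = null_threshold,
                 null = null, bootstrap_ci = bootstrap_ci, boot = boot,
                 n_participants = length(mats),
                 n_iterations = if (exact) nrow(perms) else n_perm,
                 significant = group_r > null_threshold),
            class = "group_structure_result")
}

#' @export
print.group_structure_result <- function(x, ...) {
  cat(sprintf(paste0("group structure match: r = %.3f ",
                     "(95th pct null = %.3f, %s), bootstrap CI [%.3f, %.3f], ",
                     "n = %d\n"),
              x$group_r, x$null_threshold,
              if (x$significant) "significant" else "n.s.",
              x$bootstrap_ci[1], x$bootstrap_ci[2], x$n_participants))
  invisible(x)
}

#' Per-participant structure regression controlling for visual similarity
#'
#' Ordinary least squares of a participant's dissimilarities on the
#' ground-truth structure matrix and a nuisance visual-dissimilarity
#' matrix, over upper-triangle entries. The coefficient on the structure
#' predictor (`beta_structure`) indexes structure knowledge net of visual
#' confusability.
#'
#' @param rdm participant `feature_rdm` (z-scored).
#' @param true ground-truth `feature_rdm`.
#' @param visual nuisance visual dissimilarity matrix (`feature_rdm` or
#'   plain symmetric matrix).
#' @param mask_core,core_ids optionally exclude core-feature entries.
#' @return A `participant_structure_result`: list with `beta_structure`,
#'   `beta_visual`, `intercept`, `t_structure`, `collinear` (logical),
#'   and the fitted `lm` object.
#' @export
participant_structure_regression <- function(rdm, true, visual,
                                             mask_core = FALSE,
                                             core_ids = NULL) {
  y <- upper_tri_vec(rdm_mat(rdm))
  x1 <- upper_tri_vec(rdm_mat(true))
  x2 <- upper_tri_vec(rdm_mat(visual))
  keep <- rep(TRUE, length(y))
  if (mask_core) {
    n_feat <- nrow(rdm_mat(true))
    ci <- as.integer(core_ids) + 1L
    cm <- outer(seq_len(n_feat) %in% ci, seq_len(n_feat) %in% ci, "|")
    keep <- !cm[upper.tri(cm)]
  }
  y <- y[keep]; x1 <- zscore(x1[keep]); x2 <- zscore(x2[keep])
  if (anyNA(x1) || anyNA(x2) || abs(cor(x1, x2)) > 0.999) {
    return(structure(list(beta_structure = NA_real_, beta_visual = NA_real_,
                          intercept = NA_real_, t_structure = NA_real_,
                          collinear = TRUE, fit = NULL),
                     class = "participant_structure_result"))
  }
  fit <- lm(y ~ x1 + x2)
  cf <- coef(summary(fit))
  structure(list(beta_structure = cf["x1", "Estimate"],
                 beta_visual = cf["x2", "Estimate"],
                 intercept = cf["(Intercept)", "Estimate"],
                 t_structure = cf["x1", "t value"],
                 collinear = FALSE, fit = fit),
            class = "participant_structure_result")
}

#' Feature-selection accuracy (correct core features out of 3)
#'
#' @param choices exactly 3 distinct chosen feature labels/ids.
#' @param core_ids the 3 core feature labels/ids.
#' @return Fraction of choices that are core features: 0, 1/3, 2/3, or 1.
#' @export
selection_accuracy <- function(choices, core_ids) {
  if (length(choices) != 3 || anyDuplicated(choices))
    stop("choices must be 3 distinct features")
  mean(choices %in% core_ids)
}

#' Condition-level regression model for task performance
#'
#' Fits the group-comparison models used for behavioral outcomes: a linear
#' model for continuous outcomes (missing-feature accuracy, arrangement
#' structure betas) or a binomial logistic model for the feature-selection
#' score, which is a count of correctly selected core features out of 3
#' attempts. Condition enters as a categorical predictor against a declared
#' baseline level; optional numeric covariates (e.g. earlier learning
#' accuracy, total sleep time, cue counts) are appended. The model-level
#' test compares the full model to one without the condition factor
#' (F-test for linear, likelihood-ratio chi-square for logistic).
#'
#' @param outcome per-participant outcome. Linear: numeric. Logistic:
#'   integer counts 0-3, or fractions in {0, 1/3, 2/3, 1} (converted).
#' @param condition character/factor of condition labels.
#' @param baseline condition level to treat as the reference.
#' @param model_type `"linear"` or `"logistic"`.
#' @param covariates optional data.frame of numeric covariates.
#' @param n_trials binomial denominator for the logistic model (default 3).
#' @return A `condition_model_result`: list with `model_type`,
#'   `coefficients` (estimate, se, statistic, p per term), `model_test`
#'   (statistic, df, p for the condition factor), and the fitted model.
#' @export
condition_model <- function(outcome, condition, baseline,
                            model_type = c("linear", "logistic"),
                            covariates = NULL, n_trials = 3) {
  model_type <- match.arg(model_type)
  condition <- as.factor(condition)
  if (!baseline %in% levels(condition))
    stop("baseline level '", baseline, "' absent from condition labels")
  condition <- stats::relevel(condition, ref = baseline)
  dat <- data.frame(.outcome = outcome, .condition = condition)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(outcome))
    dat <- cbind(dat, covariates)
  }
  covnames <- if (is.null(covariates)) character(0) else names(covariates)
  rhs <- paste(c(".condition", covnames), collapse = " + ")
  rhs_red <- if (length(covnames)) paste(covnames, collapse = " + ") else "1"

  if (model_type == "linear") {
    fit <- lm(as.formula(paste(".outcome ~", rhs)), data = dat)
    red <- lm(as.formula(paste(".outcome ~", rhs_red)), data = dat)
    an <- anova(red, fit)
    model_test <- list(statistic = an$F[2], df = c(an$Df[2], an$Res.Df[2]),
                       p = an$`Pr(>F)`[2])
    cf <- coef(summary(fit))
  } else {
    k <- outcome
    if (max(k, na.rm = TRUE) <= 1 && any(k %% 1 != 0)) k <- round(k * n_trials)
    stopifnot(all(k >= 0), all(k <= n_trials))
    dat$.k <- k
    fit <- glm(as.formula(paste("cbind(.k, n_trials - .k) ~", rhs)),
               family = binomial(), data = dat)
    red <- glm(as.formula(paste("cbind(.k, n_trials - .k) ~", rhs_red)),
               family = binomial(), data = dat)
    an <- anova(red, fit, test = "Chisq")
    model_test <- list(statistic = an$Deviance[2], df = an$Df[2],
                       p = an$`Pr(>Chi)`[2])
    cf <- coef(summary(fit))
  }
  colnames(cf) <- c("estimate", "se", "statistic", "p")
  structure(list(model_type = model_type, baseline = baseline,
                 coefficients = cf, model_test = model_test, fit = fit),
            class = "condition_model_result")
}

#' @export
print.condition_model_result <- function(x, ...) {
  cat(sprintf("condition model (%s, baseline = %s)\n", x$model_type, x$baseline))
  print(round(x$coefficients, 4))
  cat(sprintf("condition factor test: stat = %.3f, p = %.4g\n",
              x$model_test$statistic, x$model_test$p))
  invisible(x)
}
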