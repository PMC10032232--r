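#' Greedy LD pruning of common SNPs
#'
#' Walks SNPs in genomic order; a SNP is dropped when its squared
#' correlation with any retained SNP within the window exceeds the
#' threshold (in-sample r-squared).
#'
#' @param genotypes individuals x SNPs allele-count matrix.
#' @param chrom,pos per-SNP chromosome and position.
#' @param r2_max prune threshold on pairwise r-squared (default 0.5).
#' @param window_bp window width in bp (default 1,000 kb).
#' @return integer indices of the retained SNPs.
#' @export
ld_prune <- function(genotypes, chrom, pos, r2_max = 0.5, window_bp = 1e6) {
  G <- as.matrix(genotypes)
  ord <- order(chrom, pos)
  kept <- integer(0)
  for (j in ord) {
    near <- kept[chrom[kept] == chrom[j] & abs(pos[kept] - pos[j]) <= window_bp]
    drop <- FALSE
    for (k in near) {
      r <- suppressWarnings(stats::cor(G[, j], G[, k]))
      if (!is.na(r) && r^2 > r2_max) {
        drop <- TRUE
        break
      }
    }
    if (!drop) kept <- c(kept, j)
  }
  sort(kept)
}

#' Genetic principal components from LD-pruned common SNPs
#'
#' Common SNPs are LD-pruned, then allele counts are centered at twice
#' the allele frequency and standardized by `sqrt(2 f (1-f))`; the top k
#' left singular vectors (scaled by their singular values) are the PC
#' scores used to adjust for population structure.
#'
#' @param genotypes individuals x common-SNP allele counts (MAF > 1%).
#' @param chrom,pos per-SNP coordinates for pruning.
#' @param k number of components (default 5).
#' @param r2_max,window_bp pruning parameters, see [ld_prune()].
#' @return individuals x k score matrix (columns `PC1..PCk`), with the
#'   retained SNP indices in attribute `"kept"`.
#' @export
compute_pcs <- function(genotypes, chrom, pos, k = 5, r2_max = 0.5,
                        window_bp = 1e6) {
  kept <- ld_prune(genotypes, chrom, pos, r2_max, window_bp)
  G <- as.matrix(genotypes[, kept, drop = FALSE])
  G[is.na(G)] <- 0
  f <- colMeans(G) / 2
  ok <- f > 0 & f < 1
  G <- G[, ok, drop = FALSE]
  f <- f[ok]
  Z <- sweep(G, 2, 2 * f, "-")
  Z <- sweep(Z, 2, sqrt(2 * f * (1 - f)), "/")
  sv <- svd(Z, nu = min(dim(Z)), nv = 0)
  rank <- sum(sv$d > max(dim(Z)) * .Machine$double.eps * sv$d[1])
  if (k > rank) {
    stop("requested ", k, " components but the genotype matrix has rank ",
         rank)
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(genotypes)
  attr(scores, "kept") <- kept[ok]
  scores
}

#' Residualize predictors on principal components
#'
#' Each predictor column is regressed (ordinary least squares, with
#' intercept) on the PCs using the fit rows only; the fitted PC effect is
#' then subtracted from every row, so coefficients estimated on a
#' training fold are applied unchanged to held-out individuals.
#'
#' @param predictors individuals x predictors numeric matrix.
#' @param pcs individuals x k PC score matrix.
#' @param fit_ids rows (indices or rownames) used to estimate PC effects;
#'   defaults to all rows.
#' @return residualized predictor matrix, same shape and dimnames.
#' @export
residualize <- function(predictors, pcs, fit_ids = seq_len(nrow(predictors))) {
  if (length(fit_ids) == 0) stop("fit_ids is empty")
  X <- as.matrix(predictors)
  D <- cbind(1, as.matrix(pcs))
  qr_fit <- qr(D[fit_ids, , drop = FALSE])
  if (qr_fit$rank < ncol(D)) stop("collinear principal components")
  beta <- qr.coef(qr_fit, X[fit_ids, , drop = FALSE])
  res <- X - D %*% beta
  dimnames(res) <- dimnames(X)
  attr(res, "family") <- attr(predictors, "family")
  res
}

#' Fit a benchmark or expanded logistic risk model
#'
#' The benchmark model is an unpenalized logistic regression on the
#' known-risk predictors. The expanded model adds the meta-feature burden
#' block and solves the L1-penalized likelihood with the penalty applied
#' to the meta columns only (penalty factor 0 on known-risk columns);
#' unless a penalty is supplied, its strength is chosen by nested
#' cross-validation on the training rows (binomial deviance over a
#' log-spaced lambda path). Predictors are standardized internally for
#' the penalized fit and coefficients reported on the original scale.
#'
#' @param outcome binary vector.
#' @param known individuals x known-risk predictor matrix (may have zero
#'   columns).
#' @param meta individuals x meta-feature burden matrix (expanded only).
#' @param kind `"benchmark"` or `"expanded"`.
#' @param training_ids rows used to fit (default all).
#' @param penalty optional fixed lambda; `NULL` = nested-CV selection.
#' @param inner_folds nested CV folds (default 5).
#' @param lambda_choice `"min"` (deviance-minimizing, default) or `"1se"`.
#' @param seed seed controlling the nested fold assignment.
#' @return a `risk_model` list: `kind`, `coefficients` (named, incl.
#'   `(Intercept)`), `lambda`, `separation` flag.
#' @export
fit_model <- function(outcome, known, meta = NULL,
                      kind = c("expanded", "benchmark"),
                      training_ids = seq_along(outcome),
                      penalty = NULL, inner_folds = 5,
                      lambda_choice = c("min", "1se"), seed = 1) {
  kind <- match.arg(kind)
  lambda_choice <- match.arg(lambda_choice)
  y <- outcome[training_ids]
  if (length(unique(y)) < 2) stop("training set must contain both classes")
  known <- as.matrix(known)
  if (is.null(colnames(known)) && ncol(known) > 0) {
    colnames(known) <- paste0("known", seq_len(ncol(known)))
  }
  Xk <- known[training_ids, , drop = FALSE]

  if (kind == "benchmark" || is.null(meta) || ncol(meta) == 0) {
    fit <- suppressWarnings(stats::glm.fit(cbind("(Intercept)" = 1, Xk), y,
                                           family = stats::binomial()))
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    sep <- !fit$converged || any(abs(cf[-1]) > 15)
    if (sep) warning("possible separation in benchmark fit")
    return(structure(list(kind = "benchmark", coefficients = cf,
                          lambda = NULL, separation = sep),
                     class = "risk_model"))
  }

  meta <- as.matrix(meta)
  Xm <- meta[training_ids, , drop = FALSE]
  X <- cbind(Xk, Xm)
  pf <- c(rep(0, ncol(Xk)), rep(1, ncol(Xm)))
  if (is.null(penalty)) {
    foldid <- stratified_folds(y, inner_folds, new_seed(seed, 777L))
    cvfit <- glmnet::cv.glmnet(X, y, family = "binomial",
                               penalty.factor = pf, foldid = foldid,
                               type.measure = "deviance",
                               standardize = TRUE)
    lambda <- if (lambda_choice == "min") cvfit$lambda.min else cvfit$lambda.1se
    gfit <- cvfit$glmnet.fit
  } else {
    lambda <- penalty
    gfit <- glmnet::glmnet(X, y, family = "binomial", penalty.factor = pf,
                           lambda = penalty, standardize = TRUE,
                           thresh = 1e-10)
  }
  cf <- as.vector(stats::coef(gfit, s = lambda, exact = FALSE))
  names(cf) <- c("(Intercept)", colnames(X))
  structure(list(kind = "expanded", coefficients = cf, lambda = lambda,
                 separation = FALSE),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  nz <- sum(x$coefficients[-1] != 0)
  cat("risk_model (", x$kind, "): ", length(x$coefficients) - 1,
      " predictors, ", nz, " nonzero", sep = "")
  if (!is.null(x$lambda)) cat(", lambda =", signif(x$lambda, 3))
  cat("\n")
  invisible(x)
}

#' Linear risk score of a fitted model on new data
#'
#' @param object a `risk_model`.
#' @param known,meta predictor blocks aligned with the fit.
#' @param ... unused.
#' @return per-individual linear predictor (log-odds scale).
#' @export
predict.risk_model <- function(object, known, meta = NULL, ...) {
  X <- cbind(1, as.matrix(known))
  if (object$kind == "expanded" && !is.null(meta) && ncol(meta) > 0) {
    X <- cbind(X, as.matrix(meta))
  }
  cf <- object$coefficients
  if (ncol(X) != length(cf)) stop("predictor blocks do not match the fit")
  as.vector(X %*% cf)
}

#' Repeated stratified cross-validated AUC of a risk model
#'
#' Five iterations of 5-fold cross-validation by default. All data-driven
#' choices are confined to each training fold: low-count meta-feature
#' pruning, PC residualization coefficients, nested penalty selection and
#' the model fit itself use training rows only, then score the held-out
#' fold. The summary AUC is the mean over all repeat-by-fold AUCs.
#'
#' @param outcome binary vector.
#' @param known known-risk predictor matrix.
#' @param meta meta-feature burden matrix (`NULL` for benchmark).
#' @param pcs optional PC score matrix for residualization.
#' @param kind `"benchmark"` or `"expanded"`.
#' @param repeats,folds CV geometry (defaults 5 and 5).
#' @param seed seed for fold assignment and nested selection.
#' @param min_count training-fold feature-pruning threshold (default 5).
#' @param residualize_predictors subtract PC effects (default `TRUE` when
#'   `pcs` given).
#' @param residualize_scope `"fold"` (PC effects re-estimated per training
#'   fold, default) or `"whole"` (estimated once on all rows).
#' @param lambda_choice passed to [fit_model()].
#' @param keep_fold_models retain per-fold coefficient vectors (for
#'   leakage diagnostics).
#' @return a `cv_result` list: `auc` data.frame (`repeat_`, `fold`,
#'   `auc`), `mean_auc`, `repeats`, `folds`, `seed`, optional
#'   `fold_models`.
#' @export
cross_validate <- function(outcome, known, meta = NULL, pcs = NULL,
                           kind = c("expanded", "benchmark"),
                           repeats = 5, folds = 5, seed = 1,
                           min_count = 5,
                           residualize_predictors = !is.null(pcs),
                           residualize_scope = c("fold", "whole"),
                           lambda_choice = "min",
                           keep_fold_models = FALSE) {
  kind <- match.arg(kind)
  residualize_scope <- match.arg(residualize_scope)
  y <- as.integer(outcome)
  if (min(table(y)) < folds) stop("need at least `folds` members per class")
  known <- as.matrix(known)
  use_meta <- kind == "expanded" && !is.null(meta) && ncol(meta) > 0
  if (use_meta) meta <- as.matrix(meta)

  rows <- expand.grid(fold = seq_len(folds), repeat_ = seq_len(repeats))
  aucs <- numeric(nrow(rows))
  models <- if (keep_fold_models) vector("list", nrow(rows)) else NULL

  for (r in seq_len(repeats)) {
    assign_r <- stratified_folds(y, folds, new_seed(seed, 1000L + r))
    for (f in seq_len(folds)) {
      i <- (r - 1) * folds + f
      test <- which(assign_r == f)
      train <- which(assign_r != f)
      if (length(unique(y[test])) < 2) stop("fold with a single class")

      Xk <- known
      Xm <- if (use_meta) {
        pr <- prune_low_count_features(meta, train, min_count)
        pr
      } else NULL
      if (residualize_predictors && !is.null(pcs)) {
        fit_rows <- if (residualize_scope == "fold") train
                    else seq_along(y)
        if (ncol(Xk) > 0) Xk <- residualize(Xk, pcs, fit_rows)
        if (use_meta && ncol(Xm) > 0) Xm <- residualize(Xm, pcs, fit_rows)
      }
      m <- fit_model(y, Xk, Xm, kind = kind, training_ids = train,
                     seed = new_seed(seed, 2000L + i),
                     lambda_choice = lambda_choice)
      score <- predict(m,
                       known = Xk[test, , drop = FALSE],
                       meta = if (use_meta) Xm[test, , drop = FALSE])
      aucs[i] <- auc_score(score, y[test])
      if (keep_fold_models) {
        models[[i]] <- list(repeat_ = r, fold = f,
                            coefficients = m$coefficients,
                            lambda = m$lambda)
      }
    }
  }
  structure(list(auc = data.frame(repeat_ = rows$repeat_, fold = rows$fold,
                                  auc = aucs),
                 mean_auc = mean(aucs),
                 repeats = repeats, folds = folds, seed = seed,
                 fold_models = models),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result: mean AUC ", round(x$mean_auc, 3), " over ",
      x$repeats, " x ", x$folds, "-fold CV (sd ",
      round(stats::sd(x$auc$auc), 3), ")\n", sep = "")
  invisible(x)
}

#' Per-predictor Wald association scan
#'
#' For each predictor, a logistic regression of the outcome on intercept,
#' predictor and (optionally) the top PCs; the Wald statistic is the
#' estimate over its standard error with a two-sided p from the standard
#' normal. Significance is Bonferroni-controlled at
#' `alpha / n_tests` where `n_tests` counts the non-degenerate predictors
#' scanned.
#'
#' @param predictors individuals x predictors matrix.
#' @param outcome binary vector.
#' @param pcs optional PC adjustment matrix.
#' @param alpha family-wise level (default 0.05).
#' @return data.frame: `predictor`, `estimate`, `se`, `p`, `n_tests`,
#'   `bonferroni_threshold`, `significant` (`NA` for zero-variance
#'   predictors, which do not count toward `n_tests`).
#' @export
association_scan <- function(predictors, outcome, pcs = NULL, alpha = 0.05) {
  X <- as.matrix(predictors)
  y <- as.integer(outcome)
  p <- ncol(X)
  est <- se <- pv <- rep(NA_real_, p)
  degenerate <- apply(X, 2, function(v) stats::var(v) == 0)
  for (j in which(!degenerate)) {
    w <- logistic_wald(y, X[, j], pcs)
    est[j] <- w[["estimate"]]
    se[j] <- w[["se"]]
    pv[j] <- w[["p"]]
  }
  n_tests <- sum(!degenerate & !is.na(pv))
  thr <- alpha / n_tests
  data.frame(
    predictor = colnames(X) %||% paste0("V", seq_len(p)),
    estimate = est, se = se, p = pv,
    n_tests = n_tests,
    bonferroni_threshold = thr,
    significant = ifelse(is.na(pv), NA, pv < thr),
    stringsAsFactors = FALSE
  )
}

#' Polygenic risk score from a published weight table
#'
#' Scores are weighted sums of effect-allele counts. A weight whose SNP
#' matches a genotyped variant is oriented by its effect allele: counts
#' are used as-is when the effect allele is the alternate allele and
#' flipped (`2 - x`) when it is the reference allele. Weights that cannot
#' be resolved are skipped and reported.
#'
#' @param genotypes individuals x variants allele counts, columns named by
#'   variant id.
#' @param variants VariantRecord data.frame (`id`, `ref`, `alt`).
#' @param weights data.frame: `snp_id`, `effect_allele`, `weight`.
#' @return list: `score` (per individual), `n_used`, `skipped` (snp ids).
#' @export
prs_score <- function(genotypes, variants, weights) {
  score <- rep(0, nrow(genotypes))
  names(score) <- rownames(genotypes)
  skipped <- character(0)
  for (i in seq_len(nrow(weights))) {
    j <- match(weights$snp_id[i], variants$id)
    if (is.na(j)) {
      skipped <- c(skipped, weights$snp_id[i])
      next
    }
    x <- as.numeric(genotypes[, match(weights$snp_id[i], colnames(genotypes))])
    x[is.na(x)] <- 0
    ea <- weights$effect_allele[i]
    if (ea == variants$alt[j]) {
      dose <- x
    } else if (ea == variants$ref[j]) {
      dose <- 2 - x
    } else {
      skipped <- c(skipped, weights$snp_id[i])
      next
    }
    score <- score + weights$weight[i] * dose
  }
  list(score = score, n_used = nrow(weights) - length(skipped),
       skipped = skipped)
}
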