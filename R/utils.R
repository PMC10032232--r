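#' contextburden: context-based aggregation of rare germline variants
#'
#' Burden aggregation of rare variants over gene, 1 Mb window and SBS-96
#' meta-features; benchmark and Lasso-expanded logistic risk models with
#' principal-component residualization; repeated cross-validated AUC;
#' per-predictor Wald association scans; simulation-based power for burden
#' tests; and a synthetic-cohort generator.
#'
#' @keywords internal
#' @aliases contextburden-package
#' @importFrom stats glm glm.fit binomial plogis pnorm qnorm rbinom rbeta
#'   rpois runif rnorm var sd cor coef predict uniroot setNames
#' @importFrom utils read.delim write.table head
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")
DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A")

# Derive a child RNG seed from a base seed and an integer tag; kept inside
# the 32-bit signed range R requires of set.seed().
new_seed <- function(seed, tag) {
  as.integer((abs(as.double(seed)) * 7919 + as.double(tag) * 104729) %% 2147483629)
}

#' Area under the ROC curve of a score against a binary outcome
#'
#' Rank-based (Mann-Whitney) AUC; tied scores count one half, so the value
#' equals the proportion of case-control pairs in which the case scores
#' higher, plus half the proportion of ties.
#'
#' @param score numeric risk score, higher = more case-like.
#' @param y binary outcome (0/1 or logical), same length as `score`.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(score, y) {
  y <- as.integer(y)
  if (length(score) != length(y)) stop("score and y lengths differ")
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC requires both classes present")
  r <- rank(score, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Wald test of a single predictor in a logistic model, optionally adjusted
# for covariates. Returns estimate, standard error, and two-sided p from
# the standard normal. Degenerate (aliased) predictors return NAs.
logistic_wald <- function(y, x, covar = NULL) {
  X <- cbind(1, x, covar)
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  p <- fit$rank
  piv <- fit$qr$pivot[seq_len(p)]
  if (!(2L %in% piv)) {
    return(c(estimate = NA_real_, se = NA_real_, p = NA_real_))
  }
  covm <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  pos <- match(2L, piv)
  est <- unname(fit$coefficients[2L])
  se <- sqrt(covm[pos, pos])
  c(estimate = est, se = se, p = 2 * stats::pnorm(-abs(est / se)))
}

# Stratified fold assignment: within each outcome class, individuals are
# shuffled and dealt round-robin into `folds` folds.
stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
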