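#' Pick the burden feature whose mean is nearest the grand mean
#'
#' The power exemplar is a category with a typical count: among features
#' of the given family, the one whose per-individual mean burden is
#' closest to the mean over all those features (ties broken by catalog
#' order).
#'
#' @param burdens burden matrix with a `"family"` attribute.
#' @param family feature family to search (default `"sbs96"`).
#' @return the feature id.
#' @export
select_target_feature <- function(burdens, family = "sbs96") {
  fam <- attr(burdens, "family")
  cols <- if (is.null(fam)) colnames(burdens) else names(fam)[fam == family]
  if (length(cols) == 0) stop("no features of family ", family)
  m <- colMeans(burdens[, cols, drop = FALSE])
  cols[which.min(abs(m - mean(m)))]
}

#' Background log odds ratios for the non-target meta-features
#'
#' For every feature except the target, the slope of a univariate
#' logistic regression of the observed outcome on that feature. The
#' resulting vector is held fixed across all power iterations.
#'
#' @param burdens burden matrix.
#' @param outcome binary vector.
#' @param target feature id to exclude (its effect is the quantity under
#'   study); `NULL` = none excluded.
#' @return named numeric vector of slopes; zero-variance features get 0
#'   with a warning.
#' @export
fit_background_effects <- function(burdens, outcome, target = NULL) {
  cols <- setdiff(colnames(burdens), target)
  beta <- stats::setNames(numeric(length(cols)), cols)
  y <- as.integer(outcome)
  degen <- character(0)
  for (cl in cols) {
    x <- burdens[, cl]
    if (stats::var(x) == 0) {
      degen <- c(degen, cl)
      next
    }
    beta[cl] <- logistic_wald(y, x)[["estimate"]]
  }
  if (length(degen)) {
    warning(length(degen), " zero-variance feature(s) assigned effect 0")
  }
  beta
}

#' Configuration of the simulation-based power analysis
#'
#' @param target_feature feature id whose effect is varied (e.g. the
#'   `"G[T>C]T"` SBS-96 category).
#' @param or_grid odds ratios to evaluate (all > 0).
#' @param n_grid numbers of cases n (each iteration samples n cases and n
#'   controls).
#' @param iterations Monte-Carlo iterations per grid point (default 500).
#' @param alpha_family family-wise level (default 0.05).
#' @param n_tests_for_bonferroni divisor of the Bonferroni threshold
#'   (number of predictors in the corresponding association scan).
#' @param prevalence target expected case fraction used to calibrate the
#'   generative intercept; `NULL` leaves the intercept at 0 (the
#'   generative model without an explicit intercept term).
#' @param max_redraws redraw cap per iteration when too few cases arise.
#' @param seed RNG seed for the whole grid.
#' @return a `power_config` list.
#' @export
power_config <- function(target_feature, or_grid, n_grid, iterations = 500,
                         alpha_family = 0.05, n_tests_for_bonferroni = 100,
                         prevalence = NULL, max_redraws = 100, seed = 1) {
  stopifnot(all(or_grid > 0), iterations >= 1, all(n_grid >= 1),
            n_tests_for_bonferroni >= 1)
  structure(as.list(environment()), class = "power_config")
}

#' Simulation-based power of the Wald burden test
#'
#' Per iteration: case status is drawn for every individual from
#' `Bernoulli(plogis(c + log(OR) * S_target + S_other %*% beta))` with the
#' background counts and effects held fixed; n cases and n controls are
#' sampled without replacement; a Wald test of the target feature is
#' performed and compared against the Bonferroni threshold
#' `alpha_family / n_tests_for_bonferroni`. Power at a grid point is the
#' proportion of significant iterations. The intercept c is calibrated
#' per odds ratio so the expected case fraction equals the configured
#' prevalence (c = 0 when none is configured).
#'
#' @param config a [power_config()].
#' @param burdens burden matrix containing the target feature (actual
#'   cohort counts).
#' @param beta background effects from [fit_background_effects()]
#'   (features absent from it contribute 0).
#' @param pcs optional PC adjustment included in each Wald test.
#' @return a `power_result` data.frame: `or_`, `n`, `power`, `se`
#'   (binomial), `redraws`.
#' @export
simulate_power <- function(config, burdens, beta = NULL, pcs = NULL) {
  tf <- config$target_feature
  if (!tf %in% colnames(burdens)) {
    stop("target feature ", tf, " not present in the burden matrix")
  }
  S <- burdens[, tf]
  eta_bg <- rep(0, nrow(burdens))
  if (!is.null(beta) && length(beta) > 0) {
    use <- intersect(names(beta), setdiff(colnames(burdens), tf))
    if (length(use)) {
      eta_bg <- as.vector(as.matrix(burdens[, use, drop = FALSE]) %*% beta[use])
    }
  }
  thr <- config$alpha_family / config$n_tests_for_bonferroni
  set.seed(new_seed(config$seed, 606L))

  grid <- expand.grid(or_ = config$or_grid, n = config$n_grid)
  grid$power <- NA_real_
  grid$se <- NA_real_
  grid$redraws <- 0L
  N <- length(S)
  for (g in seq_len(nrow(grid))) {
    a <- log(grid$or_[g])
    n <- grid$n[g]
    eta0 <- a * S + eta_bg
    cc <- 0
    if (!is.null(config$prevalence)) {
      cc <- stats::uniroot(function(c0) {
        mean(stats::plogis(c0 + eta0)) - config$prevalence
      }, interval = c(-30, 30))$root
    }
    p_case <- stats::plogis(cc + eta0)
    sig <- logical(config$iterations)
    redraws <- 0L
    for (it in seq_len(config$iterations)) {
      tries <- 0L
      repeat {
        y <- stats::rbinom(N, 1, p_case)
        if (sum(y == 1) >= n && sum(y == 0) >= n) break
        tries <- tries + 1L
        if (tries > config$max_redraws) {
          stop("could not draw ", n, " cases after ", config$max_redraws,
               " redraws; achievable n is about ",
               floor(min(mean(p_case), 1 - mean(p_case)) * N))
        }
      }
      redraws <- redraws + tries
      idx <- c(sample(which(y == 1), n), sample(which(y == 0), n))
      w <- logistic_wald(y[idx], S[idx],
                         if (!is.null(pcs)) pcs[idx, , drop = FALSE])
      sig[it] <- !is.na(w[["p"]]) && w[["p"]] < thr
    }
    ph <- mean(sig)
    grid$power[g] <- ph
    grid$se[g] <- sqrt(ph * (1 - ph) / config$iterations)
    grid$redraws[g] <- redraws
  }
  class(grid) <- c("power_result", "data.frame")
  grid
}

#' Closed-form two-proportion power approximation
#'
#' For a binary exposure with control-arm prevalence `p0` and case-arm
#' prevalence implied by the odds ratio, the normal-approximation power
#' of a two-sided two-proportion test with n per arm. Used as an
#' independent cross-check of the simulation engine.
#'
#' @param p0 exposure prevalence among controls.
#' @param or_ exposure odds ratio (cases vs controls).
#' @param n per-arm sample size.
#' @param alpha two-sided significance level.
#' @return approximate power.
#' @export
two_proportion_power <- function(p0, or_, n, alpha) {
  p1 <- p0 * or_ / (1 - p0 + p0 * or_)
  pbar <- (p0 + p1) / 2
  za <- stats::qnorm(1 - alpha / 2)
  num <- abs(p1 - p0) * sqrt(n) - za * sqrt(2 * pbar * (1 - pbar))
  stats::pnorm(num / sqrt(p1 * (1 - p1) + p0 * (1 - p0)))
}
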