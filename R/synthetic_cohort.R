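#' Configuration for the synthetic-cohort generator
#'
#' Defines the statistical structure of a simulated case-control cohort:
#' a random reference genome, rare variants (ancestral MAF below 1%) with
#' realistic trinucleotide contexts, a block of common SNPs carrying
#' Balding-Nichols population substructure, gene/window/SBS-96
#' annotations, and case status from a logistic model on chosen
#' meta-feature burdens and known-risk allele counts.
#'
#' @param n_individuals cohort size.
#' @param n_rare_variants number of rare variants (the model's d).
#' @param n_common_snps number of common SNPs (structure + known risk).
#' @param n_chromosomes,chrom_length_bp genome shape.
#' @param maf_rare_range ancestral rare-variant MAF range, inside (0, 0.01).
#' @param maf_common_range common-SNP MAF range, inside (0.01, 0.5).
#' @param n_subpopulations number of subpopulations (>= 1).
#' @param fst_like_divergence Balding-Nichols divergence parameter F in
#'   `[0, 1)`; must be 0 when there is a single subpopulation. Subpopulation
#'   allele frequencies for common SNPs are drawn from
#'   Beta(f(1-F)/F, (1-f)(1-F)/F) around the ancestral frequency f.
#' @param effect_table data.frame with columns `predictor` (a burden
#'   feature id or known-risk variant id) and `log_or`; empty = null model.
#' @param baseline_log_odds intercept of the case-status logistic model.
#' @param n_known_risk_snps how many common SNPs are designated known risk
#'   variants (their allele counts become benchmark-model predictors).
#' @param n_genes,gene_fraction susceptibility-gene panel size and the
#'   fraction of rare variants assigned to a panel gene.
#' @param missing_rate genotype missingness rate (dense representation
#'   only).
#' @param indel_fraction fraction of rare variants simulated as 1-bp
#'   insertions (no SBS-96 context).
#' @param qc_violator_fraction fraction of variants given QC-metric values
#'   that violate the WES filter thresholds, so filter tests have positive
#'   cases.
#' @param family_history_rate,family_history_case_odds_multiplier marginal
#'   family-history rate and its odds multiplier among cases.
#' @param birth_year_range,diagnosis_age_range,censoring_age_range marginal
#'   distributions (uniform) for the phenotype table.
#' @param seed integer RNG seed; every generator draw derives from it.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_individuals = 2000,
                       n_rare_variants = 5000,
                       n_common_snps = 200,
                       n_chromosomes = 2,
                       chrom_length_bp = 5e6,
                       maf_rare_range = c(5e-4, 0.01),
                       maf_common_range = c(0.05, 0.5),
                       n_subpopulations = 1,
                       fst_like_divergence = 0,
                       effect_table = data.frame(predictor = character(0),
                                                 log_or = numeric(0)),
                       baseline_log_odds = -1,
                       n_known_risk_snps = 5,
                       n_genes = 20,
                       gene_fraction = 0.3,
                       missing_rate = 0,
                       indel_fraction = 0,
                       qc_violator_fraction = 0,
                       family_history_rate = 0.1,
                       family_history_case_odds_multiplier = 1,
                       birth_year_range = c(1940, 1970),
                       diagnosis_age_range = c(40, 70),
                       censoring_age_range = c(45, 80),
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(
    n_individuals >= 1, n_rare_variants >= 1, n_chromosomes >= 1,
    length(maf_rare_range) == 2, length(maf_common_range) == 2,
    maf_rare_range[1] > 0, maf_rare_range[2] <= 0.01,
    maf_rare_range[1] <= maf_rare_range[2],
    maf_common_range[1] >= 0.01, maf_common_range[2] <= 0.5,
    maf_common_range[1] <= maf_common_range[2],
    n_subpopulations >= 1,
    fst_like_divergence >= 0, fst_like_divergence < 1,
    is.data.frame(effect_table),
    all(c("predictor", "log_or") %in% names(effect_table))
  )
  if (n_subpopulations == 1 && fst_like_divergence != 0) {
    stop("fst_like_divergence must be 0 with a single subpopulation")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a random reference genome
#'
#' Chromosome sequences of i.i.d. bases over A/C/G/T, reproducible from
#' the config seed.
#'
#' @param config a [sim_config()].
#' @return named character vector of chromosome sequences (names
#'   `"1"`, `"2"`, ...).
#' @export
generate_reference <- function(config) {
  if (config$chrom_length_bp < 3) {
    stop("chromosome length below 3 bp: no trinucleotide context possible")
  }
  set.seed(new_seed(config$seed, 101L))
  L <- as.integer(config$chrom_length_bp)
  seqs <- vapply(seq_len(config$n_chromosomes), function(i) {
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- as.character(seq_len(config$n_chromosomes))
  seqs
}

# Subpopulation labels: individuals split as evenly as possible, in order.
subpop_labels <- function(config) {
  rep_len(paste0("pop", seq_len(config$n_subpopulations)),
          config$n_individuals)
}

# Draw a genotype matrix given a subpop x variant frequency matrix.
# Dense when the expected density warrants it, sparse otherwise.
draw_genotypes <- function(freq, pop_index, n, sparse) {
  d <- ncol(freq)
  if (!sparse) {
    G <- matrix(0L, n, d)
    for (s in seq_len(nrow(freq))) {
      rows <- which(pop_index == s)
      G[rows, ] <- matrix(stats::rbinom(length(rows) * d, 2,
                                        rep(freq[s, ], each = length(rows))),
                          length(rows), d)
    }
    return(G)
  }
  ii <- vector("list", d)
  xx <- vector("list", d)
  for (j in seq_len(d)) {
    carriers <- integer(0)
    vals <- integer(0)
    for (s in seq_len(nrow(freq))) {
      rows <- which(pop_index == s)
      f <- freq[s, j]
      p_nz <- 1 - (1 - f)^2
      m <- stats::rbinom(1, length(rows), p_nz)
      if (m > 0) {
        who <- rows[sample.int(length(rows), m)]
        p_hom <- f^2 / p_nz
        g <- 1L + stats::rbinom(m, 1, p_hom)
        carriers <- c(carriers, who)
        vals <- c(vals, g)
      }
    }
    ii[[j]] <- carriers
    xx[[j]] <- vals
  }
  lens <- lengths(ii)
  Matrix::sparseMatrix(i = unlist(ii), j = rep.int(seq_len(d), lens),
                       x = unlist(xx), dims = c(n, d))
}

#' Generate variants and genotypes for a synthetic cohort
#'
#' Rare-variant positions are sampled without replacement from the
#' interior of each chromosome (so flanking context exists); reference
#' alleles are read off the reference; alternate alleles differ from the
#' reference. Common SNPs carry Balding-Nichols subpopulation divergence;
#' rare variants share the ancestral frequency across subpopulations.
#' Genotypes are Binomial(2, f) allele counts. QC metric fields
#' (missingness, HWE p, depth, allele balance, imputation quality) are
#' attached from benign distributions, with an optional fraction of
#' injected threshold violators.
#'
#' @param config a [sim_config()].
#' @param reference output of [generate_reference()].
#' @param sparse return rare genotypes as a sparse `Matrix` (chosen
#'   automatically by default; forced dense when `missing_rate > 0`).
#' @return list with `genotypes` (individuals x variants), `variants`
#'   (VariantRecord data.frame with `is_common` column), `subpopulation`
#'   (per-individual label), `subpop_freq` (subpopulation x variant
#'   allele-frequency matrix actually used for the draws).
#' @export
generate_genotypes <- function(config, reference, sparse = NULL) {
  set.seed(new_seed(config$seed, 202L))
  n <- config$n_individuals
  d_r <- config$n_rare_variants
  d_c <- config$n_common_snps
  n_pop <- config$n_subpopulations
  Fd <- config$fst_like_divergence
  pop <- subpop_labels(config)
  pop_index <- match(pop, unique(pop))

  L <- nchar(reference)
  usable <- sum(pmax(0L, L - 2L))
  if (d_r + d_c > usable) {
    stop("requested ", d_r + d_c, " variants but only ", usable,
         " usable interior positions exist")
  }
  # spread variants over chromosomes proportionally to usable length
  n_chr <- length(reference)
  alloc <- diff(round(seq(0, d_r + d_c, length.out = n_chr + 1)))
  chrom <- rep(names(reference), alloc)
  pos <- unlist(lapply(seq_len(n_chr), function(k) {
    sort(sample(seq(2L, L[k] - 1L), alloc[k]))
  }), use.names = FALSE)
  ref <- substring(reference[chrom], pos, pos)
  alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1), character(1))
  # interleave: designate which of the d_r + d_c variants are common
  is_common <- rep(FALSE, d_r + d_c)
  if (d_c > 0) is_common[sample.int(d_r + d_c, d_c)] <- TRUE

  variant_class <- rep("SNV", d_r + d_c)
  if (config$indel_fraction > 0) {
    rare_idx <- which(!is_common)
    n_ind <- round(config$indel_fraction * d_r)
    if (n_ind > 0) {
      ind <- sample(rare_idx, n_ind)
      alt[ind] <- paste0(ref[ind],
                         sample(DNA_BASES, n_ind, replace = TRUE))
      variant_class[ind] <- "indel"
    }
  }

  # ancestral frequencies
  f0 <- numeric(d_r + d_c)
  f0[!is_common] <- stats::runif(d_r, config$maf_rare_range[1],
                                 config$maf_rare_range[2])
  f0[is_common] <- stats::runif(d_c, config$maf_common_range[1],
                                config$maf_common_range[2])
  # subpop frequencies: Balding-Nichols on common SNPs only
  freq <- matrix(rep(f0, each = n_pop), n_pop, d_r + d_c)
  if (Fd > 0 && n_pop > 1 && d_c > 0) {
    for (j in which(is_common)) {
      a <- f0[j] * (1 - Fd) / Fd
      b <- (1 - f0[j]) * (1 - Fd) / Fd
      freq[, j] <- pmin(pmax(stats::rbeta(n_pop, a, b), 1e-6), 1 - 1e-6)
    }
  }

  dense_needed <- config$missing_rate > 0
  if (is.null(sparse)) {
    sparse <- !dense_needed && (as.double(n) * (d_r + d_c) > 2e7)
  }
  if (sparse && dense_needed) {
    stop("missing genotypes require the dense representation")
  }
  G <- draw_genotypes(freq, pop_index, n, sparse)
  if (config$missing_rate > 0) {
    miss <- stats::runif(length(G)) < config$missing_rate
    G[miss] <- NA_integer_
  }

  f_obs <- Matrix::colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(f_obs, 1 - f_obs)

  d <- d_r + d_c
  variants <- data.frame(
    chrom = chrom, pos = pos,
    id = paste(chrom, pos, ref, alt, sep = ":"),
    ref = ref, alt = alt, variant_class = variant_class,
    is_common = is_common, ancestral_freq = f0, maf = maf,
    stringsAsFactors = FALSE
  )
  variants <- attach_qc_metrics(variants, config)
  variants <- attach_annotations(variants, config)
  colnames(G) <- variants$id
  rownames(G) <- sprintf("ind%05d", seq_len(n))
  rownames(freq) <- unique(pop)
  list(genotypes = G, variants = variants, subpopulation = pop,
       subpop_freq = freq)
}

# QC metrics from benign distributions; optional injected violators give
# filter tests positive cases.
attach_qc_metrics <- function(variants, config) {
  d <- nrow(variants)
  variants$missingness <- stats::rbeta(d, 1, 40)
  variants$missingness <- pmin(variants$missingness, 0.0999)
  variants$hwe_p <- stats::runif(d, 0.001, 1)
  variants$depth <- 10L + stats::rpois(d, 25)
  variants$allele_balance_pass <- TRUE
  variants$imputation_quality <- stats::runif(d, 0.8, 1)
  fr <- config$qc_violator_fraction
  if (fr > 0) {
    k <- max(1L, round(fr * d))
    bad <- sample.int(d, k)
    mode <- sample(c("missingness", "hwe", "depth", "balance"), k,
                   replace = TRUE)
    variants$missingness[bad[mode == "missingness"]] <-
      stats::runif(sum(mode == "missingness"), 0.10, 0.5)
    variants$hwe_p[bad[mode == "hwe"]] <- 1e-15 *
      stats::runif(sum(mode == "hwe"))
    variants$depth[bad[mode == "depth"]] <-
      sample(0:6, sum(mode == "depth"), replace = TRUE)
    variants$allele_balance_pass[bad[mode == "balance"]] <- FALSE
  }
  variants
}

# Gene panel annotations on rare variants: gene id, consequence class,
# pathogenicity flag.
attach_annotations <- function(variants, config) {
  d <- nrow(variants)
  variants$gene <- NA_character_
  variants$consequence <- "other"
  variants$pathogenic_flag <- FALSE
  rare <- which(!variants$is_common)
  n_g <- round(config$gene_fraction * length(rare))
  if (config$n_genes > 0 && n_g > 0) {
    panel <- sprintf("G%03d", seq_len(config$n_genes))
    in_gene <- sample(rare, n_g)
    variants$gene[in_gene] <- sample(panel, n_g, replace = TRUE)
    variants$consequence[in_gene] <- sample(
      c("loss_of_function", "missense", "other"), n_g,
      replace = TRUE, prob = c(0.15, 0.45, 0.40))
    variants$pathogenic_flag[in_gene] <- stats::runif(n_g) < 0.05
  }
  variants
}

#' Generate case-control phenotypes from a logistic model
#'
#' Case status is Bernoulli with probability
#' `plogis(baseline_log_odds + sum(effects * predictors))`, so status
#' depends on genotypes only through the predictors named in the effect
#' table. Matching covariates (birth year, sex, diagnosis age for cases,
#' age at death/censoring) and a family-history flag are filled from the
#' configured marginal distributions.
#'
#' @param config a [sim_config()].
#' @param predictors individuals x predictors numeric matrix whose column
#'   names cover every `effect_table$predictor`.
#' @return PhenotypeTable data.frame.
#' @export
generate_phenotypes <- function(config, predictors) {
  set.seed(new_seed(config$seed, 303L))
  n <- config$n_individuals
  eff <- config$effect_table
  eta <- rep(config$baseline_log_odds, n)
  if (nrow(eff) > 0) {
    missing_ids <- setdiff(eff$predictor, colnames(predictors))
    if (length(missing_ids)) {
      stop("unknown predictor id(s) in effect_table: ",
           paste(missing_ids, collapse = ", "))
    }
    eta <- eta + as.vector(as.matrix(predictors[, eff$predictor,
                                                drop = FALSE]) %*% eff$log_or)
  }
  y <- stats::rbinom(n, 1, stats::plogis(eta))

  birth_year <- sample(seq(config$birth_year_range[1],
                           config$birth_year_range[2]), n, replace = TRUE)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  age_dx <- ifelse(y == 1,
                   stats::runif(n, config$diagnosis_age_range[1],
                                config$diagnosis_age_range[2]), NA_real_)
  age_end <- stats::runif(n, config$censoring_age_range[1],
                          config$censoring_age_range[2])
  age_end <- ifelse(y == 1, pmax(age_end, age_dx), age_end)

  fh_odds <- config$family_history_rate /
    (1 - config$family_history_rate)
  fh_odds_case <- fh_odds * config$family_history_case_odds_multiplier
  fh_p <- ifelse(y == 1, fh_odds_case / (1 + fh_odds_case),
                 config$family_history_rate)
  fam <- stats::runif(n) < fh_p

  ids <- rownames(predictors) %||% sprintf("ind%05d", seq_len(n))
  data.frame(
    individual_id = ids,
    case = y,
    cancer_type = ifelse(y == 1, "synthetic_cancer", NA_character_),
    birth_year = birth_year,
    sex = sex,
    age_at_diagnosis = age_dx,
    age_at_death_or_censoring = age_end,
    family_history = fam,
    vital_status = "alive",
    ancestry_pass = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete synthetic cohort
#'
#' Orchestrates reference, genotypes, meta-feature burdens, known-risk
#' allele counts and phenotypes into one object. The predictor block
#' offered to the phenotype model is the burden matrix (all gene, window
#' and SBS-96 features, MAF < 1%) column-bound with the designated
#' known-risk SNP allele counts, so effect tables can target either kind.
#'
#' @param config a [sim_config()].
#' @return a `synthetic_cohort` list: `config`, `reference`, `genotypes`,
#'   `variants`, `featureset`, `burdens`, `known_risk` (allele-count
#'   matrix), `phenotypes`, `subpopulation`, `true_effects`.
#' @export
simulate_cohort <- function(config) {
  reference <- generate_reference(config)
  gt <- generate_genotypes(config, reference)
  variants <- gt$variants

  featureset <- build_feature_set(variants, reference,
                                  gene_list = sprintf("G%03d",
                                                      seq_len(config$n_genes)))
  burdens <- build_burden_matrix(gt$genotypes, featureset,
                                 maf = variants$maf, maf_max = 0.01)

  set.seed(new_seed(config$seed, 404L))
  common_idx <- which(variants$is_common)
  k <- min(config$n_known_risk_snps, length(common_idx))
  kr_idx <- if (k > 0) sort(sample(common_idx, k)) else integer(0)
  known_risk <- as.matrix(gt$genotypes[, kr_idx, drop = FALSE])
  if (is.null(colnames(known_risk)) && length(kr_idx)) {
    colnames(known_risk) <- variants$id[kr_idx]
  }
  storage.mode(known_risk) <- "double"
  known_risk[is.na(known_risk)] <- 0

  predictors <- cbind(burdens, known_risk)
  phenotypes <- generate_phenotypes(config, predictors)

  structure(list(config = config,
                 reference = reference,
                 genotypes = gt$genotypes,
                 variants = variants,
                 featureset = featureset,
                 burdens = burdens,
                 known_risk = known_risk,
                 phenotypes = phenotypes,
                 subpopulation = gt$subpopulation,
                 true_effects = config$effect_table),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$phenotypes), "individuals,",
      nrow(x$variants), "variants (",
      sum(!x$variants$is_common), "rare /", sum(x$variants$is_common),
      "common ),", ncol(x$burdens), "burden features,",
      sum(x$phenotypes$case), "cases\n")
  invisible(x)
}
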