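test_that("reference generation is seed-deterministic with the stated shape", {
  cfg <- sim_config(n_individuals = 10, n_rare_variants = 5,
                    n_chromosomes = 2, chrom_length_bp = 10, seed = 1)
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(r1, r2)
  expect_length(r1, 2)
  expect_true(all(nchar(r1) == 10))
  expect_true(all(strsplit(paste(r1, collapse = ""), "")[[1]] %in%
                    c("A", "C", "G", "T")))
  cfg$chrom_length_bp <- 2
  expect_error(generate_reference(cfg), "trinucleotide")
})

test_that("reference base composition is uniform at megabase scale", {
  cfg <- sim_config(n_individuals = 10, n_rare_variants = 5,
                    n_chromosomes = 1, chrom_length_bp = 3e6, seed = 5)
  r <- generate_reference(cfg)
  freq <- table(strsplit(r[[1]], "")[[1]]) / 3e6
  # binomial 99.99% CI half-width at p = 0.25, n = 3e6 is ~0.001
  expect_true(all(abs(freq - 0.25) < 0.01))
})

test_that("genotype generation honors frequency contracts and divergence", {
  cfg <- sim_config(n_individuals = 200, n_rare_variants = 300,
                    n_common_snps = 50, n_chromosomes = 2,
                    chrom_length_bp = 1e6,
                    maf_rare_range = c(0.001, 0.01),
                    n_subpopulations = 2, fst_like_divergence = 0, seed = 3)
  ref <- generate_reference(cfg)
  gt <- generate_genotypes(cfg, ref)
  rare <- !gt$variants$is_common
  expect_true(all(gt$variants$ancestral_freq[rare] >= 0.001 &
                    gt$variants$ancestral_freq[rare] <= 0.01))
  # divergence 0: the two subpopulations draw from identical frequencies
  expect_equal(gt$subpop_freq["pop1", ], gt$subpop_freq["pop2", ])
  # reference allele equals the reference base at the variant position
  base <- substring(ref[gt$variants$chrom], gt$variants$pos, gt$variants$pos)
  expect_identical(unname(base), gt$variants$ref)
  # alt never equals ref, genotypes in 0..2
  expect_true(all(gt$variants$ref != gt$variants$alt))
  expect_true(all(as.matrix(gt$genotypes) %in% 0:2))
})

test_that("too many requested variants is an error", {
  cfg <- sim_config(n_individuals = 10, n_rare_variants = 50,
                    n_common_snps = 0, n_chromosomes = 1,
                    chrom_length_bp = 30, seed = 1)
  ref <- generate_reference(cfg)
  expect_error(generate_genotypes(cfg, ref), "usable")
})

test_that("observed rare-variant MAF stays below 2% cohort-wide", {
  co <- null_cohort()
  expect_true(all(co$variants$maf[!co$variants$is_common] < 0.02))
})

test_that("population structure is recoverable from common SNPs by PCA", {
  co <- structured_cohort()
  ci <- which(co$variants$is_common)
  pcs <- compute_pcs(as.matrix(co$genotypes[, ci]),
                     co$variants$chrom[ci], co$variants$pos[ci], k = 2)
  r <- cor(pcs[, 1], as.integer(factor(co$subpopulation)))
  expect_gt(abs(r), 0.9)
})

test_that("phenotype generation matches the logistic model it claims", {
  # null effects: prevalence is the expit of the baseline
  cfg <- sim_config(n_individuals = 10000, n_rare_variants = 5,
                    baseline_log_odds = -1, seed = 8)
  X <- matrix(0, 10000, 1, dimnames = list(NULL, "p1"))
  ph <- generate_phenotypes(cfg, X)
  expect_equal(mean(ph$case), plogis(-1), tolerance = 0.02 / plogis(-1))

  # determinism
  ph2 <- generate_phenotypes(cfg, X)
  expect_identical(ph$case, ph2$case)

  # a log(2) effect is recovered by univariate logistic regression
  cfg2 <- sim_config(n_individuals = 20000, n_rare_variants = 5,
                     baseline_log_odds = -1,
                     effect_table = data.frame(predictor = "p1",
                                               log_or = log(2)), seed = 9)
  set.seed(1)
  X2 <- matrix(rbinom(20000, 2, 0.3), ncol = 1,
               dimnames = list(NULL, "p1"))
  ph3 <- generate_phenotypes(cfg2, X2)
  fit <- glm(ph3$case ~ X2[, 1], family = binomial())
  est <- coef(summary(fit))[2, ]
  expect_lt(abs(est["Estimate"] - log(2)), 3 * est["Std. Error"])

  # unknown predictor id is an error naming it
  cfg3 <- sim_config(n_individuals = 100, n_rare_variants = 5,
                     effect_table = data.frame(predictor = "nope",
                                               log_or = 1), seed = 1)
  expect_error(generate_phenotypes(cfg3, X[1:100, , drop = FALSE]), "nope")
})

test_that("raising a predictor's log-OR raises prevalence among carriers", {
  set.seed(4)
  X <- matrix(rbinom(50000, 1, 0.3), ncol = 1, dimnames = list(NULL, "p1"))
  prev <- vapply(c(0, log(1.5), log(3)), function(b) {
    cfg <- sim_config(n_individuals = 50000, n_rare_variants = 5,
                      baseline_log_odds = -1,
                      effect_table = data.frame(predictor = "p1",
                                                log_or = b), seed = 21)
    ph <- generate_phenotypes(cfg, X)
    mean(ph$case[X[, 1] == 1])
  }, numeric(1))
  expect_true(all(diff(prev) > 0.01))
})

test_that("with one subpopulation the top PC carries no phenotype signal", {
  ps <- vapply(1:20, function(r) {
    cfg <- sim_config(n_individuals = 150, n_rare_variants = 80,
                      n_common_snps = 60, n_chromosomes = 1,
                      chrom_length_bp = 1e6, baseline_log_odds = 0,
                      seed = 3000 + r)
    co <- simulate_cohort(cfg)
    ci <- which(co$variants$is_common)
    pcs <- compute_pcs(as.matrix(co$genotypes[, ci]),
                       co$variants$chrom[ci], co$variants$pos[ci], k = 1)
    contextburden:::logistic_wald(co$phenotypes$case, pcs[, 1])[["p"]]
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.001)
})

test_that("case status depends on genotypes only through listed predictors", {
  co <- null_cohort()
  # null effect table: case status independent of every burden feature;
  # check the strongest marginal association is unremarkable for 120 tests
  sc <- association_scan(co$burdens, co$phenotypes$case)
  expect_false(any(sc$significant, na.rm = TRUE))
})

test_that("cohort simulation is fully deterministic under a fixed seed", {
  cfg <- sim_config(n_individuals = 120, n_rare_variants = 150,
                    n_common_snps = 30, n_chromosomes = 1,
                    chrom_length_bp = 1e6, seed = 99)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$reference, c2$reference)
  expect_identical(as.matrix(c1$genotypes), as.matrix(c2$genotypes))
  expect_identical(c1$phenotypes, c2$phenotypes)
  expect_identical(c1$burdens, c2$burdens)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(maf_rare_range = c(0, 0.005)))
  expect_error(sim_config(maf_rare_range = c(0.001, 0.05)))
  expect_error(sim_config(n_subpopulations = 1, fst_like_divergence = 0.1),
               "divergence")
})
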