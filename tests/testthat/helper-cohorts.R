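# Shared synthetic cohorts, simulated once per test run.

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, config) {
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulate_cohort(config)
  }
  .cohort_cache[[key]]
}

# mid-sized null cohort: no effects, single population
null_cohort <- function() {
  cached_cohort("null_mid", sim_config(
    n_individuals = 1000, n_rare_variants = 2000, n_common_snps = 80,
    n_chromosomes = 2, chrom_length_bp = 3e6, seed = 42))
}

# two-subpopulation cohort with strong divergence
structured_cohort <- function() {
  cached_cohort("structured", sim_config(
    n_individuals = 800, n_rare_variants = 500, n_common_snps = 300,
    n_chromosomes = 2, chrom_length_bp = 2e6,
    n_subpopulations = 2, fst_like_divergence = 0.1, seed = 13))
}

# 50-variant QC fixture with deliberate boundary values and violators
filter_fixture <- function() {
  data.frame(
    chrom = rep(c("1", "2", "X", "22", "3"), each = 10),
    pos = seq_len(50) * 1000L,
    id = sprintf("v%02d", 1:50),
    ref = "A",
    alt = "G",
    variant_class = rep(c("SNV", "SNV", "SNV", "indel", "SNV"), 10),
    missingness = rep(c(0, 0.05, 0.09, 0.10, 0.099, 0.20, 0.0999, 0.03,
                        0.11, 0.01), 5),
    hwe_p = rep(c(0.5, 1e-15, 2e-15, 1e-16, 1, 1e-14, 0.01, 0, 0.9, 1e-15),
                5),
    depth = rep(c(7L, 6L, 10L, 9L, 30L, 10L, 7L, 0L, 12L, 8L), 5),
    allele_balance_pass = rep(c(TRUE, TRUE, FALSE, TRUE, TRUE), 10),
    imputation_quality = rep(c(0.8, 0.79, 1, 0.95, 0.5), 10),
    stringsAsFactors = FALSE
  )
}
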