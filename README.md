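# contextburden

Context-based aggregation of rare germline variants for cancer
case–control risk modeling.

Rare variants (MAF < 1%) are individually untestable against disease
outcomes; gene-level collapsing is the classical remedy but discards most
of the genome's context. `contextburden` aggregates rare variants into
per-individual **burden counts** over three meta-feature families
describing each variant's genomic, nucleotide, and epigenetic context:

* membership in a panel of cancer susceptibility genes (restricted to
  loss-of-function/pathogenic variants, with a missense sensitivity
  policy),
* contiguous 1 Mb chromosomal windows tiling the genome,
* the 96 single-base-substitution trinucleotide categories (SBS-96,
  COSMIC pyrimidine-centered convention).

The burden of individual *i* for meta-feature *l* is

```
s_il = Σ_j  x_ij · u_jl
```

with `x_ij ∈ {0,1,2}` the allele count and `u_jl` the membership
indicator. Burdens feed two logistic case–control models: a **benchmark**
model on known risk variants (GWAS SNPs, gene burdens, optional PRS) and
an **expanded** model adding window and SBS-96 burdens under an L1
penalty applied to the meta-feature columns only. Models are compared by
mean AUC over five iterations of stratified 5-fold cross-validation, with
all data-driven choices (low-count feature pruning, PC residualization,
penalty selection) confined to each training fold. The package also
provides the surrounding machinery: QC variant filters, 1:1
birth-year/sex-matched case–control design with a survival constraint,
LD-pruned genotype PCA and predictor residualization, per-predictor Wald
association scans with Bonferroni control, a simulation-based power
engine for burden tests, and a synthetic-cohort generator with
Balding–Nichols population structure so everything runs without
access-controlled biobank data.

Intended users: statistical geneticists and biostatisticians evaluating
whether context-based rare-variant aggregation adds predictive value over
known risk variants, and anyone needing a tested reference implementation
of the burden/meta-feature machinery.

## Worked example

```r
library(contextburden)

# a synthetic cohort with one 1 Mb window burden carrying an OR-2 effect
cfg <- sim_config(
  n_individuals = 4000, n_rare_variants = 2000, n_common_snps = 100,
  n_chromosomes = 2, chrom_length_bp = 5e6,
  effect_table = data.frame(predictor = "win_1_2", log_or = log(2)),
  baseline_log_odds = -1.5, seed = 55)
co <- simulate_cohort(cfg)
co
#> synthetic_cohort: 4000 individuals, 2100 variants ( 2000 rare / 100 common ),
#>   126 burden features, 1917 cases

y <- co$phenotypes$case
bench <- cross_validate(y, co$known_risk, kind = "benchmark", seed = 5)
expd  <- cross_validate(y, co$known_risk, co$burdens, kind = "expanded",
                        seed = 5)
bench$mean_auc
#> [1] 0.4999809
expd$mean_auc
#> [1] 0.734403
```

The benchmark AUC sits at chance (the known-risk SNPs carry no effect in
this simulation) while the expanded model recovers the injected window
burden and gains ~0.23 AUC. A marginal scan pinpoints the window:

```r
scan <- association_scan(cbind(co$known_risk, co$burdens), y)
subset(scan, significant)[, c("predictor", "estimate", "p")]
#>    predictor estimate         p
#> 20      G015    0.645  5.65e-05
#> 22      G017    0.515  1.08e-05
#> 28   win_1_2    0.672 3.22e-122
#> 55   A[C>G]T    0.425  9.32e-08
```

The injected window dominates (p ≈ 1e-122 against a Bonferroni threshold
of 0.05/131); the gene and SBS-96 hits are expected collateral — their
member variants overlap the causal window.

and the power engine estimates how large a study detects a chosen SBS-96
category's effect:

```r
tf <- select_target_feature(co$burdens)   # category with a typical count
pw <- simulate_power(
  power_config(tf, or_grid = c(1, 1.3, 1.6), n_grid = 500,
               iterations = 100, n_tests_for_bonferroni = 10,
               prevalence = 0.3, seed = 7),
  co$burdens)
```

`run_pipeline()` chains the stages (filters → burdens → matching → CV →
scan → power) and writes TSV outputs plus a JSON manifest.

See `vignettes/context-burden-methods.Rmd` for the model, the
canonicalization rules, every tunable default and the generator's scope.

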