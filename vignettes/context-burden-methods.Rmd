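---
title: "Context-based burden aggregation for germline cancer risk models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-based burden aggregation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contextburden)
```

## The problem

Rare germline variants (minor allele frequency below 1%) are individually
too sparse to test against disease outcomes: almost every carrier count is
zero. The classical remedy is gene-level collapsing. This package
implements a broader *context-based* aggregation: every rare variant is
annotated by meta-features describing its genomic, nucleotide, and
epigenetic context, and each individual's predictor is the **burden**

$$ s_{il} \;=\; \sum_j x_{ij}\, u_{jl}, $$

where $x_{ij} \in \{0,1,2\}$ is the allele count of individual $i$ for
variant $j$ (missing genotypes contribute 0) and $u_{jl}$ indicates
membership of variant $j$ in meta-feature $l$. Three meta-feature families
are built:

* **susceptibility genes** — membership in a configurable panel,
  restricted to loss-of-function or pathogenic variants (a sensitivity
  policy additionally admits missense);
* **contiguous 1 Mb windows** — a region-based aggregation tiling each
  chromosome, a proxy for regional genomic/epigenetic context such as
  replication timing;
* **SBS-96 categories** — the 96 trinucleotide single-base-substitution
  classes familiar from somatic mutational-signature analysis.

Burdens enter two logistic case–control models: a **benchmark** model on
known risk variants only (GWAS SNP allele counts, gene burdens, optionally
a PRS), and an **expanded** model that adds the window and SBS-96 burdens
with an L1 penalty on those columns only — the known-risk columns are
never penalized, so the comparison isolates what the contexts add.
Performance is the mean AUC over five iterations of 5-fold
cross-validation, and each predictor is also tested marginally by a Wald
test with Bonferroni control.

## Canonicalization choices

**SBS-96.** A substitution is labelled `X[R>A]Y` with the reference base
`R` a pyrimidine. When the reference allele is a purine, the variant
description (ref, alt and both flanks, flank order swapped) is
reverse-complemented first. This is the COSMIC convention; it is forced by
arithmetic, since 6 substitutions × 16 flank pairs = 96 only after strand
collapsing. Indels and multi-nucleotide substitutions carry no
trinucleotide substitution class and are excluded from SBS-96 (they still
contribute to window and gene burdens). Variants at the first or last base
of a chromosome have no complete context and return a not-applicable
value rather than an error.

**Windows.** Positions are 1-based; window $k$ on a chromosome covers
positions $[10^6 k + 1, 10^6 (k+1)]$, so windows tile each chromosome
without gaps or overlap. The number of windows that end up in a model is
data-dependent (only features with training-set counts of 5 or more are
kept), so no fixed window count is asserted anywhere.

**Rarity.** MAF is computed on the full supplied cohort, before any
case–control sampling, and the threshold is strict (`maf < 0.01`).

**Low-count pruning.** Meta-features whose summed count over the
*training* individuals is below 5 are dropped — re-decided inside every
cross-validation training fold, so held-out individuals can never
influence which features a model sees.

## Quality-control filters

Filter thresholds are fixed defaults of the design this package
implements, and the strictness of each boundary follows the rule's
wording: missingness `< 10%`
(strict), HWE p `> 1e-15` for exomes and `> 1e-5` for arrays (strict),
minimum depth 7 for SNVs and 10 for indels (non-strict, a minimum),
array call rate `> 95%` (strict), imputation quality `>= 0.8`
(non-strict). Allele balance is a precomputed site-level pass flag —
the underlying rule ("at least one sample per site passes") needs
per-read data unavailable at this layer, so upstream callers supply the
boolean. Depth is treated as a per-site summary supplied upstream; whether
that summary is a per-site mean or a per-genotype minimum is the
caller's choice, and this package does not re-derive it.

## Population-structure control

Confounding by ancestry is handled by **residualization**: each predictor
column is replaced by its residual from an OLS regression on the top five
genetic PCs. PCs come from common SNPs (MAF > 1%) after greedy LD pruning
at $r^2 > 0.5$ within 1,000 kb windows; allele counts are centered at
$2f$ and standardized by $\sqrt{2f(1-f)}$ before the SVD. Two deliberate
choices:

* pruning uses **in-sample** $r^2$ (an external LD reference panel is the
  common alternative; it is an input this package does not require);
* PC effects are estimated **per training fold** by default and applied
  to held-out rows with the training coefficients, preserving the
  cross-validation contract; `residualize_scope = "whole"` reproduces the
  simpler whole-data variant.

## Model fitting and evaluation

The expanded fit uses coordinate-descent L1-penalized logistic regression
(glmnet) with penalty factors 0/1 separating known-risk from meta
columns. The design leaves the penalty strength open, so it
is chosen by nested 5-fold cross-validation on the training fold
(binomial deviance, `lambda.min`), with the fold assignment derived
deterministically from the outer seed. Predictors are standardized
internally by the penalized fitter so one penalty is scale-fair;
coefficients are reported on the original scale. At an infinite penalty
the meta coefficients are exactly zero and the known-risk coefficients
equal the benchmark fit — a limit the test suite checks.

AUC is the rank-based (Mann–Whitney) probability of concordance with
ties counted one half, averaged over the 25 repeat-by-fold values. The
pooled-predictions alternative was considered and rejected as the default
because fold-level averaging is the natural reading of "average AUC
across five iterations of 5-fold cross-validation".

The association scan fits one logistic model per predictor (intercept,
predictor, five PCs) and reads the two-sided Wald p from the standard
normal. Zero-variance predictors are reported with NA and excluded from
the Bonferroni family size. The scan deliberately tests predictors
one-at-a-time rather than reading coefficients off the joint fit — the
intended family sizes (thousands, roughly one per predictor)
imply the marginal reading.

## The power engine

Power for detecting a burden effect is estimated by simulation. Each
iteration draws case status for every individual from

$$ Y_i \sim \text{Bernoulli}\!\left(\text{expit}(c + \alpha S_i +
\boldsymbol\beta^\top \mathbf S_{\text{other},i})\right), $$

with $\alpha = \log \text{OR}$ for the target feature and
$\boldsymbol\beta$ the background effects, fitted once by univariate
logistic regressions of the observed outcome on each non-target feature
and held fixed across iterations; then $n$ cases and $n$ controls are
sampled without replacement and a Wald test of the target feature is
compared against $0.05/n_{\text{tests}}$. Power is the significant
fraction of iterations (500 by default).

The generative formula is often written without an explicit
intercept; because $n$ cases must actually be drawable, the engine
includes an intercept $c$ calibrated by root-finding so the expected case
fraction equals a configured prevalence (with no prevalence configured,
$c = 0$, which is the literal formula). Iterations that produce fewer
than $n$ cases are redrawn, up to a cap, and tallied. The default target
feature is chosen as the SBS-96 category whose mean count is nearest the
mean over all categories — the "typical count" criterion — with a manual
override. Case–control draws are independent across every (OR, n,
iteration) triple.

An analytic cross-check is bundled: for a binary exposure the Wald
logistic test is asymptotically the two-proportion z-test, and the test
suite requires simulated power within 0.1 of the closed form at large n.

## The synthetic cohort generator

The generator exists so that every stage is testable without
access-controlled biobank data. What it emulates, with defaults chosen
once as field-realistic:

* **genome**: i.i.d. uniform bases (default two 5 Mb chromosomes) — enough
  to give every variant a true trinucleotide context and multiple 1 Mb
  windows;
* **rare variants**: default 5,000, ancestral MAF uniform on
  (5×10⁻⁴, 0.01), positions without replacement in chromosome interiors,
  alt ≠ ref, genotypes Binomial(2, f). Per-individual rare-allele totals
  then average ≈ 50, i.e. ≈ 0.5 per SBS-96 category; power analyses that
  need exome-like per-category means (≈ 3) scale `n_rare_variants` up,
  as the acceptance script does;
* **population structure**: a configurable number of subpopulations with
  common-SNP frequencies perturbed Balding–Nichols-style,
  Beta$(f(1-F)/F, (1-f)(1-F)/F)$ around the ancestral $f$ — a single
  divergence knob $F$ with a known PCA signature. Rare variants share
  the ancestral frequency across subpopulations, keeping all observed
  rare MAFs below 2% at any $F$; real rare variants are *more*
  geographically clustered than common ones, not less, so synthetic
  results say nothing about rare-variant stratification artifacts;
* **phenotypes**: case status from a logistic model on named burden
  features and known-risk allele counts (so status depends on genotypes
  only through those predictors); birth year, sex, diagnosis and
  censoring ages uniform over configurable windows (only their ordering
  matters to matching); family history a Bernoulli flag, optionally
  enriched among cases by an odds multiplier;
* **QC metrics**: benign distributions by default, with an option to
  inject threshold violators so filter tests have positive cases.

Not emulated: linkage disequilibrium beyond subpopulation structure,
recombination, realistic site-frequency spectra, indel mechanics beyond a
configurable fraction of length-changing alleles, and any real genome
annotation. Passing tests therefore demonstrate the *statistical
machinery* — calibration, leakage-freedom, selection behavior, power
arithmetic — not performance on real exomes.

## Matching

Greedy 1:1 exact matching on (birth year, sex) with the survival
constraint that the control's age at death or censoring is at least the
case's age at diagnosis. Cases are processed in a seed-shuffled order and
ties among eligible controls are broken uniformly at random under the
seed; no particular matching algorithm is prescribed, and the
constraints — not the assignment order — carry the design. Exact matching
is assumed (no birth-year caliper relaxation). Unmatched cases are a
reported outcome, never an error. Within a cancer type no individual is
both case and control; control reuse across cancer types is allowed by
construction since matching is run per cancer type.

## Problem sizes used in the bundled checks

The test suite and `scripts/acceptance.R` run at desk scale, chosen as
the smallest sizes at which the quantities under test are statistically
stable: null-calibration cohorts of 2,000 individuals × 5,000 rare
variants with 5×5 CV; family-wise-error replicates at 400 individuals ×
25 predictors × 1,000 replicates; signal-recovery replicates of 4,000
individuals; power grids at 100 iterations per point, with the
exome-scale power point using 20,000 individuals × 30,000 rare variants.
Monte-Carlo tolerances in the tests are derived from binomial standard
errors at those sizes.

## Known limitations

* In-sample LD pruning differs from external-reference-panel pruning; with realistic sample sizes the retained set differs
  only where in-sample and reference LD disagree.
* The Wald scan's normal approximation is conservative for very sparse
  burden counts; exact or score tests are not implemented.
* The matcher is greedy, not optimal; with tight pools an optimal
  assignment could match more cases.
* PRS columns are residualized like every other predictor — they are
  predictors; a switch to exempt them is not provided.
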