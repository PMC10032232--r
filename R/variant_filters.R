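#' Quality-control filter policy for a genotyping assay
#'
#' Default thresholds reproduce the study design per assay:
#' \describe{
#'   \item{WES}{autosomal variants with missingness < 10\% (strict),
#'     Hardy-Weinberg equilibrium p > 1e-15 (strict), read depth of at
#'     least 7 for SNVs and 10 for indels, and a passing site-level allele
#'     balance flag.}
#'   \item{SNP_array}{autosomal SNPs with call rate > 95\% (strict) and
#'     HWE p > 1e-5 (strict).}
#'   \item{imputed}{autosomal SNPs with imputation quality score >= 0.8
#'     (non-strict).}
#' }
#'
#' @param assay one of `"WES"`, `"SNP_array"`, `"imputed"`.
#' @param missingness_max,hwe_p_min,depth_min_snv,depth_min_indel,call_rate_min,imputation_quality_min,autosomes_only
#'   threshold overrides; defaults depend on `assay`.
#' @return a `filter_policy` list.
#' @export
filter_policy <- function(assay = c("WES", "SNP_array", "imputed"),
                          missingness_max = 0.10,
                          hwe_p_min = NULL,
                          depth_min_snv = 7,
                          depth_min_indel = 10,
                          call_rate_min = 0.95,
                          imputation_quality_min = 0.8,
                          autosomes_only = TRUE) {
  assay <- match.arg(assay)
  if (is.null(hwe_p_min)) {
    hwe_p_min <- switch(assay, WES = 1e-15, SNP_array = 1e-5, imputed = 1e-5)
  }
  structure(list(assay = assay,
                 missingness_max = missingness_max,
                 hwe_p_min = hwe_p_min,
                 depth_min_snv = depth_min_snv,
                 depth_min_indel = depth_min_indel,
                 call_rate_min = call_rate_min,
                 imputation_quality_min = imputation_quality_min,
                 autosomes_only = autosomes_only),
            class = "filter_policy")
}

# Rules applicable per assay, in reporting order.
filter_rules <- function(policy) {
  base <- if (policy$autosomes_only) "autosome" else character(0)
  switch(policy$assay,
    WES = c(base, "missingness", "hwe", "depth", "allele_balance"),
    SNP_array = c(base, "call_rate", "hwe"),
    imputed = c(base, "imputation_quality"))
}

# Fields each rule needs on the VariantRecord table.
rule_fields <- list(autosome = "chrom", missingness = "missingness",
                    hwe = "hwe_p", depth = c("depth", "variant_class"),
                    allele_balance = "allele_balance_pass",
                    call_rate = "missingness",
                    imputation_quality = "imputation_quality")

is_autosome <- function(chrom) {
  ch <- sub("^chr", "", as.character(chrom))
  !is.na(suppressWarnings(as.integer(ch)))
}

#' Apply quality-control filters to a variant table
#'
#' A variant is kept iff it passes every rule applicable to the policy's
#' assay. Boundary behavior is deliberate: missingness exactly at the
#' maximum is rejected, an HWE p exactly at the floor is rejected, a depth
#' exactly at the minimum is kept, an imputation quality exactly at the
#' minimum is kept, and a call rate exactly at the minimum is rejected.
#'
#' @param variants VariantRecord data.frame; required columns depend on
#'   the assay (`missingness`, `hwe_p`, `depth`, `allele_balance_pass`,
#'   `variant_class` for WES; `missingness`, `hwe_p` for SNP arrays;
#'   `imputation_quality` for imputed data; `chrom` always).
#' @param policy a [filter_policy()].
#' @return list with `kept` (the passing rows, input order preserved) and
#'   `tally` (named integer: variants rejected per rule; a variant failing
#'   several rules counts in each).
#' @export
apply_filters <- function(variants, policy = filter_policy("WES")) {
  rules <- filter_rules(policy)
  tally <- stats::setNames(integer(length(rules)), rules)
  if (nrow(variants) == 0L) {
    return(list(kept = variants, tally = tally))
  }
  for (r in rules) {
    for (fld in rule_fields[[r]]) {
      if (is.null(variants[[fld]]) || anyNA(variants[[fld]])) {
        bad <- if (is.null(variants[[fld]])) seq_len(nrow(variants))
               else which(is.na(variants[[fld]]))
        stop("variant ", paste0(variants$chrom[bad[1]], ":",
                                variants$pos[bad[1]]),
             ": missing required field '", fld, "' for assay ", policy$assay)
      }
    }
  }
  pass <- rep(TRUE, nrow(variants))
  for (r in rules) {
    ok <- switch(r,
      autosome = is_autosome(variants$chrom),
      missingness = variants$missingness < policy$missingness_max,
      hwe = variants$hwe_p > policy$hwe_p_min,
      depth = {
        need <- ifelse(variants$variant_class == "indel",
                       policy$depth_min_indel, policy$depth_min_snv)
        variants$depth >= need
      },
      allele_balance = as.logical(variants$allele_balance_pass),
      call_rate = (1 - variants$missingness) > policy$call_rate_min,
      imputation_quality =
        variants$imputation_quality >= policy$imputation_quality_min)
    tally[r] <- sum(!ok)
    pass <- pass & ok
  }
  list(kept = variants[pass, , drop = FALSE], tally = tally)
}

#' Write a per-rule filter report
#'
#' @param tally named integer vector from [apply_filters()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_filter_report <- function(tally, path) {
  utils::write.table(data.frame(rule = names(tally), rejected = as.integer(tally)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
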