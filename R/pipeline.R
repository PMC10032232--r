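#' End-to-end analysis pipeline on a synthetic or supplied cohort
#'
#' Runs the full sequence — QC filters, meta-feature burden construction,
#' case-control matching, PC computation, repeated cross-validation of
#' the benchmark and expanded risk models, the per-predictor Wald
#' association scan, and (optionally) the power grid — and writes every
#' table plus a machine-readable run manifest to the output directory.
#'
#' @param cohort a `synthetic_cohort` (from [simulate_cohort()]) or a
#'   compatible list with `variants`, `genotypes`, `reference`,
#'   `phenotypes`, `known_risk`.
#' @param out_dir output directory (created if absent).
#' @param seed seed for matching, cross-validation and power draws.
#' @param assay filter policy assay (default `"WES"`).
#' @param cv_repeats,cv_folds cross-validation geometry.
#' @param pcs_k number of principal components (default 5); `0` disables
#'   residualization and PC adjustment.
#' @param run_expanded fit the expanded model in addition to the
#'   benchmark (default `TRUE`).
#' @param power optional [power_config()]; `NULL` skips the power stage.
#' @return list with `filter`, `matched`, `cv_benchmark`, `cv_expanded`,
#'   `scan`, `power`, `manifest` (also written as `manifest.json`).
#' @export
run_pipeline <- function(cohort, out_dir, seed = 1, assay = "WES",
                         cv_repeats = 5, cv_folds = 5, pcs_k = 5,
                         run_expanded = TRUE, power = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  counts <- list()

  # --- QC filters ---------------------------------------------------------
  flt <- apply_filters(cohort$variants, filter_policy(assay))
  write_filter_report(flt$tally, file.path(out_dir, "filter_report.tsv"))
  keep_idx <- match(flt$kept$id, cohort$variants$id)
  variants <- flt$kept
  genotypes <- cohort$genotypes[, keep_idx, drop = FALSE]
  stages <- c(stages, "filter")
  counts$variants_in <- nrow(cohort$variants)
  counts$variants_kept <- nrow(variants)

  # --- meta-feature burdens ----------------------------------------------
  meta <- NULL
  if (run_expanded) {
    fs <- build_feature_set(variants, cohort$reference,
                            gene_list = sprintf("G%03d",
                                                seq_len(cohort$config$n_genes %||% 0)))
    meta <- build_burden_matrix(genotypes, fs, maf = variants$maf)
    write_burdens(meta, file.path(out_dir, "burdens.tsv"))
    stages <- c(stages, "meta_features")
    counts$meta_features <- ncol(meta)
  }

  # --- matching -----------------------------------------------------------
  ph <- cohort$phenotypes
  cases <- ph[ph$case == 1, ]
  ctrls <- ph[ph$case == 0, ]
  matched <- match_controls(
    data.frame(individual_id = cases$individual_id,
               birth_year = cases$birth_year, sex = cases$sex,
               age_at_diagnosis = cases$age_at_diagnosis),
    data.frame(individual_id = ctrls$individual_id,
               birth_year = ctrls$birth_year, sex = ctrls$sex,
               age_at_death_or_censoring = ctrls$age_at_death_or_censoring),
    seed = new_seed(seed, 11L))
  utils::write.table(cbind(cancer = "synthetic_cancer", matched$pairs),
                     file.path(out_dir, "matched_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stages <- c(stages, "match")
  counts$matched_pairs <- nrow(matched$pairs)
  counts$unmatched_cases <- length(matched$unmatched_cases)

  sel <- match(c(matched$pairs$case_id, matched$pairs$control_id),
               ph$individual_id)
  y <- c(rep(1L, nrow(matched$pairs)), rep(0L, nrow(matched$pairs)))

  # --- principal components ----------------------------------------------
  pcs <- NULL
  if (pcs_k > 0 && any(cohort$variants$is_common)) {
    ci <- which(variants$is_common %||% rep(FALSE, nrow(variants)))
    if (length(ci) > pcs_k) {
      pcs_all <- compute_pcs(as.matrix(genotypes[, ci, drop = FALSE]),
                             variants$chrom[ci], variants$pos[ci], k = pcs_k)
      pcs <- pcs_all[sel, , drop = FALSE]
      stages <- c(stages, "pcs")
    }
  }

  known <- as.matrix(cohort$known_risk)[sel, , drop = FALSE]
  meta_m <- if (run_expanded) meta[sel, , drop = FALSE] else NULL
  if (run_expanded) attr(meta_m, "family") <- attr(meta, "family")

  # --- cross-validated AUC ------------------------------------------------
  cvb <- cross_validate(y, known, NULL, pcs, kind = "benchmark",
                        repeats = cv_repeats, folds = cv_folds,
                        seed = new_seed(seed, 21L))
  cve <- NULL
  if (run_expanded) {
    cve <- cross_validate(y, known, meta_m, pcs, kind = "expanded",
                          repeats = cv_repeats, folds = cv_folds,
                          seed = new_seed(seed, 21L))
  }
  cv_tab <- rbind(cbind(model = "benchmark", cvb$auc),
                  if (run_expanded) cbind(model = "expanded", cve$auc))
  utils::write.table(cv_tab, file.path(out_dir, "cv_auc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stages <- c(stages, "cv")

  # --- association scan ---------------------------------------------------
  preds <- if (run_expanded) cbind(known, meta_m) else known
  scan <- association_scan(preds, y, pcs)
  utils::write.table(scan, file.path(out_dir, "association_scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stages <- c(stages, "scan")
  counts$predictors_scanned <- scan$n_tests[1]

  # --- power grid ---------------------------------------------------------
  pw <- NULL
  if (!is.null(power) && run_expanded) {
    beta <- suppressWarnings(
      fit_background_effects(meta[, attr(meta, "family") == "sbs96",
                                  drop = FALSE],
                             cohort$phenotypes$case,
                             target = power$target_feature))
    pw <- simulate_power(power, meta, beta)
    utils::write.table(as.data.frame(pw), file.path(out_dir, "power.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stages <- c(stages, "power")
  }

  manifest <- list(
    seed = seed,
    assay = assay,
    stages = stages,
    counts = counts,
    settings = list(cv_repeats = cv_repeats, cv_folds = cv_folds,
                    pcs_k = pcs_k, run_expanded = run_expanded),
    mean_auc = list(benchmark = cvb$mean_auc,
                    expanded = if (run_expanded) cve$mean_auc),
    outputs = list.files(out_dir),
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(filter = flt, matched = matched, cv_benchmark = cvb,
                 cv_expanded = cve, scan = scan, power = pw,
                 manifest = manifest))
}
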