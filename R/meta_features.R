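#' The 96 canonical single-base-substitution categories
#'
#' Enumerates the SBS-96 catalog: six pyrimidine-referenced substitutions
#' (C>A, C>G, C>T, T>A, T>C, T>G) crossed with the 16 pairs of flanking
#' bases, in substitution-then-flanks lexicographic order. Labels follow
#' the COSMIC convention `"X[R>A]Y"`.
#'
#' @return character vector of 96 distinct labels.
#' @export
sbs96_catalog <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) {
    for (l in DNA_BASES) {
      for (r in DNA_BASES) {
        out <- c(out, paste0(l, "[", s, "]", r))
      }
    }
  }
  out
}

#' Classify single-nucleotide variants into SBS-96 trinucleotide categories
#'
#' Each SNV is labelled by its substitution and the two reference bases
#' flanking it. Variants whose reference allele is a purine (A or G) are
#' reverse-complemented — ref, alt and both flanks, with the flank order
#' swapped — so every label is pyrimidine-centered and a variant and its
#' reverse-complement description receive the same category.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`.
#' @param reference named character vector of chromosome sequences over
#'   A/C/G/T (names matching `chrom`).
#' @return character vector of SBS-96 labels; `NA` for indels, non-ACGT
#'   alleles, and positions without both flanks (first/last base of a
#'   chromosome).
#' @export
classify_sbs96 <- function(variants, reference) {
  chrom <- as.character(variants$chrom)
  pos <- as.integer(variants$pos)
  ref <- as.character(variants$ref)
  alt <- as.character(variants$alt)
  out <- rep(NA_character_, length(pos))
  if (length(pos) == 0L) return(out)
  if (any(!chrom %in% names(reference))) {
    stop("variants on chromosomes absent from the reference: ",
         paste(unique(setdiff(chrom, names(reference))), collapse = ", "))
  }
  clen <- nchar(reference)[match(chrom, names(reference))]
  is_snv <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% DNA_BASES & alt %in% DNA_BASES & ref != alt
  ok <- is_snv & pos >= 2L & pos <= clen - 1L
  if (!any(ok)) return(out)

  ctx <- substring(reference[chrom[ok]], pos[ok] - 1L, pos[ok] + 1L)
  mid <- substr(ctx, 2L, 2L)
  bad <- mid != ref[ok]
  if (any(bad)) {
    stop("reference allele mismatch at ",
         paste(paste0(chrom[ok][bad], ":", pos[ok][bad]), collapse = ", "),
         " (reference has ", paste(mid[bad], collapse = ","), ")")
  }
  left <- substr(ctx, 1L, 1L)
  right <- substr(ctx, 3L, 3L)
  r <- ref[ok]
  a <- alt[ok]
  flip <- r %in% c("A", "G")
  l2 <- ifelse(flip, DNA_COMP[right], left)
  r2 <- ifelse(flip, DNA_COMP[left], right)
  ref2 <- ifelse(flip, DNA_COMP[r], r)
  alt2 <- ifelse(flip, DNA_COMP[a], a)
  out[ok] <- paste0(l2, "[", ref2, ">", alt2, "]", r2)
  out
}

#' Assign variants to contiguous 1 Mb chromosomal windows
#'
#' Windows tile each chromosome without gaps or overlap, starting at
#' position 1; position `pos` falls in window index `floor((pos-1)/size)`,
#' so positions 1..size share window 0 and size+1 opens window 1.
#'
#' @param variants data.frame with columns `chrom`, `pos`.
#' @param window_size_bp window width in base pairs (default 1 Mb).
#' @return character vector of window feature ids `"win_<chrom>_<index>"`.
#' @export
assign_window <- function(variants, window_size_bp = 1e6) {
  pos <- as.integer(variants$pos)
  if (any(pos < 1L)) stop("positions must be >= 1")
  idx <- (pos - 1L) %/% as.integer(window_size_bp)
  paste0("win_", as.character(variants$chrom), "_", idx)
}

#' Gene-burden membership under a consequence policy
#'
#' A variant contributes to a susceptibility gene's burden only if it lies
#' in a gene on the panel and is either loss-of-function or flagged
#' pathogenic. The sensitivity policy additionally admits missense
#' variants.
#'
#' @param variants data.frame with columns `gene`, `consequence`
#'   (`loss_of_function`, `missense`, `other`, or `NA`) and
#'   `pathogenic_flag` (logical).
#' @param gene_list character vector of panel gene ids (order defines
#'   feature order).
#' @param consequence_policy `"lof_pathogenic"` (default) or
#'   `"lof_missense_pathogenic"`.
#' @return character vector: the gene feature id each variant belongs to,
#'   `NA` when it belongs to none.
#' @export
gene_burden_membership <- function(variants, gene_list,
                                   consequence_policy = c("lof_pathogenic",
                                                          "lof_missense_pathogenic")) {
  consequence_policy <- match.arg(consequence_policy)
  gene <- as.character(variants$gene)
  cons <- as.character(variants$consequence)
  path <- variants$pathogenic_flag
  if (is.null(path)) path <- rep(FALSE, nrow(variants))
  path[is.na(path)] <- FALSE
  qual <- cons %in% "loss_of_function" | path
  if (consequence_policy == "lof_missense_pathogenic") {
    qual <- qual | cons %in% "missense"
  }
  keep <- !is.na(gene) & gene %in% gene_list & qual
  ifelse(keep, gene, NA_character_)
}

#' Build the meta-feature membership structure
#'
#' Constructs the variant-by-feature membership matrix u covering the
#' three meta-feature families: susceptibility-gene burdens (restricted by
#' the consequence policy), contiguous 1 Mb windows tiling the reference,
#' and the full SBS-96 catalog. Feature order is deterministic: genes in
#' panel order, windows by (chromosome, index), SBS-96 in catalog order.
#'
#' @param variants VariantRecord data.frame (`chrom`, `pos`, `ref`, `alt`,
#'   and, for gene features, `gene`/`consequence`/`pathogenic_flag`).
#' @param reference named character vector of chromosome sequences; may be
#'   `NULL` if `variants$sbs96` holds precomputed categories.
#' @param gene_list optional character vector of panel genes.
#' @param consequence_policy passed to [gene_burden_membership()].
#' @param window_size_bp window width (default 1 Mb).
#' @return an object of class `meta_feature_set`: list with `membership`
#'   (sparse d x p 0/1 matrix), `features` (data.frame `id`, `family`).
#' @export
build_feature_set <- function(variants, reference = NULL, gene_list = NULL,
                              consequence_policy = "lof_pathogenic",
                              window_size_bp = 1e6) {
  d <- nrow(variants)

  if (!is.null(reference)) {
    sbs <- classify_sbs96(variants, reference)
    chrom_levels <- names(reference)
    n_win <- pmax(1L, as.integer(ceiling(nchar(reference) / window_size_bp)))
  } else if (!is.null(variants$sbs96)) {
    sbs <- as.character(variants$sbs96)
    chrom_levels <- unique(as.character(variants$chrom))
    n_win <- vapply(chrom_levels, function(ch) {
      p <- variants$pos[variants$chrom == ch]
      as.integer((max(p) - 1L) %/% window_size_bp + 1L)
    }, integer(1))
  } else {
    stop("need a reference sequence or a precomputed variants$sbs96 column")
  }

  win_ids <- unlist(lapply(seq_along(chrom_levels), function(k) {
    paste0("win_", chrom_levels[k], "_", seq_len(n_win[k]) - 1L)
  }), use.names = FALSE)
  sbs_ids <- sbs96_catalog()
  gene_ids <- if (length(gene_list)) as.character(gene_list) else character(0)

  feat <- data.frame(
    id = c(gene_ids, win_ids, sbs_ids),
    family = c(rep("gene", length(gene_ids)),
               rep("window_1mb", length(win_ids)),
               rep("sbs96", length(sbs_ids))),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(feat$id)) stop("duplicate feature ids across families")

  ii <- integer(0)
  jj <- integer(0)
  if (length(gene_ids)) {
    g <- gene_burden_membership(variants, gene_ids, consequence_policy)
    hit <- which(!is.na(g))
    ii <- c(ii, hit)
    jj <- c(jj, match(g[hit], feat$id))
  }
  w <- assign_window(variants, window_size_bp)
  wj <- match(w, feat$id)
  if (anyNA(wj)) stop("variant position beyond the tiled reference")
  ii <- c(ii, seq_len(d))
  jj <- c(jj, wj)
  shit <- which(!is.na(sbs))
  ii <- c(ii, shit)
  jj <- c(jj, match(sbs[shit], feat$id))

  U <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(d, nrow(feat)),
                            dimnames = list(NULL, feat$id))
  structure(list(membership = U, features = feat,
                 window_size_bp = window_size_bp,
                 consequence_policy = consequence_policy),
            class = "meta_feature_set")
}

#' @export
print.meta_feature_set <- function(x, ...) {
  tab <- table(x$features$family)
  cat("meta_feature_set:", nrow(x$features), "features over",
      nrow(x$membership), "variants\n")
  for (f in names(tab)) cat("  ", f, ": ", tab[[f]], "\n", sep = "")
  invisible(x)
}

#' Compute the per-individual burden matrix
#'
#' The burden of individual i for meta-feature l is the sum over variants
#' of the allele count times the membership indicator, restricted to rare
#' variants (MAF below `maf_max`, assessed on the full cohort). Missing
#' genotypes contribute zero.
#'
#' @param genotypes individuals x variants allele-count matrix (0/1/2,
#'   `NA` = missing); dense or `Matrix` sparse.
#' @param featureset a [build_feature_set()] result.
#' @param maf per-variant minor allele frequencies; defaults to
#'   frequencies computed from `genotypes`.
#' @param maf_max rare-variant threshold (default 0.01, strict).
#' @return individuals x features numeric matrix of counts, with a
#'   `"family"` attribute giving each column's meta-feature family.
#' @export
build_burden_matrix <- function(genotypes, featureset, maf = NULL,
                                maf_max = 0.01) {
  U <- featureset$membership
  if (ncol(genotypes) != nrow(U)) {
    stop("genotype columns (", ncol(genotypes),
         ") do not align with feature-set variants (", nrow(U), ")")
  }
  if (is.null(maf)) {
    f <- Matrix::colMeans(genotypes, na.rm = TRUE) / 2
    maf <- pmin(f, 1 - f)
  }
  if (length(maf) != ncol(genotypes)) stop("maf length mismatch")
  keep <- !is.na(maf) & maf < maf_max
  X <- genotypes
  if (is.matrix(X) && anyNA(X)) X[is.na(X)] <- 0
  if (any(!keep)) {
    U <- U * as.numeric(keep)  # row-scale: drop non-rare variants
  }
  S <- as.matrix(X %*% U)
  rownames(S) <- rownames(genotypes)
  structure(S, family = stats::setNames(featureset$features$family,
                                        featureset$features$id))
}

#' Drop meta-features with low training-set counts
#'
#' Features whose summed burden over the training individuals falls below
#' `min_count` are removed. Inclusion is decided on the training set only,
#' so held-out individuals never influence which features enter a model.
#'
#' @param burdens individuals x features burden matrix (rownames = ids).
#' @param training_ids row names (or indices) of the training individuals.
#' @param min_count minimum training-set count to keep a feature
#'   (default 5: features with counts below 5 are excluded).
#' @return the burden matrix restricted to the kept features.
#' @export
prune_low_count_features <- function(burdens, training_ids, min_count = 5) {
  if (length(training_ids) == 0L) stop("empty training set")
  tr <- burdens[training_ids, , drop = FALSE]
  keep <- colSums(tr) >= min_count
  fam <- attr(burdens, "family")
  out <- burdens[, keep, drop = FALSE]
  if (!is.null(fam)) attr(out, "family") <- fam[colnames(out)]
  out
}
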