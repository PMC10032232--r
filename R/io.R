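#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences (names truncated at the
#'   first whitespace).
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package")
  }
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a reference genome to FASTA
#'
#' @param reference named character vector of sequences.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_fasta <- function(reference, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("writing FASTA requires the Biostrings package")
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference), path)
  invisible(path)
}

#' Read variants and genotypes from VCF or the tabular dialect
#'
#' The tabular dialect is a TSV with header columns `chrom`, `pos`,
#' `ref`, `alt` followed by one column per individual holding allele
#' counts 0/1/2 or `"."` for missing; rows are variants. VCF input (GT
#' fields) is parsed with vcfR; multi-allelic sites are split into one
#' biallelic record per alternate allele, each individual's count for a
#' record being the number of alleles matching that alternate; genotypes
#' containing a missing allele are marked missing.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"vcf"` (default: guessed from the
#'   extension).
#' @return list with `variants` (data.frame `chrom`, `pos`, `id`, `ref`,
#'   `alt`, `variant_class`) and `genotypes` (individuals x variants
#'   integer matrix, `NA` = missing).
#' @export
read_variants <- function(path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  dialect <- match.arg(dialect, c("tsv", "vcf"))
  if (dialect == "tsv") read_variants_tsv(path) else read_variants_vcf(path)
}

read_variants_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(tab))) {
    stop("tabular dialect requires header columns chrom, pos, ref, alt")
  }
  ind <- setdiff(names(tab), need)
  G <- t(vapply(seq_len(nrow(tab)), function(i) {
    v <- unlist(tab[i, ind], use.names = FALSE)
    v[v == "."] <- NA
    as.integer(v)
  }, integer(length(ind))))
  G <- t(G)  # individuals x variants
  variants <- data.frame(chrom = tab$chrom, pos = as.integer(tab$pos),
                         id = paste(tab$chrom, tab$pos, tab$ref, tab$alt,
                                    sep = ":"),
                         ref = tab$ref, alt = tab$alt,
                         stringsAsFactors = FALSE)
  variants$variant_class <- ifelse(nchar(variants$ref) == 1 &
                                     nchar(variants$alt) == 1, "SNV", "indel")
  dimnames(G) <- list(ind, variants$id)
  list(variants = variants, genotypes = G)
}

read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT genotypes")
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)

  rows <- list()
  cols <- list()
  for (r in seq_along(alts)) {
    alleles <- strsplit(gsub("|", "/", gt[r, ], fixed = TRUE), "/", fixed = TRUE)
    for (k in seq_along(alts[[r]])) {
      a <- alts[[r]][k]
      if (!grepl("^[ACGT]+$", a) || !grepl("^[ACGT]+$", ref[r])) {
        warning("skipping record ", chrom[r], ":", pos[r],
                " with non-ACGT allele")
        next
      }
      counts <- vapply(alleles, function(al) {
        if (length(al) == 0 || anyNA(al) || any(al == "." | al == "")) {
          return(NA_integer_)
        }
        sum(al == as.character(k))
      }, integer(1))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom[r], pos = pos[r],
        id = paste(chrom[r], pos[r], ref[r], a, sep = ":"),
        ref = ref[r], alt = a, stringsAsFactors = FALSE)
      cols[[length(cols) + 1L]] <- counts
    }
  }
  variants <- do.call(rbind, rows)
  variants$variant_class <- ifelse(nchar(variants$ref) == 1 &
                                     nchar(variants$alt) == 1, "SNV", "indel")
  G <- do.call(cbind, cols)
  dimnames(G) <- list(colnames(gt), variants$id)
  list(variants = variants, genotypes = G)
}

#' Write genotypes in the tabular dialect
#'
#' @param variants VariantRecord data.frame (`chrom`, `pos`, `ref`,
#'   `alt`).
#' @param genotypes individuals x variants allele counts (`NA` =
#'   missing).
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
write_genotypes_tsv <- function(variants, genotypes, path) {
  G <- t(as.matrix(genotypes))
  G[] <- as.character(G)
  G[is.na(G)] <- "."
  tab <- cbind(data.frame(chrom = variants$chrom, pos = variants$pos,
                          ref = variants$ref, alt = variants$alt,
                          stringsAsFactors = FALSE),
               as.data.frame(G, stringsAsFactors = FALSE))
  names(tab) <- c("chrom", "pos", "ref", "alt",
                  rownames(genotypes) %||% paste0("ind", seq_len(nrow(genotypes))))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a minimal GT-only VCF
#'
#' Allele counts 0/1/2 become `0/0`, `0/1`, `1/1`; missing becomes
#' `./.`.
#'
#' @inheritParams write_genotypes_tsv
#' @export
write_vcf <- function(variants, genotypes, path) {
  G <- as.matrix(genotypes)
  ids <- rownames(G) %||% paste0("ind", seq_len(nrow(G)))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[G + 1L], nrow(G), ncol(G))
  gt_str[is.na(G)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  ids_col <- variants$id %||% rep(".", nrow(variants))
  body <- vapply(seq_len(nrow(variants)), function(i) {
    paste(c(variants$chrom[i], variants$pos[i],
            ids_col[i], variants$ref[i], variants$alt[i],
            ".", "PASS", ".", "GT", gt_str[, i]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read or write a phenotype table
#'
#' @param path TSV path.
#' @return data.frame (for the reader).
#' @export
read_phenotypes <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @param phenotypes PhenotypeTable data.frame.
#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a burden matrix to TSV and sparse triplet formats
#'
#' @param burdens individuals x features burden matrix.
#' @param path output TSV (dense, individuals in rows).
#' @param triplet_path optional sparse triplet TSV (`individual`,
#'   `feature`, `count`), nonzero entries only.
#' @return the path, invisibly.
#' @export
write_burdens <- function(burdens, path, triplet_path = NULL) {
  tab <- data.frame(individual = rownames(burdens) %||%
                      seq_len(nrow(burdens)),
                    as.data.frame(unclass(burdens)[, , drop = FALSE]),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(triplet_path)) {
    nz <- which(burdens != 0, arr.ind = TRUE)
    trip <- data.frame(
      individual = (rownames(burdens) %||% seq_len(nrow(burdens)))[nz[, 1]],
      feature = colnames(burdens)[nz[, 2]],
      count = burdens[nz])
    trip <- trip[order(nz[, 1], nz[, 2]), ]
    utils::write.table(trip, triplet_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
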