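revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

test_that("SBS-96 catalog has 96 distinct well-formed labels", {
  cat96 <- sbs96_catalog()
  expect_length(cat96, 96)
  expect_length(unique(cat96), 96)
  expect_true(all(grepl("^[ACGT]\\[[CT]>[ACGT]\\][ACGT]$", cat96)))
})

test_that("pyrimidine contexts classify directly, purines reverse-complement", {
  ref <- c(`1` = "ACATG")
  v <- data.frame(chrom = "1", pos = 2L, ref = "C", alt = "A")
  expect_equal(classify_sbs96(v, ref), "A[C>A]A")

  # TGT with G>T is the reverse-complement description of ACA with C>A
  ref2 <- c(`1` = "TGTAA")
  v2 <- data.frame(chrom = "1", pos = 2L, ref = "G", alt = "T")
  expect_equal(classify_sbs96(v2, ref2), "A[C>A]A")
})

test_that("indels, edge positions and mismatches are handled", {
  ref <- c(`1` = "ACATG")
  v <- data.frame(chrom = "1", pos = c(1L, 5L, 3L, 2L),
                  ref = c("A", "G", "A", "CC"),
                  alt = c("G", "T", "AT", "C"))
  out <- classify_sbs96(v, ref)
  expect_true(all(is.na(out)))  # edges and indels: not applicable
  vbad <- data.frame(chrom = "1", pos = 2L, ref = "G", alt = "T")
  expect_error(classify_sbs96(vbad, ref), "mismatch")
})

test_that("enumerating all substitutions in all contexts yields the catalog", {
  labels <- character(0)
  for (l in c("A", "C", "G", "T")) {
    for (m in c("C", "T")) {
      for (r in c("A", "C", "G", "T")) {
        for (a in setdiff(c("A", "C", "G", "T"), m)) {
          ref <- stats::setNames(paste0(l, m, r), "1")
          v <- data.frame(chrom = "1", pos = 2L, ref = m, alt = a)
          labels <- c(labels, classify_sbs96(v, ref))
        }
      }
    }
  }
  expect_setequal(labels, sbs96_catalog())
  expect_length(unique(labels), 96)
})

test_that("classification is invariant under reverse-complement description", {
  set.seed(7)
  for (i in 1:100) {
    seq1 <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                  collapse = "")
    pos <- sample(2:20, 1)
    b <- substr(seq1, pos, pos)
    a <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    lab1 <- classify_sbs96(
      data.frame(chrom = "1", pos = pos, ref = b, alt = a),
      stats::setNames(seq1, "1"))
    lab2 <- classify_sbs96(
      data.frame(chrom = "1", pos = 21 - pos + 1,
                 ref = chartr("ACGT", "TGCA", b),
                 alt = chartr("ACGT", "TGCA", a)),
      stats::setNames(revcomp(seq1), "1"))
    expect_identical(lab1, lab2)
  }
})

test_that("window assignment is half-open, contiguous and gap-free", {
  v <- data.frame(chrom = "1", pos = c(1L, 1000000L, 1000001L))
  expect_equal(assign_window(v), c("win_1_0", "win_1_0", "win_1_1"))
  expect_error(assign_window(data.frame(chrom = "1", pos = 0L)))

  # a 3 Mb chromosome tiles into exactly 3 windows when variants span it
  pos <- seq(1L, 3000000L, by = 9973L)
  w <- assign_window(data.frame(chrom = "1", pos = pos))
  expect_setequal(unique(w), c("win_1_0", "win_1_1", "win_1_2"))
  # brute-force enumeration agrees
  expect_equal(w, paste0("win_1_", (pos - 1) %/% 1e6))
  # every variant maps to exactly one window by construction
  expect_length(w, length(pos))
})

test_that("gene membership follows the consequence policy", {
  v <- data.frame(gene = c("BRCA1", "BRCA1", "TP53", NA),
                  consequence = c("missense", "loss_of_function",
                                  "loss_of_function", "missense"),
                  pathogenic_flag = c(FALSE, FALSE, FALSE, TRUE))
  strict <- gene_burden_membership(v, c("BRCA1"))
  expect_identical(strict, c(NA, "BRCA1", NA, NA))
  sens <- gene_burden_membership(v, c("BRCA1"), "lof_missense_pathogenic")
  expect_identical(sens, c("BRCA1", "BRCA1", NA, NA))
  # pathogenic flag qualifies regardless of consequence class
  v$pathogenic_flag[1] <- TRUE
  expect_identical(gene_burden_membership(v, "BRCA1")[1], "BRCA1")
  # gene not on the panel never contributes
  expect_identical(gene_burden_membership(v, "TP53"),
                   c(NA, NA, "TP53", NA))
})

test_that("burden matrix evaluates the aggregation formula", {
  U <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 1), x = 1, dims = c(3, 1),
                            dimnames = list(NULL, "f1"))
  fs <- structure(list(membership = U,
                       features = data.frame(id = "f1", family = "gene")),
                  class = "meta_feature_set")
  X <- matrix(c(0, 1, 2), 1, 3)
  S <- build_burden_matrix(X, fs, maf = rep(0.005, 3))
  expect_equal(unname(S[1, 1]), 2)  # 0*1 + 1*0 + 2*1

  # all-zero genotype row gives an all-zero burden row
  S0 <- build_burden_matrix(matrix(0, 1, 3), fs, maf = rep(0.005, 3))
  expect_true(all(S0 == 0))

  # missing genotypes contribute zero
  Xna <- matrix(c(NA, 1, 2), 1, 3)
  expect_equal(unname(build_burden_matrix(Xna, fs,
                                          maf = rep(0.005, 3))[1, 1]), 2)

  # variants at or above the MAF cap are excluded
  expect_equal(unname(build_burden_matrix(X, fs,
                                          maf = c(0.005, 0.005, 0.02))[1, 1]),
               0)
  expect_error(build_burden_matrix(matrix(0, 1, 2), fs,
                                   maf = rep(0.005, 2)), "align")
})

test_that("burden matrix equals brute-force double-loop summation", {
  set.seed(11)
  for (rep in 1:3) {
    n <- 20; d <- 30; p <- 7
    X <- matrix(sample(0:2, n * d, replace = TRUE, prob = c(0.8, 0.15, 0.05)),
                n, d)
    Umat <- matrix(rbinom(d * p, 1, 0.3), d, p,
                   dimnames = list(NULL, paste0("f", 1:p)))
    fs <- structure(list(membership = Matrix::Matrix(Umat, sparse = TRUE),
                         features = data.frame(id = paste0("f", 1:p),
                                               family = "gene")),
                    class = "meta_feature_set")
    S <- build_burden_matrix(X, fs, maf = rep(0.004, d))
    oracle <- matrix(0, n, p)
    for (i in 1:n) for (l in 1:p) for (j in 1:d) {
      oracle[i, l] <- oracle[i, l] + X[i, j] * Umat[j, l]
    }
    expect_equal(unname(S), oracle, ignore_attr = TRUE)
  }
})

test_that("SBS-96 burdens conserve the rare SNV minor-allele total", {
  co <- null_cohort()
  fam <- attr(co$burdens, "family")
  sbs_total <- rowSums(co$burdens[, fam == "sbs96", drop = FALSE])
  # independent tally from genotypes: rare SNVs with both flanks present
  lab <- classify_sbs96(co$variants, co$reference)
  rare_ctx <- which(!is.na(lab) & co$variants$maf < 0.01)
  oracle <- as.vector(as.matrix(co$genotypes[, rare_ctx, drop = FALSE]) %*%
                        rep(1, length(rare_ctx)))
  expect_equal(unname(sbs_total), oracle)
})

test_that("low-count pruning is decided on the training set alone", {
  B <- matrix(0, 10, 3, dimnames = list(paste0("i", 1:10),
                                        c("a", "b", "c")))
  B[1:5, 1] <- 1          # training sum 5 -> kept
  B[1:4, 2] <- 1          # training sum 4 -> dropped
  B[6:10, 3] <- 100       # big counts outside training do not rescue it
  pr <- prune_low_count_features(B, paste0("i", 1:5), min_count = 5)
  expect_identical(colnames(pr), "a")

  expect_identical(colnames(prune_low_count_features(B, paste0("i", 1:5),
                                                     min_count = 0)),
                   c("a", "b", "c"))
  expect_error(prune_low_count_features(B, character(0)), "empty")

  # permuting non-training rows never changes the decision
  B2 <- B
  B2[6:10, ] <- B2[sample(6:10), ]
  pr2 <- prune_low_count_features(B2, paste0("i", 1:5), min_count = 5)
  expect_identical(colnames(pr2), colnames(pr))
})
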