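test_that("histone score applies the strand shift and half-open window", {
  genes <- data.frame(gene_id = "G1", chrom = "chr1", strand = "+",
                      tss = 10000, stringsAsFactors = FALSE)
  tags <- data.frame(chrom = "chr1",
                     pos5 = c(11900L, 11950L),   # shifted: 11973 in, 12023 out
                     strand = c("+", "+"), stringsAsFactors = FALSE)
  expect_equal(unname(histone_score(genes, tags)), 1)
  # minus-strand tag shifts backwards: 12050 - 73 = 11977, inside
  tags2 <- data.frame(chrom = "chr1", pos5 = 12050L, strand = "-",
                      stringsAsFactors = FALSE)
  expect_equal(unname(histone_score(genes, tags2)), 1)
  # no tags on the gene's chromosome
  tags3 <- data.frame(chrom = "chr9", pos5 = 10000L, strand = "+",
                      stringsAsFactors = FALSE)
  expect_equal(unname(histone_score(genes, tags3)), 0)
})

test_that("histone score equals the brute-force oracle on random fixtures", {
  set.seed(101)
  for (rep in 1:30) {
    genes <- random_genes(5)
    tags <- random_tags(200)
    expect_identical(unname(histone_score(genes, tags)),
                     brute_force_histone_score(genes, tags))
  }
})

test_that("scores are invariant to a common translation of tags and TSSs", {
  set.seed(5)
  genes <- random_genes(8)
  tags <- random_tags(300)
  off <- 12345L
  genes2 <- genes; genes2$tss <- genes2$tss + off
  tags2 <- tags; tags2$pos5 <- tags2$pos5 + off
  expect_identical(histone_score(genes, tags), histone_score(genes2, tags2))
})

test_that("score matrix assembly follows mark order and rejects duplicates", {
  set.seed(9)
  genes <- random_genes(6)
  mk <- list(H3K4me3 = random_tags(100), H3K27me3 = random_tags(100))
  A <- build_score_matrix(genes, mk)
  expect_equal(colnames(A), c("H3K4me3", "H3K27me3"))
  expect_equal(unname(A[, "H3K4me3"]),
               unname(histone_score(genes, mk$H3K4me3)))
  Ap <- build_score_matrix(genes, mk[c(2, 1)])
  expect_equal(Ap, A[, c(2, 1)])
  expect_error(build_score_matrix(genes, list(a = mk[[1]], a = mk[[2]])),
               "duplicate")
})

test_that("methylation scores match their closed forms", {
  genes <- data.frame(gene_id = "G1", chrom = "chr1", strand = "+",
                      tss = 10000, stringsAsFactors = FALSE)
  # fractions 0.2, 0.4, 0.9 inside the window
  sites <- data.frame(chrom = "chr1", pos = c(9000L, 10000L, 11000L),
                      coverage = c(10L, 10L, 10L),
                      meth_reads = c(2L, 4L, 9L),
                      fraction = c(0.2, 0.4, 0.9), stringsAsFactors = FALSE)
  smfs <- methylation_score(genes, sites,
                            scoring_config(meth_method = "SMFS"))
  mmfs <- methylation_score(genes, sites,
                            scoring_config(meth_method = "MMFS"))
  expect_equal(unname(smfs$score), 1.5)
  expect_equal(unname(mmfs$score), 0.5)
  expect_equal(unname(smfs$n_cpg), 3L)

  sites2 <- data.frame(chrom = "chr1", pos = c(10000L, 10100L),
                       coverage = c(10L, 2L), meth_reads = c(5L, 0L),
                       fraction = c(0.5, 0), stringsAsFactors = FALSE)
  mmfr <- methylation_score(genes, sites2,
                            scoring_config(meth_method = "MMFR"))
  expect_equal(unname(mmfr$score), 5 / 12)

  # SMRR closed forms: weight 1 at the TSS, exp(-2000/5000) at d = 2000
  at_tss <- data.frame(chrom = "chr1", pos = 10000L, coverage = 1L,
                       meth_reads = 1L, fraction = 1, stringsAsFactors = FALSE)
  smrr <- methylation_score(genes, at_tss,
                            scoring_config(meth_method = "SMRR"))
  expect_equal(unname(smrr$score), 1.0)
  at_edge <- data.frame(chrom = "chr1", pos = 8000L, coverage = 1L,
                        meth_reads = 1L, fraction = 1,
                        stringsAsFactors = FALSE)
  smrr2 <- methylation_score(genes, at_edge,
                             scoring_config(meth_method = "SMRR"))
  expect_equal(unname(smrr2$score), exp(-0.4), tolerance = 1e-12)
})

test_that("MMFS times assayed-CpG count reproduces SMFS on random fixtures", {
  set.seed(21)
  for (rep in 1:10) {
    genes <- random_genes(10)
    npos <- 400
    cov <- rpois(npos, 6)
    meth <- rbinom(npos, cov, runif(npos))
    sites <- data.frame(chrom = sample(c("chr1", "chr2"), npos, TRUE),
                        pos = sample(4000:102000, npos),
                        coverage = cov, meth_reads = meth,
                        fraction = ifelse(cov > 0, meth / pmax(cov, 1), NA),
                        stringsAsFactors = FALSE)
    smfs <- methylation_score(genes, sites,
                              scoring_config(meth_method = "SMFS"))
    mmfs <- methylation_score(genes, sites,
                              scoring_config(meth_method = "MMFS"))
    mmfr <- methylation_score(genes, sites,
                              scoring_config(meth_method = "MMFR"))
    ok <- !is.na(mmfs$score)
    expect_equal(mmfs$score[ok] * mmfs$n_cpg[ok], smfs$score[ok],
                 tolerance = 1e-12)
    expect_true(all(mmfr$score[!is.na(mmfr$score)] >= 0 &
                    mmfr$score[!is.na(mmfr$score)] <= 1))
    # SMRR weights lie in (0, 1], so SMRR <= total methylated reads
    smrr <- methylation_score(genes, sites,
                              scoring_config(meth_method = "SMRR"))
    expect_true(all(smrr$score[ok] >= 0))
  }
})

test_that("genes without assayed CpGs are masked, not errored", {
  genes <- data.frame(gene_id = c("G1", "G2"), chrom = c("chr1", "chr7"),
                      strand = "+", tss = c(10000, 10000),
                      stringsAsFactors = FALSE)
  sites <- data.frame(chrom = "chr1", pos = 10000L, coverage = 0L,
                      meth_reads = 0L, fraction = NA_real_,
                      stringsAsFactors = FALSE)
  ms <- methylation_score(genes, sites, scoring_config(meth_method = "MMFS"))
  expect_true(all(is.na(ms$score)))
  expect_equal(unname(ms$n_cpg), c(0L, 0L))
})

test_that("naive augmentation appends a column without touching the rest", {
  set.seed(2)
  A <- matrix(rpois(40, 5), 10, 4,
              dimnames = list(paste0("G", 1:10), paste0("M", 1:4)))
  meth <- runif(10); meth[3] <- NA
  A2 <- naive_augment(A, meth, "MMFS")
  expect_equal(dim(A2), c(10, 5))
  expect_equal(A2[, 1:4], A)
  expect_equal(unname(A2[3, "MMFS"]), 0)      # zero-imputed
  A3 <- naive_augment(A, meth, "MMFS", na_policy = "drop")
  expect_equal(nrow(A3), 9)
  expect_error(naive_augment(A2, meth, "MMFS"), "already present")
  # delete the new column -> original matrix
  expect_equal(A2[, colnames(A), drop = FALSE], A)
})
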