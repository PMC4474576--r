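# In-code fixtures and independent oracles shared across the suite.

# random gene annotation on a couple of chromosomes
random_genes <- function(n, chroms = c("chr1", "chr2")) {
  data.frame(gene_id = sprintf("G%03d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             tss = sample(5000:100000, n),
             stringsAsFactors = FALSE)
}

random_tags <- function(n, chroms = c("chr1", "chr2"), lo = 0, hi = 105000) {
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             pos5 = sample(lo:hi, n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# independent brute-force oracle for the histone score: a plain double loop
# over (gene, tag) pairs, written without any interval machinery
brute_force_histone_score <- function(genes, tags, window_bp = 2000,
                                      shift_bp = 73) {
  out <- numeric(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    cnt <- 0L
    for (k in seq_len(nrow(tags))) {
      if (tags$chrom[k] != genes$chrom[i]) next
      p <- if (tags$strand[k] == "+") tags$pos5[k] + shift_bp
           else tags$pos5[k] - shift_bp
      if (p >= genes$tss[i] - window_bp && p < genes$tss[i] + window_bp) {
        cnt <- cnt + 1L
      }
    }
    out[i] <- cnt
  }
  out
}

# independent OLS oracle via the normal equations
normal_equations_fit <- function(X, y) {
  Xi <- cbind(1, X)
  solve(t(Xi) %*% Xi, t(Xi) %*% y)[, 1]
}

# write a BED6 tag file for a tag data frame (fixed 36 bp reads)
write_tags_bed <- function(tags, path) {
  start <- ifelse(tags$strand == "+", tags$pos5, tags$pos5 - 35L)
  writeLines(paste(tags$chrom, start, start + 36L,
                   paste0("r", seq_len(nrow(tags))), 0L, tags$strand,
                   sep = "\t"), path)
  path
}

# small synthetic dataset reused by several test files
small_dataset <- function(seed = 7, n = 1200) {
  simulate_dataset(synthetic_config(n_genes = n, seed = seed))
}

paper_topology <- "(MMFS:(H2A.Z:H2A.Z-|H2A.Z+)|MMFS+)"

balanced_accuracy <- function(truth, pred) {
  (mean(pred[truth]) + mean(!pred[!truth])) / 2
}
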