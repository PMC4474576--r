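#' Configuration for the synthetic chromatin/expression generator
#'
#' Defines a toy chromosome of well-separated genes, each drawn from one of
#' four latent regulatory classes whose chromatin and expression structure
#' mirrors a promoter-localised histone/methylation code:
#' \describe{
#'   \item{silenced}{high promoter methylation and H3K9me3, near-zero
#'     expression with a weak residual repression-depth gradient,}
#'   \item{bivalent}{H3K4me3 + H3K27me3 + H2A.Z (poised), low expression,
#'     H3K4me3 acting mildly repressive in this context,}
#'   \item{active}{high H3K4me3, unmethylated, high expression,}
#'   \item{repressed}{high H3K27me3, unmethylated, low expression (silenced
#'     by Polycomb-like activity rather than methylation).}
#' }
#' Tag counts are Poisson with per-gene Gamma rate heterogeneity
#' (overdispersed, as real ChIP-seq coverage is); tag centres are Normal
#' around the TSS and recorded as strand-shifted 5' read ends, so the
#' promoter-window scorer recovers the generator's realised scores exactly.
#' Per-CpG methylation is Binomial around a per-gene Beta level. Expression
#' is class-conditional and linear on the arsinh scale in the realised
#' scores, with Normal noise applied on that scale and two pseudo-replicates
#' sharing scores but not noise.
#'
#' @param n_genes Number of genes.
#' @param seed Integer seed; every draw is reproducible from it.
#' @param class_proportions Named proportions over the four classes
#'   (must sum to 1).
#' @param tag_rates Class-by-mark matrix of mean tag counts per promoter.
#' @param rate_shape Gamma shape of the per-gene rate heterogeneity.
#' @param tag_sd SD (bp) of tag centre positions around the TSS.
#' @param cpg_per_promoter CpGs simulated per promoter.
#' @param cpg_coverage Mean per-CpG read coverage (Poisson).
#' @param meth_beta Class-by-2 matrix of Beta(a, b) parameters for the
#'   per-gene methylation level.
#' @param expr_intercept Named per-class intercept (arsinh scale).
#' @param expr_coef Class-by-mark coefficient matrix (arsinh scale, applied
#'   to arsinh of the realised scores).
#' @param noise_sd Expression noise SD on the arsinh scale.
#' @param chrom,tss_start,tss_spacing Toy chromosome layout; spacing keeps
#'   promoter windows disjoint.
#' @param window_bp,shift_bp Promoter window and nucleosome shift used for
#'   the generator's internal realised-score bookkeeping (match
#'   [scoring_config()]).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_genes = 5000L, seed = 1L,
    class_proportions = c(silenced = 0.40, bivalent = 0.20,
                          active = 0.25, repressed = 0.15),
    tag_rates = rbind(silenced  = c(H3K4me3 = 5,  H3K27me3 = 15, H3K9me3 = 60, H2A.Z = 5),
                      bivalent  = c(H3K4me3 = 60, H3K27me3 = 60, H3K9me3 = 5,  H2A.Z = 80),
                      active    = c(H3K4me3 = 100, H3K27me3 = 5, H3K9me3 = 5,  H2A.Z = 25),
                      repressed = c(H3K4me3 = 8,  H3K27me3 = 60, H3K9me3 = 10, H2A.Z = 8)),
    rate_shape = 3,
    tag_sd = 300,
    cpg_per_promoter = 20L,
    cpg_coverage = 10,
    meth_beta = rbind(silenced = c(9, 1), bivalent = c(1, 9),
                      active = c(1, 9), repressed = c(1, 9)),
    expr_intercept = c(silenced = 1.2, bivalent = 1.5,
                       active = 0.5, repressed = 0.5),
    expr_coef = rbind(silenced  = c(H3K4me3 = 0.25, H3K27me3 = 0,    H3K9me3 = -0.35, H2A.Z = 0),
                      bivalent  = c(H3K4me3 = -0.2, H3K27me3 = -0.2, H3K9me3 = 0,     H2A.Z = 0),
                      active    = c(H3K4me3 = 1.0,  H3K27me3 = -0.6, H3K9me3 = 0,     H2A.Z = 0),
                      repressed = c(H3K4me3 = 1.0,  H3K27me3 = -0.6, H3K9me3 = 0,     H2A.Z = 0)),
    noise_sd = 0.5,
    chrom = "chrS", tss_start = 10000L, tss_spacing = 50000L,
    window_bp = 2000L, shift_bp = 73L) {
  classes <- rownames(tag_rates)
  stopifnot(!is.null(classes),
            identical(sort(names(class_proportions)), sort(classes)),
            identical(sort(rownames(meth_beta)), sort(classes)),
            identical(sort(rownames(expr_coef)), sort(classes)),
            identical(sort(names(expr_intercept)), sort(classes)),
            identical(colnames(tag_rates), colnames(expr_coef)))
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class_proportions must sum to 1", call. = FALSE)
  }
  if (any(tag_rates < 0) || any(meth_beta <= 0) || cpg_coverage < 0 ||
      noise_sd < 0 || tag_sd < 0 || rate_shape <= 0) {
    stop("rates, Beta parameters and SDs must be non-negative", call. = FALSE)
  }
  structure(list(
    n_genes = as.integer(n_genes), seed = as.integer(seed),
    class_proportions = class_proportions[classes],
    classes = classes, marks = colnames(tag_rates),
    tag_rates = tag_rates, rate_shape = rate_shape, tag_sd = tag_sd,
    cpg_per_promoter = as.integer(cpg_per_promoter),
    cpg_coverage = cpg_coverage,
    meth_beta = meth_beta[classes, , drop = FALSE],
    expr_intercept = expr_intercept[classes],
    expr_coef = expr_coef[classes, , drop = FALSE],
    noise_sd = noise_sd, chrom = chrom,
    tss_start = as.integer(tss_start),
    tss_spacing = as.integer(tss_spacing),
    window_bp = as.integer(window_bp), shift_bp = as.integer(shift_bp)),
    class = "synthetic_config")
}

#' Analytic expected scores per class (simulation oracle)
#'
#' Expected histone score per class and mark (mean tag rate times the
#' probability that a tag centre lands inside the promoter window) and
#' expected MMFS per class (the Beta mean of the methylation level).
#'
#' @param config A [synthetic_config()].
#' @return List with matrices/vectors `histone` (class x mark) and `mmfs`
#'   (per class).
#' @export
expected_scores <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  w <- config$window_bp
  # rounded Normal offset lands in [-w, w - 1]
  p_in <- stats::pnorm(w - 0.5, sd = config$tag_sd) -
    stats::pnorm(-w - 0.5, sd = config$tag_sd)
  list(histone = config$tag_rates * p_in,
       mmfs = stats::setNames(
         config$meth_beta[, 1] / rowSums(config$meth_beta),
         config$classes))
}

#' Simulate a matched chromatin/expression dataset
#'
#' Draws gene classes, per-mark tag files, an RRBS CpG table and a
#' two-replicate expression table with planted class-conditional structure
#' (see [synthetic_config()]), together with the ground truth: class
#' labels, the realised gene-by-regulator score matrix (histone marks plus
#' MMFS) and the generating coefficients.
#'
#' @param config A [synthetic_config()].
#' @return Object of class `synthetic_dataset`: `genes`, `tags` (named list
#'   of per-mark tag data frames), `meth`, `expression` (gene_id, rpkm_1,
#'   rpkm_2) and `truth` (list: `class`, `pi`, `scores`, `config`).
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_genes
  w <- config$window_bp
  cls <- sample(config$classes, n, replace = TRUE,
                prob = config$class_proportions)
  tss <- config$tss_start + (seq_len(n) - 1L) * config$tss_spacing
  genes <- data.frame(gene_id = sprintf("G%05d", seq_len(n)),
                      chrom = config$chrom,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      tss = as.integer(tss), stringsAsFactors = FALSE)
  # per-mark tags; realised score = tags whose centre offset lies in
  # [-w, w - 1], i.e. exactly what the half-open promoter window counts
  tags <- list()
  scores <- matrix(0, n, length(config$marks),
                   dimnames = list(genes$gene_id,
                                   c(config$marks)))
  for (mk in config$marks) {
    lam <- config$tag_rates[cls, mk]
    rate_g <- stats::rgamma(n, shape = config$rate_shape,
                            rate = config$rate_shape / pmax(lam, 1e-9))
    counts <- stats::rpois(n, rate_g)
    gi <- rep(seq_len(n), counts)
    off <- as.integer(round(stats::rnorm(sum(counts), 0, config$tag_sd)))
    centre <- tss[gi] + off
    strand <- sample(c("+", "-"), sum(counts), replace = TRUE)
    pos5 <- ifelse(strand == "+", centre - config$shift_bp,
                   centre + config$shift_bp)
    tags[[mk]] <- data.frame(chrom = config$chrom, pos5 = as.integer(pos5),
                             strand = strand, stringsAsFactors = FALSE)
    inwin <- off >= -w & off <= w - 1L
    scores[, mk] <- tabulate(gi[inwin], nbins = n)
  }
  # RRBS: CpG offsets within +/-1500 bp (inside every promoter window)
  k <- config$cpg_per_promoter
  pi_gene <- stats::rbeta(n, config$meth_beta[cls, 1],
                          config$meth_beta[cls, 2])
  cpg_off <- t(vapply(seq_len(n), function(i) {
    sort(sample(seq(-1500L, 1499L), k))
  }, integer(k)))
  cpg_pos <- as.integer(t(cpg_off + tss))        # row-major: gene by gene
  coverage <- stats::rpois(n * k, config$cpg_coverage)
  meth_reads <- stats::rbinom(n * k, coverage, rep(pi_gene, each = k))
  meth <- data.frame(chrom = config$chrom, pos = cpg_pos,
                     coverage = as.integer(coverage),
                     meth_reads = as.integer(meth_reads),
                     stringsAsFactors = FALSE)
  gi_cpg <- rep(seq_len(n), each = k)
  assayed <- coverage > 0
  frac <- ifelse(assayed, meth_reads / pmax(coverage, 1L), NA_real_)
  n_cpg <- tabulate(gi_cpg[assayed], nbins = n)
  sum_frac <- rep(0, n)
  agg <- rowsum(frac[assayed], gi_cpg[assayed])
  sum_frac[as.integer(rownames(agg))] <- agg[, 1]
  mmfs <- ifelse(n_cpg > 0, sum_frac / pmax(n_cpg, 1L), NA_real_)
  A_truth <- cbind(scores, MMFS = mmfs)
  # class-conditional expression on the arsinh scale
  eta <- config$expr_intercept[cls] +
    rowSums(asinh(scores) * config$expr_coef[cls, , drop = FALSE])
  y1 <- sinh(pmax(0, eta + stats::rnorm(n, 0, config$noise_sd)))
  y2 <- sinh(pmax(0, eta + stats::rnorm(n, 0, config$noise_sd)))
  expression <- data.frame(gene_id = genes$gene_id,
                           rpkm_1 = y1, rpkm_2 = y2,
                           stringsAsFactors = FALSE)
  structure(list(genes = genes, tags = tags, meth = meth,
                 expression = expression,
                 truth = list(class = stats::setNames(cls, genes$gene_id),
                              pi = pi_gene, scores = A_truth,
                              eta = unname(eta), config = config)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic chromatin/expression dataset\n")
  cat(sprintf("  %d genes on %s; marks: %s\n", nrow(x$genes),
              x$truth$config$chrom,
              paste(names(x$tags), collapse = ", ")))
  print(table(x$truth$class))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits re-readable plain-text files: `annotation.bed` (BED6),
#' `tags_<mark>.bed` (BED6, one read per record), `methylation.tsv`
#' (simple RRBS dialect: chrom, pos, coverage, meth_reads),
#' `expression.tsv` (TSV with header, two replicates, full double
#' precision) and `truth_classes.tsv`.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(annotation = file.path(dir, "annotation.bed"),
             methylation = file.path(dir, "methylation.tsv"),
             expression = file.path(dir, "expression.tsv"),
             truth = file.path(dir, "truth_classes.tsv"))
  g <- dataset$genes
  writeLines(paste(g$chrom, g$tss, g$tss + 1L, g$gene_id, 0L, g$strand,
                   sep = "\t"), paths["annotation"])
  read_len <- 36L
  for (mk in names(dataset$tags)) {
    tg <- dataset$tags[[mk]]
    start <- ifelse(tg$strand == "+", tg$pos5, tg$pos5 - read_len + 1L)
    end <- start + read_len
    p <- file.path(dir, paste0("tags_", gsub("[^A-Za-z0-9]+", "_", mk),
                               ".bed"))
    writeLines(paste(tg$chrom, start, end,
                     paste0("r", seq_len(nrow(tg))), 0L, tg$strand,
                     sep = "\t"), p)
    paths[paste0("tags_", mk)] <- p
  }
  m <- dataset$meth
  writeLines(paste(m$chrom, m$pos, m$coverage, m$meth_reads, sep = "\t"),
             paths["methylation"])
  e <- dataset$expression
  writeLines(c("gene_id\trpkm_1\trpkm_2",
               paste(e$gene_id, sprintf("%.17g", e$rpkm_1),
                     sprintf("%.17g", e$rpkm_2), sep = "\t")),
             paths["expression"])
  write_class_assignments(g$gene_id, dataset$truth$class, paths["truth"])
  invisible(paths)
}
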