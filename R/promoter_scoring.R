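#' Scoring configuration
#'
#' Parameters shared by the promoter-window quantifications.
#'
#' @param window_bp Half-width of the promoter window in bp; a gene's window
#'   is the half-open interval `[tss - window_bp, tss + window_bp)`.
#' @param shift_bp Nucleosome-centre shift applied to ChIP-seq read 5' ends:
#'   `+shift_bp` for `+`-strand reads and `-shift_bp` for `-`-strand reads,
#'   centring each read on the modified nucleosome.
#' @param meth_method Gene-level methylation score: `"SMFS"` (sum of CpG
#'   methylation fractions), `"MMFS"` (mean fraction over assayed CpGs),
#'   `"MMFR"` (methylated reads / total reads in the window) or `"SMRR"`
#'   (distance-decayed sum of methylated reads).
#' @param d0 Decay constant (bp) for the SMRR weight `exp(-|d| / d0)`.
#' @param smrr_literal If `TRUE`, use the unbounded weight `-exp(|d| / d0)`
#'   instead of the decaying form; kept only for comparison.
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(window_bp = 2000L, shift_bp = 73L,
                           meth_method = c("MMFS", "SMFS", "MMFR", "SMRR"),
                           d0 = 5000, smrr_literal = FALSE) {
  meth_method <- match.arg(meth_method)
  stopifnot(window_bp > 0, d0 > 0, shift_bp >= 0)
  structure(list(window_bp = as.integer(window_bp),
                 shift_bp = as.integer(shift_bp),
                 meth_method = meth_method, d0 = d0,
                 smrr_literal = isTRUE(smrr_literal)),
            class = "scoring_config")
}

# GRanges over a shared seqlevel universe so overlap ops never warn about
# disjoint seqinfo. Positions are 0-based; +1 converts to 1-based GRanges.
.point_granges <- function(chrom, pos0, seqlevels) {
  GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = pos0 + 1L, width = 1L))
}

.window_granges <- function(genes, window_bp, seqlevels) {
  GenomicRanges::GRanges(
    seqnames = factor(genes$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = genes$tss - window_bp + 1L,
                              end = genes$tss + window_bp))
}

#' Gene-level histone score (constrained sum of shifted tags)
#'
#' For each gene, counts the ChIP-seq reads whose shifted 5'-end position
#' falls inside the half-open promoter window
#' `[tss - window_bp, tss + window_bp)`. Reads on the `+` strand are shifted
#' by `+shift_bp`, reads on the `-` strand by `-shift_bp` (default 73 bp,
#' half a nucleosome), so each count is anchored on the modified nucleosome
#' centre. Genes on chromosomes absent from the tag file score 0.
#'
#' @param genes Gene annotation data frame (see [read_tss_annotation()]).
#' @param tags Tag data frame (see [read_tag_file()]).
#' @param config A [scoring_config()].
#' @return Numeric vector of counts, one per gene, named by gene id.
#' @export
histone_score <- function(genes, tags, config = scoring_config()) {
  stopifnot(is.data.frame(genes), is.data.frame(tags))
  out <- stats::setNames(numeric(nrow(genes)), genes$gene_id)
  if (nrow(genes) == 0) return(out)
  if (nrow(tags) == 0) return(out)
  shifted <- ifelse(tags$strand == "+",
                    tags$pos5 + config$shift_bp,
                    tags$pos5 - config$shift_bp)
  lv <- union(unique(genes$chrom), unique(tags$chrom))
  win <- .window_granges(genes, config$window_bp, lv)
  pts <- .point_granges(tags$chrom, as.integer(shifted), lv)
  out[] <- GenomicRanges::countOverlaps(win, pts)
  out
}

#' Assemble the gene-by-mark histone score matrix
#'
#' @param genes Gene annotation data frame.
#' @param mark_tags Named list mapping mark name to a tag data frame; column
#'   order of the result follows the list order.
#' @param config A [scoring_config()].
#' @return Numeric matrix, genes x marks, with gene-id row names.
#' @export
build_score_matrix <- function(genes, mark_tags, config = scoring_config()) {
  stopifnot(is.list(mark_tags), length(mark_tags) >= 1)
  nms <- names(mark_tags)
  if (is.null(nms) || any(nms == "")) {
    stop("mark_tags must be a fully named list", call. = FALSE)
  }
  if (anyDuplicated(nms)) {
    stop("duplicate mark names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  A <- vapply(mark_tags, function(tg) histone_score(genes, tg, config),
              numeric(nrow(genes)))
  A <- matrix(A, nrow = nrow(genes), dimnames = list(genes$gene_id, nms))
  A
}

#' Gene-level promoter DNA methylation score
#'
#' Scores each gene's promoter window (`[tss - window_bp, tss + window_bp)`)
#' from per-CpG RRBS counts. Only CpGs with coverage > 0 count as assayed.
#' The four methods:
#' \describe{
#'   \item{SMFS}{sum of per-CpG methylation fractions in the window,}
#'   \item{MMFS}{SMFS divided by the number of assayed CpGs,}
#'   \item{MMFR}{total methylated reads / total reads in the window,}
#'   \item{SMRR}{sum over CpGs of `meth_reads * exp(-|d| / d0)` where `d` is
#'     the CpG's distance from the TSS.}
#' }
#' Genes with no assayed CpG in the window get `NA` (an exclusion mask for
#' downstream fits).
#'
#' @param genes Gene annotation data frame.
#' @param sites RRBS data frame (see [read_rrbs()]).
#' @param config A [scoring_config()]; `meth_method` selects the score.
#' @return List with `score` (named numeric vector, `NA` where undefined) and
#'   `n_cpg` (named integer vector of assayed CpGs per window).
#' @export
methylation_score <- function(genes, sites, config = scoring_config()) {
  n <- nrow(genes)
  score <- stats::setNames(rep(NA_real_, n), genes$gene_id)
  n_cpg <- stats::setNames(integer(n), genes$gene_id)
  if (n == 0 || nrow(sites) == 0) return(list(score = score, n_cpg = n_cpg))
  lv <- union(unique(genes$chrom), unique(sites$chrom))
  win <- .window_granges(genes, config$window_bp, lv)
  pts <- .point_granges(sites$chrom, sites$pos, lv)
  hits <- GenomicRanges::findOverlaps(win, pts)
  gi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  assayed <- sites$coverage[si] > 0
  gi_a <- gi[assayed]; si_a <- si[assayed]
  n_cpg[] <- tabulate(gi_a, nbins = n)
  method <- config$meth_method
  if (method == "SMFS" || method == "MMFS") {
    smfs <- rep(0, n)
    agg <- rowsum(sites$fraction[si_a], gi_a)
    smfs[as.integer(rownames(agg))] <- agg[, 1]
    if (method == "SMFS") {
      score[n_cpg > 0] <- smfs[n_cpg > 0]
    } else {
      score[n_cpg > 0] <- smfs[n_cpg > 0] / n_cpg[n_cpg > 0]
    }
  } else if (method == "MMFR") {
    covs <- rep(0, n); meths <- rep(0, n)
    agg_c <- rowsum(as.numeric(sites$coverage[si_a]), gi_a)
    agg_m <- rowsum(as.numeric(sites$meth_reads[si_a]), gi_a)
    covs[as.integer(rownames(agg_c))] <- agg_c[, 1]
    meths[as.integer(rownames(agg_m))] <- agg_m[, 1]
    score[covs > 0] <- meths[covs > 0] / covs[covs > 0]
  } else { # SMRR
    d <- abs(sites$pos[si_a] - genes$tss[gi_a])
    w <- if (config$smrr_literal) -exp(d / config$d0) else exp(-d / config$d0)
    vals <- rep(0, n)
    agg <- rowsum(sites$meth_reads[si_a] * w, gi_a)
    vals[as.integer(rownames(agg))] <- agg[, 1]
    score[n_cpg > 0] <- vals[n_cpg > 0]
  }
  list(score = score, n_cpg = n_cpg)
}

#' Append a methylation score column to a score matrix
#'
#' Naive model integration: the methylation vector is concatenated as one
#' more column of the gene-by-regulator matrix, leaving the original columns
#' unchanged.
#'
#' @param A Score matrix.
#' @param meth Numeric vector of length `nrow(A)` (may contain `NA` for
#'   genes with no assayed CpG).
#' @param name Column name for the new column.
#' @param na_policy `"zero"` imputes `NA` scores as 0; `"drop"` removes those
#'   genes (rows) from the returned matrix.
#' @return The augmented matrix (n x (m + 1), or fewer rows under
#'   `"drop"`).
#' @export
naive_augment <- function(A, meth, name, na_policy = c("zero", "drop")) {
  na_policy <- match.arg(na_policy)
  stopifnot(is.matrix(A))
  if (length(meth) != nrow(A)) {
    stop("meth must have one value per gene (", nrow(A), "), got ",
         length(meth), call. = FALSE)
  }
  if (name %in% colnames(A)) {
    stop("column '", name, "' already present", call. = FALSE)
  }
  meth <- as.numeric(meth)
  if (na_policy == "zero") {
    meth[is.na(meth)] <- 0
    keep <- seq_len(nrow(A))
  } else {
    keep <- which(!is.na(meth))
  }
  out <- cbind(A[keep, , drop = FALSE], meth[keep])
  colnames(out) <- c(colnames(A), name)
  out
}
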