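#' @title File readers and writers
#' @name genomic_io
#' @description
#' Plain-text readers/writers for the formats the pipeline touches: BED6 and
#' minimal GTF gene annotation, BED6 ChIP-seq tag files, RRBS CpG methylation
#' tables (bedMethyl or a simple 4-column dialect) and TSV expression tables.
#' All coordinates are held 0-based, half-open internally (BED convention);
#' GTF input (1-based, closed) is converted on read. All readers accept
#' gzip-compressed files.
NULL

# Connection that transparently handles .gz input.
.open_input <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

# read.table wrapper: returns a zero-row data frame for empty files and
# rethrows ragged-line errors with their line number intact.
.read_tabular <- function(path, sep = "", header = FALSE, comment.char = "#") {
  con <- .open_input(path)
  on.exit(close(con))
  out <- tryCatch(
    utils::read.table(con, sep = sep, header = header, quote = "",
                      comment.char = comment.char, stringsAsFactors = FALSE,
                      blank.lines.skip = TRUE, check.names = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) return(NULL)
      stop("parse error in ", path, ": ", conditionMessage(e), call. = FALSE)
    })
  out
}

.check_strand <- function(strand, path) {
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    stop("missing or invalid strand (must be '+' or '-') at record ",
         which(bad)[1], " of ", path, call. = FALSE)
  }
}

#' Read a TSS annotation and de-duplicate to one TSS per gene
#'
#' Reads gene annotation from BED6 or a minimal GTF and reduces multiple
#' transcripts/isoforms to a single row per gene identifier by keeping the
#' most 5'-located TSS: the minimum start for `+`-strand genes and the
#' maximum (end - 1) for `-`-strand genes. Coordinates in the returned table
#' are 0-based.
#'
#' @param path File path (optionally gzipped). BED6 columns: chrom, start,
#'   end, gene id, score, strand. GTF: standard 9 tab-separated columns with
#'   a `gene_id "..."` attribute.
#' @param format `"bed6"` or `"gtf"`.
#' @return A data frame with columns `gene_id`, `chrom`, `strand`, `tss`
#'   (0-based), one row per unique gene id.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t500\tG1\t0\t+", "chr1\t200\t600\tG1\t0\t+"), bed)
#' read_tss_annotation(bed, "bed6") # keeps tss = 100
#' @export
read_tss_annotation <- function(path, format = c("bed6", "gtf")) {
  format <- match.arg(format)
  empty <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), tss = integer(),
                      stringsAsFactors = FALSE)
  if (format == "bed6") {
    d <- .read_tabular(path)
    if (is.null(d)) return(empty)
    if (ncol(d) < 6) {
      stop("BED6 annotation needs >= 6 columns, found ", ncol(d),
           " in ", path, call. = FALSE)
    }
    gene_id <- as.character(d[[4]])
    chrom   <- as.character(d[[1]])
    strand  <- as.character(d[[6]])
    .check_strand(strand, path)
    start <- as.integer(d[[2]]); end <- as.integer(d[[3]])
    if (anyNA(start) || anyNA(end)) {
      stop("non-integer coordinate in ", path, call. = FALSE)
    }
    tss <- ifelse(strand == "+", start, end - 1L)
  } else {
    d <- .read_tabular(path, sep = "\t")
    if (is.null(d)) return(empty)
    if (ncol(d) < 9) {
      stop("GTF needs 9 tab-separated columns, found ", ncol(d),
           " in ", path, call. = FALSE)
    }
    attrs <- as.character(d[[9]])
    has_id <- grepl('gene_id\\s+"[^"]+"', attrs)
    if (any(!has_id)) {
      stop("GTF record ", which(!has_id)[1], " lacks a gene_id attribute",
           call. = FALSE)
    }
    gene_id <- sub('.*gene_id\\s+"([^"]+)".*', "\\1", attrs)
    chrom   <- as.character(d[[1]])
    strand  <- as.character(d[[7]])
    .check_strand(strand, path)
    # GTF is 1-based closed: 0-based TSS is start-1 (+) or end-1 (-).
    tss <- ifelse(strand == "+", as.integer(d[[4]]) - 1L,
                  as.integer(d[[5]]) - 1L)
  }
  if (any(tss < 0)) stop("negative TSS coordinate in ", path, call. = FALSE)
  # most 5' rule: smallest tss on '+', largest on '-'
  pref <- ifelse(strand == "+", tss, -tss)
  o <- order(gene_id, pref)
  keep <- o[!duplicated(gene_id[o])]
  out <- data.frame(gene_id = gene_id[keep], chrom = chrom[keep],
                    strand = strand[keep], tss = as.integer(tss[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$gene_id, gene_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a BED6 ChIP-seq tag file
#'
#' Each BED record is one mapped read, reduced to its 5'-end coordinate:
#' `start` for `+`-strand reads and `end - 1` for `-`-strand reads
#' (0-based).
#'
#' @param path BED6 file path (optionally gzipped).
#' @return Data frame with columns `chrom`, `pos5` (0-based), `strand`; one
#'   row per read.
#' @export
read_tag_file <- function(path) {
  d <- .read_tabular(path)
  if (is.null(d)) {
    return(data.frame(chrom = character(), pos5 = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  if (ncol(d) < 6) {
    stop("BED6 tag file needs >= 6 columns, found ", ncol(d),
         " in ", path, call. = FALSE)
  }
  strand <- as.character(d[[6]])
  .check_strand(strand, path)
  pos5 <- ifelse(strand == "+", as.integer(d[[2]]), as.integer(d[[3]]) - 1L)
  if (any(pos5 < 0)) stop("negative read coordinate in ", path, call. = FALSE)
  data.frame(chrom = as.character(d[[1]]), pos5 = as.integer(pos5),
             strand = strand, stringsAsFactors = FALSE)
}

#' Read an RRBS CpG methylation table
#'
#' @param path File path (optionally gzipped).
#' @param dialect `"bedmethyl"` (coverage in column 10, percent methylated in
#'   column 11; methylated read count recovered as
#'   `round(coverage * percent / 100)`) or `"simple"` (4 columns: chrom,
#'   0-based position, coverage, methylated reads; no header).
#' @return Data frame with columns `chrom`, `pos`, `coverage`, `meth_reads`,
#'   `fraction` (`meth_reads / coverage`; `NA` where coverage is 0).
#' @export
read_rrbs <- function(path, dialect = c("bedmethyl", "simple")) {
  dialect <- match.arg(dialect)
  d <- .read_tabular(path)
  if (is.null(d)) {
    return(data.frame(chrom = character(), pos = integer(),
                      coverage = integer(), meth_reads = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  }
  if (dialect == "bedmethyl") {
    if (ncol(d) < 11) {
      stop("bedMethyl needs >= 11 columns, found ", ncol(d), " in ", path,
           call. = FALSE)
    }
    chrom <- as.character(d[[1]]); pos <- as.integer(d[[2]])
    coverage <- as.integer(d[[10]])
    pct <- as.numeric(d[[11]])
    if (any(pct < 0 | pct > 100)) {
      stop("percent methylated outside [0, 100] in ", path, call. = FALSE)
    }
    meth_reads <- as.integer(round(coverage * pct / 100))
  } else {
    if (ncol(d) < 4) {
      stop("simple RRBS dialect needs 4 columns, found ", ncol(d),
           " in ", path, call. = FALSE)
    }
    chrom <- as.character(d[[1]]); pos <- as.integer(d[[2]])
    coverage <- as.integer(d[[3]]); meth_reads <- as.integer(d[[4]])
  }
  if (any(coverage < 0) || any(meth_reads < 0)) {
    stop("negative count in RRBS table ", path, call. = FALSE)
  }
  if (any(meth_reads > coverage)) {
    stop("meth_reads > coverage at record ",
         which(meth_reads > coverage)[1], " of ", path, call. = FALSE)
  }
  fraction <- ifelse(coverage > 0, meth_reads / coverage, NA_real_)
  data.frame(chrom = chrom, pos = pos, coverage = coverage,
             meth_reads = meth_reads, fraction = fraction,
             stringsAsFactors = FALSE)
}

#' Read an expression table and select a replicate
#'
#' @param path TSV with a header row; gene ids in the first column, one RPKM
#'   column per replicate in the remaining columns.
#' @param replicate 1-based replicate index, or `"mean"` for the per-gene
#'   mean across all replicate columns.
#' @return Data frame with columns `gene_id` and `rpkm`.
#' @export
read_expression <- function(path, replicate = 1) {
  d <- .read_tabular(path, sep = "\t", header = TRUE, comment.char = "")
  if (is.null(d) || ncol(d) < 2) {
    stop("expression table needs a header and >= 2 columns: ", path,
         call. = FALSE)
  }
  gene_id <- as.character(d[[1]])
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene id '", gene_id[duplicated(gene_id)][1],
         "' in ", path, call. = FALSE)
  }
  reps <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(reps) <- "double"
  if (any(reps < 0, na.rm = TRUE)) {
    stop("negative RPKM value in ", path, call. = FALSE)
  }
  if (identical(replicate, "mean")) {
    rpkm <- rowMeans(reps)
  } else {
    replicate <- as.integer(replicate)
    if (is.na(replicate) || replicate < 1 || replicate > ncol(reps)) {
      stop("replicate must be 'mean' or an index in 1..", ncol(reps),
           call. = FALSE)
    }
    rpkm <- reps[, replicate]
  }
  data.frame(gene_id = gene_id, rpkm = as.numeric(rpkm),
             stringsAsFactors = FALSE)
}

#' Write per-gene regulatory class assignments
#'
#' @param genes A gene annotation data frame (with a `gene_id` column) or a
#'   character vector of gene ids.
#' @param labels Character vector of class labels, one per gene.
#' @param path Output TSV path.
#' @param valid_labels Optional character vector (e.g. the fitted tree's leaf
#'   names); any label outside this set is an error.
#' @return `path`, invisibly.
#' @export
write_class_assignments <- function(genes, labels, path, valid_labels = NULL) {
  ids <- if (is.data.frame(genes)) as.character(genes$gene_id)
         else as.character(genes)
  labels <- as.character(labels)
  if (length(ids) != length(labels)) {
    stop("length mismatch: ", length(ids), " genes vs ", length(labels),
         " labels", call. = FALSE)
  }
  if (!is.null(valid_labels)) {
    bad <- setdiff(unique(labels), valid_labels)
    if (length(bad)) {
      stop("unknown class label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  utils::write.table(
    data.frame(gene_id = ids, class = labels, stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read class assignments written by [write_class_assignments()]
#' @param path TSV path.
#' @return Data frame with columns `gene_id`, `class`.
#' @export
read_class_assignments <- function(path) {
  d <- .read_tabular(path, sep = "\t", header = TRUE, comment.char = "")
  data.frame(gene_id = as.character(d[[1]]), class = as.character(d[[2]]),
             stringsAsFactors = FALSE)
}

#' Write a gene-by-regulator score matrix as TSV
#'
#' First column `gene_id`, then one column per regulator; missing scores
#' written as `NA`. Values are written at full double precision so that a
#' write/read round trip is lossless.
#'
#' @param A Numeric matrix with gene ids as row names and regulator names as
#'   column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(A, path) {
  stopifnot(is.matrix(A), !is.null(rownames(A)), !is.null(colnames(A)))
  cells <- apply(A, 2, function(x) {
    ifelse(is.na(x), "NA", sprintf("%.17g", x))
  })
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = nrow(A))
  lines <- c(paste(c("gene_id", colnames(A)), collapse = "\t"),
             paste(rownames(A), apply(cells, 1, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a score matrix written by [write_score_matrix()]
#' @param path TSV path.
#' @return Numeric matrix with gene-id row names and regulator column names.
#' @export
read_score_matrix <- function(path) {
  d <- .read_tabular(path, sep = "\t", header = TRUE, comment.char = "")
  A <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(A) <- "double"
  rownames(A) <- as.character(d[[1]])
  A
}
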