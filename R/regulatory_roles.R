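#' PCA of the arsinh-transformed score matrix
#'
#' Singular value decomposition `arsinh(A) = U S V'` (after optional column
#' mean-centring, the standard PCA convention). The columns of `U S` are the
#' principal components; the rows of `V'` are the loadings, one weight per
#' regulator and component.
#'
#' @param A Score matrix (n genes x m regulators, `n >= m`), no missing
#'   values — mask or impute first (see [naive_augment()]).
#' @param center Column mean-centre before decomposition (default `TRUE`;
#'   `FALSE` reproduces the raw-SVD variant).
#' @return Object of class `pca_decomp`: `U`, `S` (singular values,
#'   non-increasing), `V` (loadings, regulators x components), `pcs`
#'   (`U %*% diag(S)`), `column_means`, `regulators`.
#' @export
pca_decompose <- function(A, center = TRUE) {
  A <- as.matrix(A)
  if (anyNA(A)) {
    stop("A contains missing values; drop masked genes or impute ",
         "(see naive_augment na_policy) before PCA", call. = FALSE)
  }
  n <- nrow(A); m <- ncol(A)
  if (n < m) stop("need at least as many genes as regulators", call. = FALSE)
  X <- asinh(A)
  cm <- if (isTRUE(center)) colMeans(X) else rep(0, m)
  Xc <- sweep(X, 2, cm)
  sv <- svd(Xc)
  rownames(sv$v) <- colnames(A)
  structure(list(U = sv$u, S = sv$d, V = sv$v,
                 pcs = sweep(sv$u, 2, sv$d, `*`),
                 column_means = stats::setNames(cm, colnames(A)),
                 regulators = colnames(A), center = isTRUE(center)),
            class = "pca_decomp")
}

#' Per-component predictiveness of gene expression
#'
#' Adjusted R-squared of the univariate regression of `arsinh(y)` on each
#' principal component alone (one predictor, so `p = 1`).
#'
#' @param decomp A [pca_decompose()] result.
#' @param y Expression vector (raw RPKM), one value per gene.
#' @return Numeric vector, one adjusted R-squared per component.
#' @export
pc_predictiveness <- function(decomp, y) {
  stopifnot(inherits(decomp, "pca_decomp"))
  n <- nrow(decomp$pcs)
  if (length(y) != n) stop("length(y) != number of genes", call. = FALSE)
  ay <- asinh(y)
  vapply(seq_len(ncol(decomp$pcs)), function(c) {
    pc <- decomp$pcs[, c]
    if (stats::sd(pc) == 0 || stats::sd(ay) == 0) return(0)
    r2 <- stats::cor(pc, ay)^2
    1 - (1 - r2) * (n - 1) / (n - 2)
  }, numeric(1))
}

#' Data-derived regulatory roles
#'
#' The putative regulatory role of each regulator is its loading on the
#' principal component most predictive of expression, with the sign oriented
#' so that the selected component correlates positively with
#' `arsinh(y)` — positive loadings then read as activator-like, negative as
#' repressor-like. Ties in predictiveness resolve to the lowest component
#' index with a warning.
#'
#' @param decomp A [pca_decompose()] result.
#' @param y Expression vector (raw RPKM).
#' @return Object of class `role_loadings`: `selected_pc` (1-based index),
#'   `loadings` (named, sign-oriented) and `per_pc_adj_r2`.
#' @export
derive_roles <- function(decomp, y) {
  per_pc <- pc_predictiveness(decomp, y)
  best <- max(per_pc)
  if (sum(per_pc == best) > 1) {
    warning("tie in per-PC predictiveness; selecting the lowest index")
  }
  sel <- which.max(per_pc)
  s <- stats::cor(decomp$pcs[, sel], asinh(y))
  s <- if (is.na(s) || s >= 0) 1 else -1
  structure(list(selected_pc = sel,
                 loadings = stats::setNames(s * decomp$V[, sel],
                                            decomp$regulators),
                 per_pc_adj_r2 = per_pc),
            class = "role_loadings")
}

#' @export
print.role_loadings <- function(x, ...) {
  cat(sprintf("regulatory roles from PC%d (adj R^2 = %.4f)\n",
              x$selected_pc, x$per_pc_adj_r2[x$selected_pc]))
  print(round(x$loadings, 4))
  invisible(x)
}

#' Write derived roles as TSV
#' @param roles A [derive_roles()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roles <- function(roles, path) {
  d <- data.frame(regulator = names(roles$loadings),
                  loading = unname(roles$loadings),
                  selected_pc = roles$selected_pc,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
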