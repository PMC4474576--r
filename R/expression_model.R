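#' Inverse hyperbolic sine
#'
#' `arsinh(x) = log(x + sqrt(1 + x^2))`. Log-like for large `x`
#' (`arsinh(x) ~ log(2x)`) but defined at 0, which makes it the natural
#' variance-stabilising transform for RPKM values and tag counts: no
#' pseudo-count needs to be meta-optimised.
#'
#' @param x Numeric vector.
#' @return `asinh(x)`.
#' @export
arsinh <- function(x) asinh(x)

# Adjusted R^2 without input policing; returns NA when the observed values
# have zero variance or n <= p + 1. Used by the threshold scan, where
# degenerate subsets must drop out of the curve rather than abort it.
.adj_r2 <- function(observed, predicted, n_predictors) {
  n <- length(observed)
  if (n <= n_predictors + 1) return(NA_real_)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot <= 0) return(NA_real_)
  r2 <- 1 - sum((observed - predicted)^2) / ss_tot
  1 - (1 - r2) * (n - 1) / (n - n_predictors - 1)
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - R^2) (n - 1) / (n - p - 1)` with
#' `R^2 = 1 - SS_res / SS_tot`. The penalty prevents spurious inflation of
#' the statistic as explanatory variables are added; with `p = 0` it equals
#' plain `R^2`.
#'
#' @param observed,predicted Equal-length numeric vectors (any common scale;
#'   throughout this package both are on the arsinh scale).
#' @param n_predictors Number of explanatory variables `p`.
#' @return The adjusted R-squared.
#' @export
adjusted_r2 <- function(observed, predicted, n_predictors) {
  n <- length(observed)
  if (length(predicted) != n) stop("length mismatch", call. = FALSE)
  if (n <= n_predictors + 1) {
    stop("need n > n_predictors + 1 (n = ", n, ", p = ", n_predictors, ")",
         call. = FALSE)
  }
  if (sum((observed - mean(observed))^2) <= 0) {
    stop("observed values have zero variance", call. = FALSE)
  }
  .adj_r2(observed, predicted, n_predictors)
}

# Predictor design: optionally arsinh-transform score columns.
.design <- function(A, transform) {
  X <- as.matrix(A)
  storage.mode(X) <- "double"
  if (transform) X <- asinh(X)
  X
}

#' Fit the arsinh-linear gene expression model
#'
#' Ordinary least squares of `arsinh(y)` on the score columns of `A` plus an
#' intercept:
#' `arsinh(y_i) = mu + sum_j beta_j x_ij + eps_i`,
#' where `x_ij` is `arsinh(a_ij)` by default (`transform_predictors = TRUE`;
#' tag counts have heavy right tails) or the raw score `a_ij` otherwise.
#' Genes with a missing value in `y` or any used score column are excluded
#' from the fit.
#'
#' @param A Score matrix (genes x regulators, with column names).
#' @param y Non-negative expression vector (raw RPKM scale), length
#'   `nrow(A)`.
#' @param transform_predictors Arsinh-transform the score columns before
#'   fitting (default `TRUE`).
#' @param weights Optional non-negative observation weights.
#' @return An object of class `expr_fit`: intercept `mu` (basal expression,
#'   arsinh scale), named coefficients `beta`, `residuals`, `fitted`, `r2`,
#'   `adj_r2`, `n_obs`, `n_predictors`, the gene ids used, and the transform
#'   flag.
#' @export
fit_linear <- function(A, y, transform_predictors = TRUE, weights = NULL) {
  stopifnot(is.matrix(A) || is.data.frame(A))
  A <- as.matrix(A)
  if (is.null(colnames(A))) {
    stop("A must have regulator column names", call. = FALSE)
  }
  if (length(y) != nrow(A)) stop("length(y) != nrow(A)", call. = FALSE)
  keep <- stats::complete.cases(A) & !is.na(y)
  A <- A[keep, , drop = FALSE]
  y <- y[keep]
  if (!is.null(weights)) weights <- weights[keep]
  n <- nrow(A); m <- ncol(A)
  if (n <= m + 1) {
    stop("need n > m + 1 complete observations (n = ", n, ", m = ", m, ")",
         call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, .design(A, transform_predictors))
  qx <- qr(if (is.null(weights)) X else X * sqrt(weights))
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  ay <- asinh(y)
  fit <- if (is.null(weights)) stats::lm.fit(X, ay)
         else stats::lm.wfit(X, ay, w = weights)
  fitted <- ay - fit$residuals
  ss_tot <- sum((ay - mean(ay))^2)
  r2 <- if (ss_tot <= 0) 0 else 1 - sum(fit$residuals^2) / ss_tot
  adj <- if (ss_tot <= 0) 0 else 1 - (1 - r2) * (n - 1) / (n - m - 1)
  structure(list(
    mu = unname(fit$coefficients[1]),
    beta = fit$coefficients[-1],
    predictors = colnames(A),
    transform = isTRUE(transform_predictors),
    residuals = stats::setNames(fit$residuals, rownames(A)),
    fitted = stats::setNames(fitted, rownames(A)),
    r2 = r2, adj_r2 = adj,
    n_obs = n, n_predictors = m,
    gene_ids = rownames(A)), class = "expr_fit")
}

#' @export
print.expr_fit <- function(x, ...) {
  cat("arsinh-linear expression model\n")
  cat(sprintf("  n = %d genes, %d predictor(s)%s\n", x$n_obs, x$n_predictors,
              if (x$transform) " (arsinh-transformed)" else ""))
  cat(sprintf("  mu = %.4f, adj R^2 = %.4f\n", x$mu, x$adj_r2))
  print(round(x$beta, 4))
  invisible(x)
}

#' Predict arsinh-expression from a fitted model
#'
#' Columns of `A` are aligned to the fit's predictors by name, so column
#' order is irrelevant; missing predictor columns are an error. Predictions
#' are on the arsinh scale used at fit time.
#'
#' @param object An `expr_fit`.
#' @param A Score matrix containing at least the fit's predictor columns.
#' @param ... Unused.
#' @return Numeric vector of predicted arsinh-expression values.
#' @export
predict.expr_fit <- function(object, A, ...) {
  A <- as.matrix(A)
  missing_cols <- setdiff(object$predictors, colnames(A))
  if (length(missing_cols)) {
    stop("score matrix lacks predictor column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- .design(A[, object$predictors, drop = FALSE], object$transform)
  drop(object$mu + X %*% object$beta)
}

#' Evaluation scheme for expression models
#'
#' @param mode `"in_sample"` (the fit's own adjusted R-squared), `"kfold"`
#'   (pooled out-of-fold predictions scored once) or `"replicate_holdout"`
#'   (fit on one RNA-seq replicate, score against another).
#' @param k Fold count for `"kfold"` (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @return A list of class `eval_scheme`.
#' @export
eval_scheme <- function(mode = c("in_sample", "kfold", "replicate_holdout"),
                        k = 10L, seed = 1L) {
  mode <- match.arg(mode)
  k <- as.integer(k)
  if (mode == "kfold" && k < 2) stop("kfold needs k >= 2", call. = FALSE)
  structure(list(mode = mode, k = k, seed = as.integer(seed)),
            class = "eval_scheme")
}

#' Evaluate prediction accuracy of the arsinh-linear model
#'
#' @param A Score matrix.
#' @param y Expression vector (raw RPKM), length `nrow(A)`: the training
#'   replicate.
#' @param scheme An [eval_scheme()].
#' @param predictors Optional subset of column names to use.
#' @param y2 Second expression replicate, required for
#'   `"replicate_holdout"`.
#' @param transform_predictors Passed to [fit_linear()].
#' @return List with `adj_r2` and `predictions` (arsinh scale; out-of-fold
#'   predictions for `"kfold"`).
#' @export
evaluate_model <- function(A, y, scheme = eval_scheme(), predictors = NULL,
                           y2 = NULL, transform_predictors = TRUE) {
  A <- as.matrix(A)
  if (!is.null(predictors)) {
    missing_cols <- setdiff(predictors, colnames(A))
    if (length(missing_cols)) {
      stop("unknown predictor(s): ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    A <- A[, predictors, drop = FALSE]
  }
  keep <- stats::complete.cases(A) & !is.na(y)
  if (scheme$mode == "replicate_holdout") {
    if (is.null(y2)) stop("replicate_holdout needs y2", call. = FALSE)
    keep <- keep & !is.na(y2)
  }
  A <- A[keep, , drop = FALSE]; y <- y[keep]
  n <- nrow(A); m <- ncol(A)
  if (scheme$mode == "in_sample") {
    fit <- fit_linear(A, y, transform_predictors)
    return(list(adj_r2 = fit$adj_r2, predictions = fit$fitted, fit = fit))
  }
  if (scheme$mode == "replicate_holdout") {
    y2 <- y2[keep]
    fit <- fit_linear(A, y, transform_predictors)
    pred <- predict(fit, A)
    return(list(adj_r2 = adjusted_r2(asinh(y2), pred, m),
                predictions = pred, fit = fit))
  }
  # kfold: pooled out-of-fold predictions scored once
  k <- scheme$k
  set.seed(scheme$seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  if (n - max(tabulate(fold, k)) <= m + 1) {
    stop("a training fold has n <= m + 1 genes; use a smaller k",
         call. = FALSE)
  }
  pred <- numeric(n)
  for (f in seq_len(k)) {
    test <- fold == f
    fit <- fit_linear(A[!test, , drop = FALSE], y[!test],
                      transform_predictors)
    pred[test] <- predict(fit, A[test, , drop = FALSE])
  }
  list(adj_r2 = adjusted_r2(asinh(y), pred, m), predictions = pred)
}
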