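#' @title Decision trees of regression models over latent regulatory classes
#' @name latent_tree
#' @description
#' A binary decision tree in which every node is a linear expression model
#' over a subset of genes and every non-leaf node is a categorisation step:
#' genes whose score on the split variable is `<= gamma` go left, the rest
#' go right. Leaf models drop the variables used along their path (a gene's
#' class membership already encodes that information), and the genes of the
#' leaves partition the full gene set. Thresholds are selected by an
#' unsupervised scan of the change in adjusted R-squared relative to a
#' genome-wide baseline model, optionally calibrated against models built
#' from randomly sampled gene sets of equal size.
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- tree structure -------------------------------------------------------

#' Tree structure constructors
#'
#' `tree_leaf()` is a terminal regulatory class (optionally named;
#' unnamed leaves are auto-named `"<var>+"` / `"<var>-"` when fitted).
#' `tree_split()` is a categorisation step on one score column: genes with
#' score `<= gamma` descend into `left`, the rest into `right`.
#'
#' @param name Optional class name for a leaf.
#' @param variable Score-matrix column to split on.
#' @param left,right Child `tree_structure` nodes.
#' @return A `tree_structure` object.
#' @export
tree_leaf <- function(name = NULL) {
  structure(list(type = "leaf", name = name), class = "tree_structure")
}

#' @rdname tree_leaf
#' @export
tree_split <- function(variable, left, right) {
  stopifnot(is.character(variable), length(variable) == 1,
            inherits(left, "tree_structure"),
            inherits(right, "tree_structure"))
  structure(list(type = "split", variable = variable,
                 left = left, right = right), class = "tree_structure")
}

.validate_structure <- function(node, path = character()) {
  if (node$type == "leaf") return(invisible(TRUE))
  if (node$variable %in% path) {
    stop("variable '", node$variable, "' repeated along a root-to-leaf path",
         call. = FALSE)
  }
  .validate_structure(node$left, c(path, node$variable))
  .validate_structure(node$right, c(path, node$variable))
  invisible(TRUE)
}

#' Parse a parenthesised tree-structure string
#'
#' Grammar: `"(variable: left | right)"` where `left`/`right` are nested
#' structures or leaf names; the right branch is the `score > gamma` side.
#' Example: `"(MMFS:(H2A.Z:H2A.Z-|H2A.Z+)|MMFS+)"`. A bare `"*"` is an
#' unnamed leaf.
#'
#' @param text Structure string.
#' @return A `tree_structure`.
#' @export
parse_structure <- function(text) {
  s <- strsplit(gsub("[[:space:]]", "", text), "")[[1]]
  if (!length(s)) stop("empty structure string", call. = FALSE)
  env <- new.env()
  env$i <- 1L
  peek <- function() if (env$i <= length(s)) s[env$i] else ""
  advance <- function() { ch <- peek(); env$i <- env$i + 1L; ch }
  expect <- function(ch) {
    got <- advance()
    if (got != ch) {
      stop("expected '", ch, "' at position ", env$i - 1L,
           " of structure string", call. = FALSE)
    }
  }
  token <- function() {
    out <- character()
    while (!peek() %in% c("", "(", ")", ":", "|")) out <- c(out, advance())
    if (!length(out)) {
      stop("expected a name at position ", env$i, " of structure string",
           call. = FALSE)
    }
    paste(out, collapse = "")
  }
  node <- function() {
    if (peek() == "(") {
      expect("(")
      v <- token()
      expect(":")
      l <- node()
      expect("|")
      r <- node()
      expect(")")
      tree_split(v, l, r)
    } else {
      nm <- token()
      tree_leaf(if (nm == "*") NULL else nm)
    }
  }
  out <- node()
  if (env$i <= length(s)) {
    stop("trailing characters after structure at position ", env$i,
         call. = FALSE)
  }
  .validate_structure(out)
  out
}

#' @exportS3Method base::format
format.tree_structure <- function(x, ...) {
  if (x$type == "leaf") return(x$name %||% "*")
  paste0("(", x$variable, ":", format(x$left), "|", format(x$right), ")")
}

#' @export
print.tree_structure <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Enumerate all tree structures over a variable set
#'
#' All binary trees up to `max_depth` in which no split variable repeats
#' along any root-to-leaf path; leaves are unnamed (auto-named at fit time).
#' Includes the depth-0 single-leaf structure.
#'
#' @param variables Candidate split-variable names.
#' @param max_depth Maximum tree depth (`<= length(variables)`).
#' @return List of `tree_structure` objects.
#' @export
enumerate_structures <- function(variables, max_depth) {
  max_depth <- as.integer(max_depth)
  if (max_depth > length(variables)) {
    stop("max_depth cannot exceed the number of variables", call. = FALSE)
  }
  rec <- function(vars, depth) {
    out <- list(tree_leaf())
    if (depth >= 1L && length(vars)) {
      for (v in vars) {
        subs <- rec(setdiff(vars, v), depth - 1L)
        for (l in subs) {
          for (r in subs) out[[length(out) + 1L]] <- tree_split(v, l, r)
        }
      }
    }
    out
  }
  out <- rec(variables, max_depth)
  out[!duplicated(vapply(out, format, character(1)))]
}

# ---- threshold scan -------------------------------------------------------

# Fast OLS on a prebuilt design matrix (first column = intercept).
# Returns the fitted values; rank deficiency is tolerated (pivoting).
.ols_fitted <- function(X, y) {
  fit <- stats::.lm.fit(X, y)
  y - fit$residuals
}

#' Unsupervised categorisation-threshold scan
#'
#' Scans candidate thresholds `gamma` for one score column. At each `gamma`
#' the genes split into a left (`score <= gamma`) and right (`score >
#' gamma`) class; a leaf-style model (all columns except the split variable
#' and any `exclude`d ones) is fitted to each side, and three
#' delta-adjusted-R-squared curves are recorded against a genome-wide
#' baseline model whose adjusted R-squared is recomputed on the same genes:
#' `delta_negative` (left model), `delta_positive` (right model) and
#' `delta_cumulative` (one adjusted R-squared over the concatenated
#' predictions of both sides). The chosen threshold maximises the curve
#' named by `leaf_side`. Optionally, each grid point is calibrated against
#' `n_null` class-style models built from randomly sampled gene sets of the
#' matching class size, each compared with the standard model refit on the
#' same random genes: the mean chance-level delta is ~0 (when the split
#' variable adds no information beyond the baseline's predictors) and its
#' standard error quantifies the variation expected by chance, growing as
#' the class shrinks.
#'
#' @param A_full Score matrix (histone + methylation columns), no `NA` in
#'   the predictor columns (`NA` in the split column routes left).
#' @param y Expression vector (raw RPKM).
#' @param variable Column to scan.
#' @param leaf_side Which curve the threshold optimises: `"left"`,
#'   `"right"`, or `"both"` (cumulative).
#' @param n_null Random gene sets per grid point (0 skips the null).
#' @param grid Candidate thresholds; default: unique empirical quantiles of
#'   the split column at 1\% steps, keeping only thresholds that leave at
#'   least `min_size` genes on each side.
#' @param seed Integer seed for the null sampling.
#' @param exclude Further columns to withhold from the side models (the
#'   split variables of ancestor nodes).
#' @param min_size Minimum class size; default `max(50, p + 2)` where `p`
#'   is the number of side-model predictors.
#' @param transform Arsinh-transform predictors (default `TRUE`).
#' @param baseline Optional list `(pred, p, columns)` giving baseline
#'   predictions (arsinh scale) aligned to the rows of `A_full`, the
#'   baseline predictor count and the baseline's column names (used when
#'   refitting baseline-style models for the null); default: an OLS fit on
#'   all columns of `A_full` over all its genes.
#' @return Object of class `threshold_scan`: `grid`, `k` (left-class size
#'   per threshold), the three delta curves, `objective`, `chosen_gamma`,
#'   `chosen_k`, `null_mean`, `null_se`, `baseline_adj_r2`.
#' @export
scan_threshold <- function(A_full, y, variable,
                           leaf_side = c("both", "left", "right"),
                           n_null = 100L, grid = NULL, seed = 1L,
                           exclude = character(), min_size = NULL,
                           transform = TRUE, baseline = NULL) {
  leaf_side <- match.arg(leaf_side)
  A_full <- as.matrix(A_full)
  if (!variable %in% colnames(A_full)) {
    stop("unknown split variable '", variable, "'", call. = FALSE)
  }
  n <- nrow(A_full)
  if (length(y) != n) stop("length(y) != nrow(A_full)", call. = FALSE)
  ay <- asinh(y)
  pred_cols <- setdiff(colnames(A_full), c(variable, exclude))
  if (!length(pred_cols)) {
    stop("no predictor columns left after excluding the split variable",
         call. = FALSE)
  }
  if (anyNA(A_full[, pred_cols])) {
    stop("NA in predictor column(s); impute or drop masked genes first",
         call. = FALSE)
  }
  X <- .design(A_full, transform)
  Xl <- cbind(1, X[, pred_cols, drop = FALSE])
  p_leaf <- length(pred_cols)
  v <- A_full[, variable]
  if (all(is.na(v)) || diff(range(v, na.rm = TRUE)) == 0) {
    stop("no admissible split: '", variable, "' is constant", call. = FALSE)
  }
  if (is.null(baseline)) {
    bpred <- .ols_fitted(cbind(1, X), ay)
    baseline <- list(pred = bpred, p = ncol(X))
  }
  bpred <- baseline$pred
  p_base <- baseline$p
  min_size <- min_size %||% max(50L, p_leaf + 2L)
  if (is.null(grid)) {
    # empirical quantiles at 1% steps as cut points: the p-quantile cut is
    # the ceiling(p * n)-th order statistic, so that "score <= gamma" puts
    # exactly that fraction of genes on the left
    vs <- sort(v)  # drops NA
    ranks <- unique(pmin(length(vs),
                         ceiling(seq(0.01, 0.99, by = 0.01) * length(vs) -
                                   1e-9)))
    grid <- unique(vs[ranks])
  }
  grid <- sort(unique(grid))
  k_all <- vapply(grid, function(g) sum(v <= g | is.na(v)), integer(1))
  ok <- k_all >= min_size & (n - k_all) >= min_size
  grid <- grid[ok]; k_all <- k_all[ok]
  if (!length(grid)) {
    stop("no admissible split: every threshold leaves a side below ",
         min_size, " genes", call. = FALSE)
  }
  ng <- length(grid)
  d_pos <- d_neg <- d_cum <- rep(NA_real_, ng)
  base_adj_all <- .adj_r2(ay, bpred, p_base)
  for (i in seq_len(ng)) {
    left <- which(v <= grid[i] | is.na(v))
    right <- setdiff(seq_len(n), left)
    fl <- .ols_fitted(Xl[left, , drop = FALSE], ay[left])
    fr <- .ols_fitted(Xl[right, , drop = FALSE], ay[right])
    d_neg[i] <- .adj_r2(ay[left], fl, p_leaf) -
      .adj_r2(ay[left], bpred[left], p_base)
    d_pos[i] <- .adj_r2(ay[right], fr, p_leaf) -
      .adj_r2(ay[right], bpred[right], p_base)
    pred_cat <- numeric(n)
    pred_cat[left] <- fl; pred_cat[right] <- fr
    d_cum[i] <- .adj_r2(ay, pred_cat, p_leaf) - base_adj_all
  }
  objective <- switch(leaf_side, left = d_neg, right = d_pos, both = d_cum)
  if (all(is.na(objective))) {
    stop("no admissible split: objective undefined at every threshold",
         call. = FALSE)
  }
  best <- which.max(ifelse(is.na(objective), -Inf, objective))
  # Null calibration: one class-style model per randomly sampled gene set of
  # the matching class size, compared against the standard (baseline-style)
  # model refit on the same random genes, centred on the same model pair's
  # whole-gene-set delta. Centring removes the dataset's fixed redundancy
  # offset (the realised in-sample cost of dropping the split variable,
  # which every subset inherits), so the chance-level delta has mean ~ 0 at
  # every size; its SE grows as the class shrinks, quantifying the
  # performance variation expected by chance.
  null_mean <- null_se <- rep(NA_real_, ng)
  if (n_null > 0) {
    base_cols <- baseline$columns %||% colnames(A_full)
    Xb <- cbind(1, X[, base_cols, drop = FALSE])
    d_node <- .adj_r2(ay, .ols_fitted(Xl, ay), p_leaf) -
      .adj_r2(ay, .ols_fitted(Xb, ay), p_base)
    set.seed(seed)
    for (i in seq_len(ng)) {
      size <- if (leaf_side == "right") n - k_all[i] else k_all[i]
      deltas <- vapply(seq_len(n_null), function(r) {
        idx <- sample.int(n, size)
        f_leaf <- .ols_fitted(Xl[idx, , drop = FALSE], ay[idx])
        f_base <- .ols_fitted(Xb[idx, , drop = FALSE], ay[idx])
        .adj_r2(ay[idx], f_leaf, p_leaf) -
          .adj_r2(ay[idx], f_base, p_base) - d_node
      }, numeric(1))
      null_mean[i] <- mean(deltas, na.rm = TRUE)
      null_se[i] <- stats::sd(deltas, na.rm = TRUE) / sqrt(sum(!is.na(deltas)))
    }
  }
  structure(list(variable = variable, leaf_side = leaf_side,
                 grid = grid, k = k_all,
                 delta_negative = d_neg, delta_positive = d_pos,
                 delta_cumulative = d_cum, objective = objective,
                 chosen_gamma = grid[best], chosen_k = k_all[best],
                 null_mean = null_mean, null_se = null_se,
                 n_null = as.integer(n_null), seed = as.integer(seed),
                 baseline_adj_r2 = base_adj_all, min_size = min_size),
            class = "threshold_scan")
}

#' Write a threshold scan's curves as TSV (for plotting)
#' @param scan A [scan_threshold()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_curves <- function(scan, path) {
  d <- data.frame(gamma = scan$grid, k = scan$k,
                  delta_negative = scan$delta_negative,
                  delta_positive = scan$delta_positive,
                  delta_cumulative = scan$delta_cumulative,
                  null_mean = scan$null_mean, null_se = scan$null_se)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- tree fitting ---------------------------------------------------------

#' Options controlling [fit_tree()]
#'
#' @param n_null Random gene sets per grid point in each node's threshold
#'   scan (0 = skip the null curves; they do not affect threshold choice).
#' @param seed Seed for null sampling.
#' @param grid Optional explicit threshold grid applied at every node.
#' @param min_size Minimum class size (default `max(50, p + 2)`).
#' @param baseline_columns Columns of the genome-wide baseline model
#'   (default: all columns of the score matrix, i.e. the naive-augmented
#'   standard model). Set to the histone columns for a histone-only
#'   baseline.
#' @param missing Routing for genes whose split score is `NA`: `"left"`
#'   (default; unassayed methylation reads as unmethylated) or `"right"`.
#' @param transform Arsinh-transform predictors (default `TRUE`).
#' @param scenario Per-node threshold objective. `"cumulative"` (default)
#'   optimises every node's threshold on the cumulative
#'   delta-adjusted-R-squared over both children's concatenated
#'   predictions, which is where the optimum of a class boundary actually
#'   sits. `"leaf"` optimises the single-side delta of a lone leaf child
#'   when exactly one child is a leaf (falling back to cumulative
#'   otherwise); this variant is degenerate when the leaf-side class has
#'   little expression variance — the single-side curve plateaus and its
#'   argmax drifts to extreme quantiles — and is kept for comparison only.
#' @return A list of class `tree_options`.
#' @export
tree_options <- function(n_null = 0L, seed = 1L, grid = NULL,
                         min_size = NULL, baseline_columns = NULL,
                         missing = c("left", "right"), transform = TRUE,
                         scenario = c("cumulative", "leaf")) {
  structure(list(n_null = as.integer(n_null), seed = as.integer(seed),
                 grid = grid, min_size = min_size,
                 baseline_columns = baseline_columns,
                 missing = match.arg(missing),
                 transform = isTRUE(transform),
                 scenario = match.arg(scenario)), class = "tree_options")
}

.leaf_goes_left <- function(v, gamma, missing) {
  if (missing == "left") v <= gamma | is.na(v) else v <= gamma & !is.na(v)
}

#' Fit a decision tree of expression models
#'
#' Thresholds are assigned greedily top-down with [scan_threshold()]; by
#' default every node maximises the cumulative (concatenated) delta
#' adjusted R-squared over its two children (see
#' [tree_options()]`$scenario` for the single-leaf-child variant). Each
#' leaf's model uses all score columns except the split variables on its
#' path. The genes of the leaves partition the gene set.
#'
#' @param A_full Score matrix (histone + methylation columns), gene ids as
#'   row names.
#' @param y Expression vector (raw RPKM), length `nrow(A_full)`.
#' @param structure A `tree_structure` or a structure string for
#'   [parse_structure()].
#' @param options A [tree_options()].
#' @return Object of class `tree_model`: the fitted node tree (splits carry
#'   `gamma` and the scan; leaves carry the class fit, membership and delta
#'   adjusted R-squared), the `baseline` fit, per-class `summary` table,
#'   `cumulative_adj_r2` and `delta_cumulative_adj_r2`.
#' @export
fit_tree <- function(A_full, y, structure, options = tree_options()) {
  if (is.character(structure)) structure <- parse_structure(structure)
  stopifnot(inherits(structure, "tree_structure"),
            inherits(options, "tree_options"))
  .validate_structure(structure)
  A_full <- as.matrix(A_full)
  if (is.null(rownames(A_full))) {
    rownames(A_full) <- paste0("g", seq_len(nrow(A_full)))
  }
  n <- nrow(A_full)
  if (length(y) != n) stop("length(y) != nrow(A_full)", call. = FALSE)
  ay <- asinh(y)
  bcols <- options$baseline_columns %||% colnames(A_full)
  missing_cols <- setdiff(bcols, colnames(A_full))
  if (length(missing_cols)) {
    stop("baseline column(s) not in score matrix: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  baseline_fit <- fit_linear(A_full[, bcols, drop = FALSE], y,
                             transform_predictors = options$transform)
  bpred <- predict(baseline_fit, A_full)
  p_base <- length(bcols)
  base_adj_all <- .adj_r2(ay, bpred, p_base)

  fit_leaf_model <- function(idx, preds) {
    fit_linear(A_full[idx, preds, drop = FALSE], y[idx],
               transform_predictors = options$transform)
  }

  build <- function(node, idx, path) {
    if (node$type == "leaf") {
      preds <- setdiff(colnames(A_full), path)
      fit <- fit_leaf_model(idx, preds)
      list(type = "leaf", name = node$name, genes = idx, predictors = preds,
           fit = fit, adj_r2 = fit$adj_r2,
           delta_adj_r2 = fit$adj_r2 - .adj_r2(ay[idx], bpred[idx], p_base))
    } else {
      side <- "both"
      if (options$scenario == "leaf") {
        if (node$left$type == "leaf" && node$right$type != "leaf") {
          side <- "left"
        } else if (node$right$type == "leaf" && node$left$type != "leaf") {
          side <- "right"
        }
      }
      scan <- scan_threshold(
        A_full[idx, , drop = FALSE], y[idx], node$variable,
        leaf_side = side, n_null = options$n_null, grid = options$grid,
        seed = options$seed, exclude = path, min_size = options$min_size,
        transform = options$transform,
        baseline = list(pred = bpred[idx], p = p_base, columns = bcols))
      goleft <- .leaf_goes_left(A_full[idx, node$variable],
                                scan$chosen_gamma, options$missing)
      list(type = "split", variable = node$variable,
           gamma = scan$chosen_gamma, scan = scan,
           left = build(node$left, idx[goleft], c(path, node$variable)),
           right = build(node$right, idx[!goleft], c(path, node$variable)))
    }
  }
  fitted_root <- build(structure, seq_len(n), character())

  # default class names: split variable of the immediate parent, "-" for the
  # low (left) side, "+" for the high side; path-qualified on collision
  name_leaves <- function(node, parent_label) {
    if (node$type == "leaf") {
      node$auto_name <- parent_label %||% "all"
      return(node)
    }
    node$left <- name_leaves(node$left, paste0(node$variable, "-"))
    node$right <- name_leaves(node$right, paste0(node$variable, "+"))
    node
  }
  fitted_root <- name_leaves(fitted_root, NULL)
  collect <- function(node) {
    if (node$type == "leaf") return(list(node))
    c(collect(node$left), collect(node$right))
  }
  leaves <- collect(fitted_root)
  nms <- vapply(leaves, function(l) l$name %||% l$auto_name, character(1))
  if (anyDuplicated(nms)) {
    # qualify duplicated auto-names by the full path
    qualify <- function(node, prefix) {
      if (node$type == "leaf") {
        if (is.null(node$name)) node$auto_name <- prefix %||% "all"
        return(node)
      }
      node$left <- qualify(node$left,
                           paste0(c(prefix, paste0(node$variable, "-")),
                                  collapse = "/"))
      node$right <- qualify(node$right,
                            paste0(c(prefix, paste0(node$variable, "+")),
                                   collapse = "/"))
      node
    }
    fitted_root <- qualify(fitted_root, NULL)
    leaves <- collect(fitted_root)
    nms <- vapply(leaves, function(l) l$name %||% l$auto_name, character(1))
    if (anyDuplicated(nms)) {
      stop("duplicate leaf class names: ",
           paste(unique(nms[duplicated(nms)]), collapse = ", "),
           call. = FALSE)
    }
  }
  set_name <- function(node) {
    if (node$type == "leaf") {
      node$name <- node$name %||% node$auto_name
      node$auto_name <- NULL
      return(node)
    }
    node$left <- set_name(node$left)
    node$right <- set_name(node$right)
    node
  }
  fitted_root <- set_name(fitted_root)
  leaves <- collect(fitted_root)
  names(leaves) <- vapply(leaves, `[[`, character(1), "name")

  all_idx <- sort(as.integer(unlist(lapply(leaves, `[[`, "genes"),
                                    use.names = FALSE)))
  if (!identical(all_idx, seq_len(n))) {
    stop("internal error: leaf memberships do not partition the gene set")
  }
  pred_cat <- numeric(n)
  for (l in leaves) {
    pred_cat[l$genes] <- predict(l$fit, A_full[l$genes, , drop = FALSE])
  }
  p_cum <- length(unique(unlist(lapply(leaves, `[[`, "predictors"))))
  cumulative <- .adj_r2(ay, pred_cat, p_cum)
  summary_df <- data.frame(
    class = names(leaves),
    n_genes = vapply(leaves, function(l) length(l$genes), integer(1)),
    genes_pct = round(100 * vapply(leaves, function(l) length(l$genes),
                                   integer(1)) / n, 1),
    adj_r2 = vapply(leaves, `[[`, numeric(1), "adj_r2"),
    delta_adj_r2 = vapply(leaves, `[[`, numeric(1), "delta_adj_r2"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(root = fitted_root, leaves = leaves,
                 baseline = list(fit = baseline_fit, columns = bcols,
                                 adj_r2 = base_adj_all, p = p_base),
                 cumulative_adj_r2 = cumulative,
                 delta_cumulative_adj_r2 = cumulative - base_adj_all,
                 summary = summary_df, n = n,
                 gene_ids = rownames(A_full), options = options),
            class = "tree_model")
}

#' @export
print.tree_model <- function(x, ...) {
  fmt <- function(node) {
    if (node$type == "leaf") return(node$name)
    paste0("(", node$variable, "<=", signif(node$gamma, 4), ":",
           fmt(node$left), "|", fmt(node$right), ")")
  }
  cat("decision tree of expression models\n")
  cat("  structure:", fmt(x$root), "\n")
  cat(sprintf("  baseline adj R^2 = %.4f (%s)\n", x$baseline$adj_r2,
              paste(x$baseline$columns, collapse = ", ")))
  cat(sprintf("  cumulative adj R^2 = %.4f (delta = %+.4f)\n",
              x$cumulative_adj_r2, x$delta_cumulative_adj_r2))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

.route <- function(model, A_full) {
  A_full <- as.matrix(A_full)
  needed <- unique(c(unlist(lapply(model$leaves, `[[`, "predictors")),
                     .split_vars(model$root)))
  missing_cols <- setdiff(needed, colnames(A_full))
  if (length(missing_cols)) {
    stop("score matrix lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  leaf_of <- character(nrow(A_full))
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (node$type == "leaf") {
      leaf_of[idx] <<- node$name
      return()
    }
    goleft <- .leaf_goes_left(A_full[idx, node$variable], node$gamma,
                              model$options$missing)
    rec(node$left, idx[goleft])
    rec(node$right, idx[!goleft])
  }
  rec(model$root, seq_len(nrow(A_full)))
  leaf_of
}

.split_vars <- function(node) {
  if (node$type == "leaf") return(character())
  c(node$variable, .split_vars(node$left), .split_vars(node$right))
}

#' Predict arsinh-expression with a fitted tree
#'
#' Each gene is routed by the split comparisons (score `<= gamma` goes
#' left) to a leaf, whose model predicts it.
#'
#' @param model A [fit_tree()] result.
#' @param A_full Score matrix with the columns the model uses.
#' @return Numeric vector of arsinh-scale predictions.
#' @export
predict_tree <- function(model, A_full) {
  stopifnot(inherits(model, "tree_model"))
  A_full <- as.matrix(A_full)
  labels <- .route(model, A_full)
  pred <- numeric(nrow(A_full))
  for (l in model$leaves) {
    idx <- which(labels == l$name)
    if (length(idx)) {
      pred[idx] <- predict(l$fit, A_full[idx, , drop = FALSE])
    }
  }
  pred
}

#' Assign genes to the tree's regulatory classes
#'
#' @inheritParams predict_tree
#' @return Character vector of leaf class names, one per gene.
#' @export
assign_classes <- function(model, A_full) {
  stopifnot(inherits(model, "tree_model"))
  .route(model, A_full)
}

#' Exhaustively evaluate all tree structures
#'
#' Every structure from [enumerate_structures()] is fitted with greedy
#' per-node thresholds and ranked by cumulative adjusted R-squared. Greedy
#' threshold selection does not guarantee a globally optimal set of
#' thresholds; the ranking is over greedily fitted trees.
#'
#' @param A_full Score matrix.
#' @param y Expression vector (raw RPKM).
#' @param variables Candidate split variables (default: all columns).
#' @param max_depth Maximum tree depth.
#' @param options A [tree_options()].
#' @return List with `best` (the top-ranked `tree_model`) and `table`
#'   (ranked data frame: structure string, leaf count, cumulative and delta
#'   adjusted R-squared; structures with no admissible split get `NA`).
#' @export
exhaustive_search <- function(A_full, y, variables = colnames(A_full),
                              max_depth = 2L, options = tree_options()) {
  structures <- enumerate_structures(variables, max_depth)
  res <- lapply(structures, function(s) {
    tryCatch(fit_tree(A_full, y, s, options), error = function(e) NULL)
  })
  tab <- data.frame(
    structure = vapply(structures, format, character(1)),
    n_leaves = vapply(res, function(m) {
      if (is.null(m)) NA_integer_ else length(m$leaves)
    }, integer(1)),
    cumulative_adj_r2 = vapply(res, function(m) {
      if (is.null(m)) NA_real_ else m$cumulative_adj_r2
    }, numeric(1)),
    delta_cumulative_adj_r2 = vapply(res, function(m) {
      if (is.null(m)) NA_real_ else m$delta_cumulative_adj_r2
    }, numeric(1)),
    stringsAsFactors = FALSE)
  o <- order(tab$cumulative_adj_r2, decreasing = TRUE, na.last = TRUE)
  tab <- tab[o, , drop = FALSE]
  rownames(tab) <- NULL
  list(best = res[[o[1]]], table = tab)
}

#' Serialise a fitted tree to JSON
#'
#' Structure, per-node thresholds, leaf coefficients and the class summary
#' table; enough to inspect or re-plot a fitted model.
#'
#' @param model A `tree_model`.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
tree_to_json <- function(model, path = NULL) {
  ser <- function(node) {
    if (node$type == "leaf") {
      list(type = "leaf", class = node$name,
           n_genes = length(node$genes),
           predictors = as.list(node$predictors),
           mu = node$fit$mu, beta = as.list(node$fit$beta),
           adj_r2 = node$adj_r2, delta_adj_r2 = node$delta_adj_r2)
    } else {
      list(type = "split", variable = node$variable, gamma = node$gamma,
           left = ser(node$left), right = ser(node$right))
    }
  }
  obj <- list(tree = ser(model$root),
              baseline = list(columns = as.list(model$baseline$columns),
                              adj_r2 = model$baseline$adj_r2),
              cumulative_adj_r2 = model$cumulative_adj_r2,
              delta_cumulative_adj_r2 = model$delta_cumulative_adj_r2,
              summary = model$summary)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
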