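test_that("structure strings parse, validate and round-trip", {
  s <- parse_structure("(MMFS:(H2A.Z:H2A.Z-|H2A.Z+)|MMFS+)")
  expect_equal(s$variable, "MMFS")
  expect_equal(s$right$name, "MMFS+")
  expect_equal(s$left$left$name, "H2A.Z-")
  expect_equal(format(s), "(MMFS:(H2A.Z:H2A.Z-|H2A.Z+)|MMFS+)")
  expect_equal(format(parse_structure(" ( a : x | y ) ")), "(a:x|y)")
  expect_error(parse_structure("(a:(a:x|y)|z)"), "repeated")
  expect_error(parse_structure("(a:x|y"), "expected")
  expect_error(parse_structure("(a:x|y)z"), "trailing")
})

test_that("structure enumeration matches an independent recursive count", {
  # independent oracle: count(d, v) = 1 + v * count(d-1, v-1)^2, count(0,.) = 1
  count_oracle <- function(depth, v) {
    if (depth == 0 || v == 0) return(1)
    1 + v * count_oracle(depth - 1, v - 1)^2
  }
  for (v in 1:3) {
    for (d in 0:v) {
      vars <- paste0("V", seq_len(v))
      expect_length(enumerate_structures(vars, d), count_oracle(d, v))
    }
  }
  expect_length(enumerate_structures("x", 1), 2)
  one <- enumerate_structures(c("x", "y"), 0)
  expect_length(one, 1)
  expect_equal(one[[1]]$type, "leaf")
  expect_error(enumerate_structures("x", 2), "max_depth")
})

test_that("threshold scan recovers a planted boundary and honours tie rules", {
  set.seed(50)
  n <- 1000
  k4 <- rpois(n, 60)
  high <- seq_len(n) <= 300
  meth <- ifelse(high, runif(n, 0.7, 1), runif(n, 0, 0.3))
  y <- ifelse(high, sinh(pmax(0, rnorm(n, 0, 0.2))),
              sinh(2 * asinh(k4) + rnorm(n, 0, 0.2)))
  A <- cbind(H3K4me3 = k4, MMFS = meth)
  sc <- scan_threshold(A, y, "MMFS", leaf_side = "both", n_null = 0,
                       min_size = 50)
  expect_gte(sc$chosen_gamma, max(meth[!high]))
  expect_lt(sc$chosen_gamma, min(meth[high]))
  # objective at the chosen gamma dominates the whole grid
  expect_true(all(sc$objective <= max(sc$objective, na.rm = TRUE)))
  expect_equal(sc$chosen_gamma, sc$grid[which.max(sc$objective)])
  expect_equal(sc$chosen_k, sum(meth <= sc$chosen_gamma))
  expect_error(scan_threshold(cbind(A[, 1, drop = FALSE],
                                    const = rep(1, n)), y, "const"),
               "no admissible split")
})

test_that("null calibration: structureless data yields flat delta curves", {
  # a single global linear model with no conditional structure and no
  # information in the split variable beyond the baseline's predictors
  deltas <- vapply(1:8, function(s) {
    set.seed(700 + s)
    n <- 2000
    A <- cbind(H3K4me3 = rpois(n, 50), H3K27me3 = rpois(n, 30),
               MMFS = runif(n))
    y <- sinh(pmax(0, 2 + 0.5 * asinh(A[, 1]) - 0.3 * asinh(A[, 2]) +
                     rnorm(n, 0, 0.5)))
    sc <- scan_threshold(A, y, "MMFS", leaf_side = "both", n_null = 0,
                         seed = s)
    max(sc$delta_cumulative, na.rm = TRUE)
  }, numeric(1))
  expect_lt(max(deltas), 0.01)
})

test_that("random-gene-set null is centred on zero", {
  set.seed(60)
  n <- 600
  A <- cbind(m1 = rpois(n, 40), m2 = rpois(n, 40), MMFS = runif(n))
  y <- sinh(pmax(0, 1.5 + 0.4 * asinh(A[, 1]) + rnorm(n, 0, 0.5)))
  sc <- scan_threshold(A, y, "MMFS", leaf_side = "both", n_null = 40,
                       seed = 3)
  ok <- abs(sc$null_mean) <= 3 * sc$null_se
  expect_gte(mean(ok), 0.95)
})

test_that("single-leaf tree equals the baseline model", {
  ds <- small_dataset(seed = 71, n = 800)
  A <- naive_augment(ds$truth$scores[, 1:4], ds$truth$scores[, "MMFS"],
                     "MMFS")
  y <- ds$expression$rpkm_1
  tm <- fit_tree(A, y, tree_leaf("all"))
  expect_equal(length(tm$leaves), 1)
  expect_equal(tm$cumulative_adj_r2, tm$baseline$adj_r2, tolerance = 1e-10)
  expect_equal(tm$delta_cumulative_adj_r2, 0, tolerance = 1e-10)
  expect_equal(unname(tm$leaves[[1]]$delta_adj_r2), 0, tolerance = 1e-10)
  expect_equal(predict_tree(tm, A), unname(predict(tm$baseline$fit, A)),
               tolerance = 1e-10)
})

test_that("fitted tree partitions genes and prunes path predictors", {
  ds <- small_dataset(seed = 72, n = 1500)
  A <- naive_augment(ds$truth$scores[, 1:4], ds$truth$scores[, "MMFS"],
                     "MMFS")
  y <- ds$expression$rpkm_1
  tm <- fit_tree(A, y, paper_topology, tree_options(min_size = 30))
  sizes <- vapply(tm$leaves, function(l) length(l$genes), integer(1))
  expect_equal(sum(sizes), nrow(A))
  expect_equal(sort(names(tm$leaves)), sort(c("MMFS+", "H2A.Z+", "H2A.Z-")))
  # path rule: MMFS+ keeps H2A.Z; the H2A.Z leaves lose both split variables
  expect_true("H2A.Z" %in% tm$leaves[["MMFS+"]]$predictors)
  expect_false("MMFS" %in% tm$leaves[["MMFS+"]]$predictors)
  expect_equal(sort(tm$leaves[["H2A.Z+"]]$predictors),
               sort(setdiff(colnames(A), c("MMFS", "H2A.Z"))))
  expect_equal(sum(tm$summary$genes_pct), 100, tolerance = 0.2)
  # class labels match the leaves and routing is reproducible
  labs <- assign_classes(tm, A)
  expect_setequal(unique(labs), names(tm$leaves))
  for (l in tm$leaves) expect_equal(sum(labs == l$name), length(l$genes))
})

test_that("ties at gamma route left and the missing policy is honoured", {
  set.seed(73)
  n <- 400
  A <- cbind(mark = rpois(n, 30), MMFS = round(runif(n), 2))
  y <- sinh(pmax(0, 1 + 0.5 * asinh(A[, 1]) - 2 * A[, 2] + rnorm(n, 0, 0.3)))
  tm <- fit_tree(A, y, "(MMFS:low|high)", tree_options(min_size = 20))
  g <- tm$root$gamma
  labs <- assign_classes(tm, A)
  expect_true(all(labs[A[, "MMFS"] == g] == "low"))
  # genes with NA split score follow the missing policy
  A_na <- A; A_na[1:5, "MMFS"] <- NA
  expect_true(all(assign_classes(tm, A_na)[1:5] == "low"))
  tm_r <- tm; tm_r$options$missing <- "right"
  expect_true(all(assign_classes(tm_r, A_na)[1:5] == "high"))
})

test_that("trees beat the standard model only when structure is planted", {
  ds <- small_dataset(seed = 74, n = 2000)
  A <- naive_augment(ds$truth$scores[, 1:4], ds$truth$scores[, "MMFS"],
                     "MMFS")
  y <- ds$expression$rpkm_1
  tm <- fit_tree(A, y, paper_topology)
  expect_gt(tm$delta_cumulative_adj_r2, 0.05)
  pred <- predict_tree(tm, A)
  expect_gt(adjusted_r2(asinh(y), pred, 5),
            tm$baseline$adj_r2 + 0.05)
  ba <- balanced_accuracy(ds$truth$class == "silenced",
                          assign_classes(tm, A) == "MMFS+")
  expect_gt(ba, 0.9)
})

test_that("exhaustive search recovers the planted conditional variables", {
  ds <- small_dataset(seed = 75, n = 1500)
  A <- naive_augment(ds$truth$scores[, 1:4], ds$truth$scores[, "MMFS"],
                     "MMFS")
  y <- ds$expression$rpkm_1
  res <- exhaustive_search(A, y, variables = c("MMFS", "H2A.Z"),
                           max_depth = 2, options = tree_options())
  expect_equal(nrow(res$table), length(enumerate_structures(
    c("MMFS", "H2A.Z"), 2)))
  # the winner uses both planted conditioning variables; split order is not
  # identifiable when either order realises the same partition
  expect_match(res$table$structure[1], "MMFS")
  expect_match(res$table$structure[1], "H2A\\.Z")
  # the methylation split is the dominant single categorisation
  d1 <- res$table[res$table$structure %in% c("(MMFS:*|*)", "(H2A.Z:*|*)"), ]
  expect_gt(d1$cumulative_adj_r2[d1$structure == "(MMFS:*|*)"],
            d1$cumulative_adj_r2[d1$structure == "(H2A.Z:*|*)"])
  # a single leaf never outranks the planted structure
  single <- res$table[res$table$structure == "*", ]
  expect_lt(single$cumulative_adj_r2, res$table$cumulative_adj_r2[1])
  expect_equal(res$best$cumulative_adj_r2, res$table$cumulative_adj_r2[1])
})

test_that("identical seeds reproduce thresholds, fits and labels exactly", {
  ds1 <- small_dataset(seed = 76, n = 1000)
  ds2 <- small_dataset(seed = 76, n = 1000)
  expect_identical(ds1$truth$scores, ds2$truth$scores)
  A <- naive_augment(ds1$truth$scores[, 1:4], ds1$truth$scores[, "MMFS"],
                     "MMFS")
  y <- ds1$expression$rpkm_1
  t1 <- fit_tree(A, y, paper_topology, tree_options(n_null = 10, seed = 9))
  t2 <- fit_tree(A, y, paper_topology, tree_options(n_null = 10, seed = 9))
  expect_identical(t1$root$gamma, t2$root$gamma)
  expect_identical(t1$summary, t2$summary)
  expect_identical(assign_classes(t1, A), assign_classes(t2, A))
  expect_identical(t1$root$scan$null_mean, t2$root$scan$null_mean)
})

test_that("tree serialises to JSON with thresholds and class table", {
  ds <- small_dataset(seed = 77, n = 800)
  A <- naive_augment(ds$truth$scores[, 1:4], ds$truth$scores[, "MMFS"],
                     "MMFS")
  tm <- fit_tree(A, ds$expression$rpkm_1, paper_topology,
                 tree_options(min_size = 30))
  f <- tempfile(fileext = ".json")
  tree_to_json(tm, f)
  parsed <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_equal(parsed$tree$variable, "MMFS")
  expect_equal(parsed$tree$gamma, tm$root$gamma)
  expect_length(parsed$summary, 3)
})
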