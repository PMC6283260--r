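test_that("two planted blocks are recovered exactly and the objective ascends", {
  pb <- planted_two_blocks(n = 2000, flip = 0.05, seed = 42)
  fit <- fit_corex(pb$x, n_factors = 2, seed = 1, restarts = 3)
  # assignment partitions the variables exactly into the two blocks
  expect_length(unique(fit$assignment[1:5]), 1)
  expect_length(unique(fit$assignment[6:10]), 1)
  expect_false(fit$assignment[1] == fit$assignment[6])
  expect_equal(mclust::adjustedRandIndex(fit$assignment, pb$truth), 1)
  # per-block explained TC close to the exact plug-in TC of one block
  tc_block <- total_correlation(pb$x[, 1:5])
  expect_true(all(abs(sort(fit$explained_tc) - tc_block) < 0.15))
  expect_true(all(diff(fit$tc_history) >= -1e-9))
  expect_true(fit$converged)
})

test_that("a duplicated column's factor explains its exact total correlation", {
  x <- rep(c(0, 1), 1000)
  y4 <- cbind(x, x, x, x)
  colnames(y4) <- paste0("d", 1:4)
  fit <- fit_corex(y4, n_factors = 1, cardinality = 2, seed = 2, restarts = 2)
  expect_equal(fit$explained_tc, total_correlation(y4), tolerance = 0.05)
})

test_that("independent variables leave nothing to explain", {
  set.seed(7)
  Z <- matrix(rbinom(2000 * 10, 1, 0.5), 2000, 10)
  colnames(Z) <- paste0("z", 1:10)
  fit <- suppressWarnings(fit_corex(Z, n_factors = 3, seed = 3, restarts = 3))
  expect_lt(sum(fit$explained_tc), 0.05)
  expect_true(all(fit$explained_tc >= 0))
})

test_that("affinities are a convex competition and labels are valid states", {
  pb <- planted_two_blocks(n = 600, seed = 9)
  fit <- fit_corex(pb$x, n_factors = 2, seed = 4, restarts = 2)
  expect_true(all(fit$alpha >= 0 & fit$alpha <= 1))
  expect_equal(unname(rowSums(fit$alpha)), rep(1, 10), tolerance = 1e-9)
  expect_true(all(fit$labels %in% 0:1))
  expect_identical(dim(fit$labels), c(600L, 2L))
})

test_that("maximum-likelihood labels break ties toward the lowest state", {
  layer <- toy_layer(0.9)
  x <- matrix(c(0L, 1L), ncol = 1, dimnames = list(c("s1", "s2"), "a"))
  lab <- factor_labels(layer, x, panel = "plasma")
  expect_identical(unname(ft_data(lab)[, 1]), c(0, 1))  # posterior 0.9/0.1
  tie <- toy_layer(0.5)                                  # posterior exactly 0.5/0.5
  lab_tie <- factor_labels(tie, x, panel = "plasma")
  expect_identical(unname(ft_data(lab_tie)[, 1]), c(0, 0))
  expect_identical(unname(ft_classes(lab)), "corex_plasma")
})

test_that("labelling new data requires the training width", {
  pb <- planted_two_blocks(n = 300, seed = 5)
  fit <- fit_corex(pb$x, n_factors = 2, seed = 1, restarts = 2)
  expect_error(factor_labels(fit, pb$x[, 1:4]), "trained on")
  lab <- factor_labels(fit, pb$x[1:10, ], panel = "brain")
  expect_identical(ncol(ft_data(lab)), 2L)
  expect_true(all(startsWith(colnames(ft_data(lab)), "corexB_")))
})

test_that("a serialized layer labels new data identically after reload", {
  pb <- planted_two_blocks(n = 800, seed = 6)
  fit <- fit_corex(pb$x, n_factors = 2, seed = 1, restarts = 2)
  path <- withr::local_tempfile(fileext = ".json")
  corex_to_json(fit, path)
  fit2 <- corex_from_json(path)
  expect_identical(ft_data(factor_labels(fit, pb$x[1:100, ])),
                   ft_data(factor_labels(fit2, pb$x[1:100, ])))
  expect_equal(fit2$explained_tc, fit$explained_tc, tolerance = 1e-12)
  expect_equal(unname(fit2$alpha), unname(fit$alpha), tolerance = 1e-12)
})

test_that("fit_corex validates its arguments", {
  pb <- planted_two_blocks(n = 100, seed = 1)
  expect_error(fit_corex(pb$x, n_factors = 0), "n_factors")
  expect_error(fit_corex(pb$x, n_factors = 2, cardinality = 1), "cardinality")
  expect_error(fit_corex(pb$x - 1, n_factors = 2), "0-based")
})

test_that("fits are bit-reproducible given the seed", {
  pb <- planted_two_blocks(n = 400, seed = 8)
  f1 <- fit_corex(pb$x, n_factors = 2, seed = 11, restarts = 2)
  f2 <- fit_corex(pb$x, n_factors = 2, seed = 11, restarts = 2)
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$tc_history, f2$tc_history)
})

test_that("empirical MI matrix agrees with the pairwise plug-in estimator", {
  set.seed(13)
  x <- matrix(sample(0:2, 200 * 3, replace = TRUE), 200, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  lab <- matrix(sample(0:1, 200 * 2, replace = TRUE), 200, 2,
                dimnames = list(NULL, c("f1", "f2")))
  lab[, 1] <- (x[, 1] > 0) * 1L   # dependence for one pair
  mi <- corexad:::empirical_mi_matrix(x, lab)
  for (i in 1:3) for (j in 1:2) {
    expect_equal(mi[i, j], mutual_information(x[, i], lab[, j]),
                 tolerance = 1e-12)
  }
})

test_that("hierarchies stack layers and recover a planted 2+2 grouping", {
  set.seed(3)
  n <- 1500
  top <- matrix(rnorm(n * 2), n, 2)
  zb <- sapply(1:4, function(b) 0.85 * top[, ceiling(b / 2)] +
                 sqrt(1 - 0.85^2) * rnorm(n))
  X <- do.call(cbind, lapply(1:4, function(b) {
    sapply(1:5, function(i) 0.9 * zb[, b] + sqrt(1 - 0.81) * rnorm(n))
  }))
  colnames(X) <- paste0("v", 1:20)
  h <- suppressWarnings(fit_hierarchy(X, layer_sizes = c(4, 2), seed = 3,
                                      restarts = 5))
  l1 <- h$layers[[1]]; l2 <- h$layers[[2]]
  blk <- rep(1:4, each = 5)
  # layer 1: each block maps to one factor, all four factors distinct
  per_block <- vapply(split(l1$assignment, blk), function(v) v[1], numeric(1))
  expect_true(all(vapply(split(l1$assignment, blk),
                         function(v) length(unique(v)) == 1, logical(1))))
  expect_length(unique(per_block), 4)
  # layer 2: sibling blocks share a parent, the two groups differ
  parents <- l2$assignment[per_block]
  expect_identical(parents[[1]], parents[[2]])
  expect_identical(parents[[3]], parents[[4]])
  expect_false(parents[[1]] == parents[[3]])
  # edge invariants: MI >= 0 and bounded by the child/parent entropies
  expect_true(all(h$edges$mi >= 0))
  labels2 <- l2$labels
  h_parent <- apply(labels2, 2, function(col) plugin_entropy(table(col)))
  e2 <- h$edges[h$edges$layer == 2, ]
  pidx <- as.integer(sub("L2_F", "", e2$parent)) + 1L
  expect_true(all(e2$mi <= h_parent[pidx] + 1e-9))
})

test_that("layer sizes must strictly decrease", {
  pb <- planted_two_blocks(n = 100, seed = 2)
  expect_error(fit_hierarchy(pb$x, layer_sizes = c(4, 4)), "strictly decreasing")
  expect_error(fit_hierarchy(pb$x, layer_sizes = c(2, 3)), "strictly decreasing")
})
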