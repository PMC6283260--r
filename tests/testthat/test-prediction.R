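test_that("stratified splits preserve class proportions within one subject", {
  y <- rep(c(0, 1), c(40, 60))
  sp <- stratified_split(y, 0.7, seed = 2)
  expect_length(sp$train, 70)
  expect_identical(as.vector(table(y[sp$train])), c(28L, 42L))
  expect_identical(sort(c(sp$train, sp$test)), seq_along(y))
  # 10 subjects 5/5: train must be 7 under the within-one rule
  y2 <- rep(c(0, 1), each = 5)
  sp2 <- stratified_split(y2, 0.7, seed = 3)
  expect_length(sp2$train, 7)
  expect_true(all(table(y2[sp2$train]) %in% 3:4))
  # determinism and the small-class error
  expect_identical(stratified_split(y, 0.7, seed = 9),
                   stratified_split(y, 0.7, seed = 9))
  expect_error(stratified_split(c(0, 1, 1, 1), 0.7), "at least 2")
})

test_that("class weights are inverse-frequency with mean one", {
  y <- rep(c(0, 1), c(30, 10))
  w <- class_weights(y)
  expect_equal(mean(w), 1)
  expect_equal(w[y == 1][1] / w[y == 0][1], 3)
})

tiny_grid <- data.frame(nrounds = 50, max_depth = 2, eta = 0.1,
                        min_child_weight = 10)

test_that("boosting separates a separable toy problem", {
  set.seed(10)
  X <- rbind(matrix(rnorm(100 * 2, -2), 100, 2), matrix(rnorm(100 * 2, 2), 100, 2))
  colnames(X) <- c("a", "b")
  y <- rep(c(0L, 1L), each = 100)
  m <- fit_gbm(X, y, grid = tiny_grid, seed = 1, cv_repeats = 1, cv_folds = 3)
  ev <- evaluate(m, X, y)
  expect_equal(ev$auc, 1)
  expect_equal(ev$accuracy, 100)
})

test_that("duplicated feature columns leave the predictions unchanged", {
  set.seed(11)
  X <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.integer(X[, 1] + 0.5 * X[, 2] > 0)
  m1 <- fit_gbm(X, y, grid = tiny_grid, seed = 4, cv_repeats = 1, cv_folds = 3)
  Xd <- cbind(X, a2 = X[, 1])
  m2 <- fit_gbm(Xd, y, grid = tiny_grid, seed = 4, cv_repeats = 1, cv_folds = 3)
  expect_equal(predict(m1, X), predict(m2, Xd), tolerance = 1e-6)
})

test_that("grid search is deterministic and validates inputs", {
  set.seed(12)
  X <- matrix(rnorm(120 * 3), 120, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.integer(X[, 1] > 0)
  g2 <- rbind(tiny_grid, transform(tiny_grid, max_depth = 1))
  m1 <- fit_gbm(X, y, grid = g2, seed = 6, cv_repeats = 1, cv_folds = 3)
  m2 <- fit_gbm(X, y, grid = g2, seed = 6, cv_repeats = 1, cv_folds = 3)
  expect_identical(m1$best_params, m2$best_params)
  expect_identical(m1$cv_loss, m2$cv_loss)
  expect_error(fit_gbm(X, y, grid = tiny_grid[0, ]), "empty")
  expect_error(fit_gbm(X, y + 1, grid = tiny_grid), "binary")
})

test_that("evaluation metrics recompute exactly from confusion counts", {
  # fixture with known confusion at threshold 0.5: TP=9 FN=1 TN=8 FP=2
  probs <- c(rep(0.9, 9), 0.1, rep(0.2, 8), rep(0.8, 2))
  truth <- c(rep(1, 10), rep(0, 10))
  fake_model <- structure(list(p = probs), class = "fixed_probs")
  predict.fixed_probs <<- function(object, newdata, ...) object$p
  on.exit(rm(predict.fixed_probs, envir = .GlobalEnv), add = TRUE)
  ev <- evaluate(fake_model, matrix(0, 20, 1), truth)
  expect_identical(unname(ev$counts), c(9L, 1L, 8L, 2L))
  expect_equal(ev$sensitivity, 90)
  expect_equal(ev$specificity, 80)
  expect_equal(ev$accuracy, 85)
  # metrics reproduce from the stored per-subject predictions
  pr <- ev$predictions
  expect_equal(100 * mean(pr$label == pr$truth), ev$accuracy)
  expect_equal(100 * sum(pr$label == 1 & pr$truth == 1) / sum(pr$truth == 1),
               ev$sensitivity)
})

test_that("the trapezoidal AUC matches an independent implementation", {
  set.seed(13)
  prob <- runif(60)
  y <- as.integer(runif(60) < prob)
  if (length(unique(y)) == 1) y[1] <- 1 - y[1]
  ours <- corexad:::auc_trapezoid(prob, y)
  theirs <- as.numeric(suppressMessages(pROC::auc(y, prob)))
  expect_equal(ours, theirs, tolerance = 1e-12)
  expect_equal(corexad:::auc_trapezoid(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_true(is.na(corexad:::auc_trapezoid(prob, rep(1, 60))))
  perfect <- corexad:::auc_trapezoid(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(perfect, 1)
})

test_that("the McNemar comparison follows both branches", {
  # b=5, c=15: exact two-sided binomial, p = 2 * P(Bin(20, 1/2) <= 5)
  pa <- c(rep(1, 5), rep(0, 15), rep(1, 30))
  pb <- c(rep(0, 5), rep(1, 15), rep(1, 30))
  tr <- rep(1, 50)
  out <- mcnemar_compare(pa, pb, tr)
  expect_identical(c(out$b, out$c), c(5L, 15L))
  brute <- 2 * sum(choose(20, 0:5)) / 2^20
  expect_equal(out$p_value, brute, tolerance = 1e-12)
  expect_equal(out$p_value, 0.04138947, tolerance = 1e-6)
  expect_true(is.na(out$statistic))
  # b = c: symmetric, p = 1 in the exact branch
  out_eq <- mcnemar_compare(c(1, 0), c(0, 1), c(1, 1))
  expect_equal(out_eq$p_value, 1)
  # b=30, c=10: continuity-corrected chi-squared (|20|-1)^2/40
  pa2 <- c(rep(1, 30), rep(0, 10)); pb2 <- c(rep(0, 30), rep(1, 10))
  out2 <- mcnemar_compare(pa2, pb2, rep(1, 40))
  expect_equal(out2$statistic, 9.025)
  expect_equal(out2$p_value, pchisq(9.025, 1, lower.tail = FALSE))
  # cross-check the chi-squared branch against stats::mcnemar.test
  ref <- mcnemar.test(matrix(c(5, 30, 10, 5), 2, 2), correct = TRUE)
  expect_equal(out2$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(mcnemar_compare(c(1, 0), c(1, 0, 1), c(1, 0)), "lengths differ")
})

test_that("run_contrast averages splits and keeps selection leakage-free", {
  co <- generate_cohort(cohort_spec(
    n_subjects = 300, n_plasma_blocks = 3, block_sizes = rep(4L, 3),
    block_loading = 0.7, n_noise_analytes = 4, n_roi_pairs = 3,
    hallmark_effect = 0.8, seed = 31))
  g <- assign_groups(co$diagnoses)
  y <- contrast_outcome(g, 3)
  spl <- stratified_split(y, 0.7, seed = 7 + 31)   # split 1 inside run_contrast
  mk_canary <- function(values) {
    full <- setNames(rep(0, nrow(ft_data(co$features))), ft_subjects(co$features))
    full[names(y)] <- values
    feature_table(matrix(full, ncol = 1,
                         dimnames = list(names(full), "canary")),
                  c(canary = "plasma"))
  }
  set.seed(99)
  v <- rnorm(length(y))
  v[spl$test] <- y[spl$test] * 5   # equals the outcome on test rows only
  res <- suppressWarnings(run_contrast(
    co, 3, n_factors = 3, restarts = 2, k = 10,
    selection_cv = c(1, 3), gbm_cv = c(1, 3), grid = tiny_grid,
    n_splits = 1, seed = 7, extra_features = mk_canary(v)))
  # training-only selection treats the canary as exchangeable noise: it must
  # never outrank the genuinely informative features at the head of its class
  top_plasma <- function(r) {
    sel <- r$selected[[1]]
    sel[attr(sel, "classes")[sel] == "plasma"][1]
  }
  expect_false(top_plasma(res) == "canary")
  expect_true(all(c("plasma", "brain", "corex_plasma", "corex_brain",
                    "combined") %in% res$metrics$feature_set))
  expect_true(all(res$metrics$auc >= 0 & res$metrics$auc <= 1))
  # positive control: a canary leaking the outcome on training rows must
  # dominate its class outright
  res_leak <- suppressWarnings(run_contrast(
    co, 3, n_factors = 3, restarts = 2, k = 10,
    selection_cv = c(1, 3), gbm_cv = c(1, 3), grid = tiny_grid,
    n_splits = 1, seed = 7,
    extra_features = mk_canary(y * 5 + rnorm(length(y), 0, 0.1))))
  expect_identical(top_plasma(res_leak), "canary")
})

test_that("repeated run_contrast calls are bit-reproducible", {
  co <- generate_cohort(cohort_spec(
    n_subjects = 250, n_plasma_blocks = 2, block_sizes = c(4L, 4L),
    block_loading = 0.7, n_noise_analytes = 2, n_roi_pairs = 2,
    hallmark_effect = 0.6, seed = 32))
  args <- list(co, 3, n_factors = 2, restarts = 2, k = 4,
               selection_cv = c(1, 3), gbm_cv = c(1, 3), grid = tiny_grid,
               n_splits = 1, seed = 5,
               feature_sets = list(plasma = "plasma"))
  r1 <- suppressWarnings(do.call(run_contrast, args))
  r2 <- suppressWarnings(do.call(run_contrast, args))
  expect_identical(r1$metrics, r2$metrics)
})
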