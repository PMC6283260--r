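# Gradient-boosted classification of progression contrasts: stratified
# 70/30 splits, inverse-class-frequency weighting, grid-searched boosting
# hyperparameters under repeated k-fold CV on the training partition only,
# hold-out metrics, and McNemar comparison of paired classifiers.

#' Stratified train/test split
#'
#' Preserves per-class proportions to within one subject, using
#' largest-remainder apportionment of the total training size.
#'
#' @param y Binary outcome vector (0/1 or factor).
#' @param train_frac Training fraction (default 0.7).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(y, train_frac = 0.7, seed = 1L) {
  classes <- unique(y)
  counts <- table(factor(y, levels = classes))
  if (any(counts < 2)) stop("every class needs at least 2 members")
  set.seed(as.integer(seed))
  n <- length(y)
  target_total <- round(train_frac * n)
  base <- floor(train_frac * counts)
  rem <- train_frac * counts - base
  short <- target_total - sum(base)
  if (short > 0) {
    bump <- order(-rem)[seq_len(short)]
    base[bump] <- base[bump] + 1
  }
  train <- integer(0)
  for (i in seq_along(classes)) {
    idx <- which(y == classes[i])
    take <- max(1L, min(base[i], length(idx) - 1L))
    train <- c(train, sample(idx, take))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Inverse class-frequency weights normalized to mean 1
#' @param y Binary outcome vector.
#' @return Numeric weights, one per subject.
#' @export
class_weights <- function(y) {
  tab <- table(y)
  w <- 1 / as.numeric(tab[as.character(y)])
  w / mean(w)
}

default_gbm_grid <- function() {
  expand.grid(nrounds = c(100L, 300L, 500L), max_depth = 1:3,
              eta = c(0.1, 0.01), min_child_weight = 10)
}

weighted_logloss <- function(p, y, w) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / sum(w)
}

#' Grid-searched gradient boosting with class weighting
#'
#' Fits boosted trees over a hyperparameter grid, scoring each grid point by
#' weighted cross-validated log-loss under a repeated k-fold scheme on the
#' training data, then refits the best configuration on all of it. Folds in
#' which a class vanishes are re-drawn with a warning.
#'
#' @param X Training features (`feature_table` or matrix).
#' @param y Binary 0/1 outcome.
#' @param weights Per-subject weights; defaults to inverse class frequency
#'   normalized to mean 1.
#' @param grid Data.frame with columns `nrounds`, `max_depth`, `eta`,
#'   `min_child_weight` (default: 100/300/500 trees x depth 1-3 x
#'   learning rate 0.1/0.01, minimum leaf weight 10).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param cv_repeats,cv_folds Repeated CV scheme (defaults 10 x 10).
#' @return Object of class `gbm_model`: the fitted booster, chosen
#'   hyperparameters, the grid CV losses and feature names.
#' @export
fit_gbm <- function(X, y, weights = NULL, grid = default_gbm_grid(),
                    seed = 1L, cv_repeats = 10L, cv_folds = 10L) {
  if (inherits(X, "feature_table")) X <- ft_data(X)
  X <- as.matrix(X)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1")
  if (nrow(grid) == 0) stop("empty hyperparameter grid")
  if (is.null(weights)) weights <- class_weights(y)
  set.seed(as.integer(seed))
  losses <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    reps <- numeric(cv_repeats)
    for (r in seq_len(cv_repeats)) {
      for (attempt in 1:5) {
        folds <- make_folds(y, cv_folds, stratify = TRUE)
        ok <- all(vapply(folds, function(te) {
          length(unique(y[-te])) == 2
        }, logical(1)))
        if (ok) break
        warning("re-drawing folds: a fold lost a class")
      }
      fold_loss <- numeric(length(folds))
      for (f in seq_along(folds)) {
        te <- folds[[f]]
        fit <- xgb_fit(X[-te, , drop = FALSE], y[-te], "classification",
                       seed + r * 100 + f,
                       nrounds = grid$nrounds[g], max_depth = grid$max_depth[g],
                       eta = grid$eta[g],
                       min_child_weight = grid$min_child_weight[g],
                       weights = weights[-te])
        p <- predict(fit, X[te, , drop = FALSE])
        fold_loss[f] <- weighted_logloss(p, y[te], weights[te])
      }
      reps[r] <- mean(fold_loss)
    }
    losses[g] <- mean(reps)
  }
  best <- which.min(losses)
  final <- xgb_fit(X, y, "classification", seed,
                   nrounds = grid$nrounds[best], max_depth = grid$max_depth[best],
                   eta = grid$eta[best],
                   min_child_weight = grid$min_child_weight[best],
                   weights = weights)
  structure(list(booster = final,
                 best_params = grid[best, , drop = FALSE],
                 grid = grid, cv_loss = losses,
                 features = colnames(X), seed = as.integer(seed)),
            class = "gbm_model")
}

#' @export
predict.gbm_model <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_table")) newdata <- ft_data(newdata)
  newdata <- as.matrix(newdata)[, object$features, drop = FALSE]
  predict(object$booster, newdata)
}

# trapezoidal AUC via the rank (Mann-Whitney) identity, ties averaged
auc_trapezoid <- function(prob, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hold-out evaluation of a fitted classifier
#'
#' Computes trapezoidal AUC on the predicted probabilities and accuracy,
#' sensitivity and specificity (percent) at a fixed probability threshold,
#' treating the progressor/AD class (1) as positive. All metrics recompute
#' exactly from the stored per-subject predictions.
#'
#' @param model A `gbm_model` (or any object with a `predict` method
#'   returning probabilities).
#' @param X_test,y_test Held-out subjects.
#' @param threshold Probability threshold (default 0.5).
#' @return Object of class `prediction_result` with `auc` (fraction, `NA` if
#'   the test set has one class), `accuracy`/`sensitivity`/`specificity`
#'   (percent), confusion counts, and the per-subject predictions.
#' @export
evaluate <- function(model, X_test, y_test, threshold = 0.5) {
  prob <- predict(model, X_test)
  y_test <- as.integer(y_test)
  pred <- as.integer(prob > threshold)
  tp <- sum(pred == 1 & y_test == 1); fn <- sum(pred == 0 & y_test == 1)
  tn <- sum(pred == 0 & y_test == 0); fp <- sum(pred == 1 & y_test == 0)
  ids <- if (inherits(X_test, "feature_table")) ft_subjects(X_test) else rownames(as.matrix(X_test))
  structure(list(
    auc = auc_trapezoid(prob, y_test),
    accuracy = 100 * (tp + tn) / length(y_test),
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    counts = c(tp = tp, fn = fn, tn = tn, fp = fp),
    threshold = threshold,
    predictions = data.frame(subject = if (is.null(ids)) seq_along(prob) else ids,
                             prob = prob, label = pred, truth = y_test,
                             stringsAsFactors = FALSE)
  ), class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> AUC %.3f | ACC %.1f%% | SEN %.1f%% | SPEC %.1f%%\n",
              x$auc, x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' McNemar comparison of two paired classifiers
#'
#' Counts test subjects where exactly one model is correct: `b` (A right, B
#' wrong) and `c` (A wrong, B right). With `b + c >= 25` the
#' continuity-corrected chi-squared statistic `(|b-c|-1)^2/(b+c)` is referred
#' to a 1-df chi-squared distribution; otherwise the exact two-sided binomial
#' tail `2 P(Bin(b+c, 1/2) <= min(b,c))`, capped at 1, is used.
#'
#' @param pred_a,pred_b Predicted labels from the two models.
#' @param truth True labels (same test subjects, same order).
#' @return Named list: `b`, `c`, `statistic` (`NA` in the exact branch),
#'   `p_value`, `method`.
#' @export
mcnemar_compare <- function(pred_a, pred_b, truth) {
  if (length(pred_a) != length(truth) || length(pred_b) != length(truth)) {
    stop("prediction and truth lengths differ")
  }
  ca <- pred_a == truth
  cb <- pred_b == truth
  b <- sum(ca & !cb)
  cc <- sum(!ca & cb)
  if (b + cc >= 25) {
    stat <- (abs(b - cc) - 1)^2 / (b + cc)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chi-squared with continuity correction"
  } else {
    stat <- NA_real_
    p <- if (b + cc == 0) 1 else min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
    method <- "exact binomial"
  }
  list(b = b, c = cc, statistic = stat, p_value = p, method = method)
}

#' End-to-end contrast prediction over feature-set combinations
#'
#' Runs the full supervised arm for one diagnostic contrast: residualizes the
#' brain panel, learns plasma-side and brain-side latent factor layers,
#' then for each repeated stratified 70/30 split performs ensemble feature
#' selection on the training partition only (top `k` per class), fits the
#' class-weighted boosted classifier on the selected features and evaluates
#' on the hold-out. In `"paper-faithful"` mode the residualization,
#' discretization and factor layers are fit on the full cohort before
#' splitting; `"split-safe"` refits all of them on each training partition
#' and applies them frozen to the test partition.
#'
#' @param cohort A `synthetic_cohort` (or list with `features`, `diagnoses`).
#' @param contrast Integer 1 (CN-s vs progressors), 2 (MCI-s vs progressors)
#'   or 3 (AD-ever vs never).
#' @param feature_sets Named list of class-tag combinations to evaluate;
#'   default: each of the four selection classes alone plus all combined.
#' @param n_factors,n_bins,cardinality,restarts Latent-factor settings.
#' @param k Top features per class in selection.
#' @param selection_cv,gbm_cv `c(repeats, folds)` for the two CV schemes.
#' @param grid Boosting grid (see [fit_gbm()]).
#' @param n_splits Number of repeated 70/30 splits to average over.
#' @param mode `"paper-faithful"` or `"split-safe"`.
#' @param seed Integer seed.
#' @param extra_features Optional `feature_table` of additional columns
#'   appended to the candidate panel (used by leakage diagnostics).
#' @return Object of class `contrast_result`: per-feature-set data.frame of
#'   split-averaged metrics (`auc` fraction; `accuracy`/`sensitivity`/
#'   `specificity` percent), per-split results, and the selected features.
#' @export
run_contrast <- function(cohort, contrast,
                         feature_sets = NULL,
                         n_factors = 25L, n_bins = 3L, cardinality = 2L,
                         restarts = 5L, k = 10L,
                         selection_cv = c(2L, 5L), gbm_cv = c(2L, 5L),
                         grid = default_gbm_grid(),
                         n_splits = 10L,
                         mode = c("paper-faithful", "split-safe"),
                         seed = 1L,
                         extra_features = NULL) {
  mode <- match.arg(mode)
  groups <- assign_groups(cohort$diagnoses)
  y_all <- contrast_outcome(groups, contrast)
  ft <- cohort$features
  subjects <- intersect(ft_subjects(ft), names(y_all))
  y <- y_all[subjects]
  ft <- ft_select(ft, subjects = subjects)
  if (is.null(feature_sets)) {
    feature_sets <- list(
      plasma = "plasma", brain = "brain",
      corex_plasma = "corex_plasma", corex_brain = "corex_brain",
      combined = c("plasma", "brain", "corex_plasma", "corex_brain"))
  }
  covariates <- as.data.frame(ft_data(ft_select(ft, tags = "demographic")))
  plasma_panel <- ft_select(ft, tags = c("plasma", "hallmark", "demographic"))
  brain_panel_raw <- ft_select(ft, tags = c("brain_thickness", "brain_area",
                                            "brain_volume"))

  build_panels <- function(train_idx = NULL) {
    # fit residualization, discretization and factor layers either on the
    # full cohort (paper-faithful) or on the training subjects only
    fit_idx <- if (is.null(train_idx)) seq_along(y) else train_idx
    brain_res_fit <- residualize(ft_select(brain_panel_raw, subjects = fit_idx),
                                 covariates[fit_idx, , drop = FALSE])
    brain_res <- residualize(brain_panel_raw, covariates,
                             coefficients = attr(brain_res_fit, "coefficients"))
    dp_plasma <- discretize(ft_select(plasma_panel, subjects = fit_idx), n_bins)
    dp_brain <- discretize(ft_select(brain_res, subjects = fit_idx), n_bins)
    cx_plasma <- fit_corex(dp_plasma, n_factors = n_factors,
                           cardinality = cardinality, seed = seed,
                           restarts = restarts)
    cx_brain <- fit_corex(dp_brain, n_factors = n_factors,
                          cardinality = cardinality, seed = seed + 1,
                          restarts = restarts)
    lab_plasma <- factor_labels(cx_plasma,
                                apply_discretization(dp_plasma, plasma_panel),
                                panel = "plasma")
    lab_brain <- factor_labels(cx_brain,
                               apply_discretization(dp_brain, brain_res),
                               panel = "brain")
    full <- ft_cbind(plasma_panel, brain_res, lab_plasma, lab_brain)
    if (!is.null(extra_features)) full <- ft_cbind(full, extra_features)
    full
  }

  if (mode == "paper-faithful") full_panel <- build_panels(NULL)

  split_results <- list()
  selected_log <- list()
  for (s in seq_len(n_splits)) {
    sp <- stratified_split(y, 0.7, seed = seed + 31L * s)
    panel <- if (mode == "paper-faithful") full_panel else build_panels(sp$train)
    Xtr_all <- ft_select(panel, subjects = sp$train)
    rep_sel <- ensemble_importance(Xtr_all, y[sp$train], "classification",
                                   seed = seed + s,
                                   cv_repeats = selection_cv[1],
                                   cv_folds = selection_cv[2])
    top <- top_k_per_class(rep_sel, k = k)
    top_classes <- attr(top, "classes")
    selected_log[[s]] <- top
    for (fs in names(feature_sets)) {
      keep <- top[top_classes %in% feature_sets[[fs]]]
      if (length(keep) == 0) next
      Xtr <- ft_select(panel, features = keep, subjects = sp$train)
      Xte <- ft_select(panel, features = keep, subjects = sp$test)
      model <- fit_gbm(Xtr, y[sp$train], grid = grid, seed = seed + s,
                       cv_repeats = gbm_cv[1], cv_folds = gbm_cv[2])
      res <- evaluate(model, Xte, y[sp$test])
      split_results[[length(split_results) + 1]] <- list(
        split = s, feature_set = fs, result = res,
        params = model$best_params, features = keep)
    }
  }
  fs_names <- unique(vapply(split_results, `[[`, character(1), "feature_set"))
  metrics <- do.call(rbind, lapply(fs_names, function(fs) {
    rs <- Filter(function(r) r$feature_set == fs, split_results)
    data.frame(
      feature_set = fs,
      auc = mean(vapply(rs, function(r) r$result$auc, numeric(1)), na.rm = TRUE),
      accuracy = mean(vapply(rs, function(r) r$result$accuracy, numeric(1))),
      sensitivity = mean(vapply(rs, function(r) r$result$sensitivity, numeric(1)), na.rm = TRUE),
      specificity = mean(vapply(rs, function(r) r$result$specificity, numeric(1)), na.rm = TRUE),
      n_splits = length(rs),
      stringsAsFactors = FALSE)
  }))
  structure(list(contrast = contrast, metrics = metrics,
                 splits = split_results, selected = selected_log,
                 mode = mode, seed = as.integer(seed),
                 n_subjects = length(y)),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast_result> contrast %d (%s mode), %d subjects\n",
              x$contrast, x$mode, x$n_subjects))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}
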