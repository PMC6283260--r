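# Ensemble feature importance and top-k-per-class selection.
#
# Five learners per task (classification: logistic GLM, gradient boosting,
# bagged trees, LDA, KNN; regression: linear model, gradient boosting, KNN,
# ridge, LASSO) each produce a cross-validated error and a per-feature
# importance on a 0-100 scale. The combined score is the convex combination
# of the per-learner importances weighted by inverse CV error, so learners
# that generalize better get more say.

make_folds <- function(y, n_folds, stratify = TRUE) {
  n <- length(y)
  fold <- integer(n)
  if (stratify) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
    }
  } else {
    fold <- sample(rep(seq_len(n_folds), length.out = n))
  }
  lapply(seq_len(n_folds), function(f) which(fold == f))
}

std_coef_importance <- function(beta, sds) {
  beta[is.na(beta)] <- 0
  abs(beta) * sds
}

fit_treebag <- function(X, y, task, n_trees = 25L) {
  df <- as.data.frame(X)
  df$.y <- if (task == "classification") factor(y) else y
  n <- nrow(df)
  trees <- vector("list", n_trees)
  oob <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    idx <- sample(n, replace = TRUE)
    trees[[t]] <- rpart::rpart(
      .y ~ ., data = df[idx, , drop = FALSE],
      method = if (task == "classification") "class" else "anova",
      control = rpart::rpart.control(cp = 0.01, xval = 0))
    oob[[t]] <- setdiff(seq_len(n), unique(idx))
  }
  structure(list(trees = trees, oob = oob, task = task), class = "treebag")
}

predict_treebag <- function(model, X) {
  df <- as.data.frame(X)
  preds <- vapply(model$trees, function(tr) {
    if (model$task == "classification") {
      pr <- predict(tr, df, type = "prob")
      if ("1" %in% colnames(pr)) pr[, "1"] else 1 - pr[, 1]
    } else {
      predict(tr, df)
    }
  }, numeric(nrow(df)))
  rowMeans(preds)
}

treebag_perm_importance <- function(model, X, y) {
  p <- ncol(X)
  imp <- numeric(p)
  err_fun <- if (model$task == "classification") {
    function(pred, truth) mean((pred > 0.5) != truth)
  } else {
    function(pred, truth) mean((pred - truth)^2)
  }
  for (t in seq_along(model$trees)) {
    oob <- model$oob[[t]]
    if (length(oob) < 5) next
    Xo <- X[oob, , drop = FALSE]
    perm <- sample(nrow(Xo))   # one shared permutation per tree, so the
                               # importances do not depend on column order
    base <- err_fun(predict_treebag(structure(list(trees = model$trees[t],
                                                   oob = model$oob[t],
                                                   task = model$task),
                                              class = "treebag"), Xo), y[oob])
    for (j in seq_len(p)) {
      Xp <- Xo
      Xp[, j] <- Xp[perm, j]
      ej <- err_fun(predict_treebag(structure(list(trees = model$trees[t],
                                                   oob = model$oob[t],
                                                   task = model$task),
                                              class = "treebag"), Xp), y[oob])
      imp[j] <- imp[j] + (ej - base)
    }
  }
  imp / length(model$trees)
}

knn_perm_importance <- function(X, y, task, k = 5L) {
  n <- nrow(X); p <- ncol(X)
  Xs <- scale(X)
  Xs[is.nan(Xs)] <- 0
  if (task == "classification") {
    base <- mean(as.character(class::knn.cv(Xs, factor(y), k = k)) != as.character(y))
    err_j <- function(Xp) mean(as.character(class::knn.cv(Xp, factor(y), k = k)) != as.character(y))
  } else {
    loo_mse <- function(Xp) {
      fit <- caret::knnreg(Xp, y, k = k)
      mean((predict(fit, Xp) - y)^2)   # resubstitution proxy (knn is lazy)
    }
    base <- loo_mse(Xs)
    err_j <- loo_mse
  }
  imp <- numeric(p)
  perm <- sample(n)   # shared permutation: column-order invariant
  for (j in seq_len(p)) {
    Xp <- Xs
    Xp[, j] <- Xp[perm, j]
    imp[j] <- err_j(Xp) - base
  }
  imp
}

xgb_fit <- function(X, y, task, seed, nrounds = 100L, max_depth = 3L, eta = 0.1,
                    min_child_weight = 1, weights = NULL) {
  params <- list(
    objective = if (task == "classification") "binary:logistic" else "reg:squarederror",
    max_depth = max_depth, eta = eta, min_child_weight = min_child_weight,
    nthread = 1, seed = as.integer(seed) %% .Machine$integer.max)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y,
                                 weight = if (is.null(weights)) rep(1, length(y)) else weights)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds, verbose = 0)
}

xgb_importance <- function(model, feature_names) {
  imp <- tryCatch(xgboost::xgb.importance(model = model), error = function(e) NULL)
  out <- stats::setNames(numeric(length(feature_names)), feature_names)
  if (!is.null(imp) && nrow(imp)) out[imp$Feature] <- imp$Gain
  out
}

learner_set <- function(task) {
  if (task == "classification") c("glm", "gbm", "treebag", "lda", "knn")
  else c("glm", "gbm", "knn", "ridge", "lasso")
}

cv_error_one <- function(X, y, task, learner, folds, seed) {
  errs <- numeric(0)
  for (f in seq_along(folds)) {
    te <- folds[[f]]
    tr <- setdiff(seq_len(nrow(X)), te)
    if (task == "classification" && length(unique(y[tr])) < 2) next
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    ytr <- y[tr]; yte <- y[te]
    pred <- switch(
      learner,
      glm = {
        df <- as.data.frame(Xtr); df$.y <- ytr
        fam <- if (task == "classification") stats::binomial() else stats::gaussian()
        fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = fam))
        suppressWarnings(predict(fit, as.data.frame(Xte), type = "response"))
      },
      gbm = {
        fit <- xgb_fit(Xtr, ytr, task, seed)
        predict(fit, as.matrix(Xte))
      },
      treebag = {
        fit <- fit_treebag(Xtr, ytr, task)
        predict_treebag(fit, Xte)
      },
      lda = {
        fit <- tryCatch(MASS::lda(Xtr, grouping = factor(ytr)),
                        error = function(e) NULL)
        if (is.null(fit)) rep(mean(ytr), length(yte))
        else predict(fit, Xte)$posterior[, "1"]
      },
      knn = {
        ms <- colMeans(Xtr); ss <- pmax(apply(Xtr, 2, stats::sd), 1e-12)
        Xtr_s <- scale(Xtr, ms, ss); Xte_s <- scale(Xte, ms, ss)
        if (task == "classification") {
          as.numeric(as.character(class::knn(Xtr_s, Xte_s, factor(ytr), k = 5)))
        } else {
          predict(caret::knnreg(Xtr_s, ytr, k = 5), Xte_s)
        }
      },
      ridge = ,
      lasso = {
        a <- if (learner == "ridge") 0 else 1
        cvfit <- glmnet::cv.glmnet(as.matrix(Xtr), ytr, alpha = a, nfolds = 5)
        as.numeric(predict(cvfit, as.matrix(Xte), s = "lambda.min"))
      })
    errs <- c(errs, if (task == "classification") mean((pred > 0.5) != (yte == 1))
              else mean((pred - yte)^2))
  }
  mean(errs)
}

importance_one <- function(X, y, task, learner, seed) {
  sds <- apply(X, 2, stats::sd)
  switch(
    learner,
    glm = {
      df <- as.data.frame(X); df$.y <- y
      fam <- if (task == "classification") stats::binomial() else stats::gaussian()
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = fam))
      std_coef_importance(stats::coef(fit)[colnames(X)], sds)
    },
    gbm = {
      fit <- xgb_fit(X, y, task, seed)
      xgb_importance(fit, colnames(X))
    },
    treebag = {
      fit <- fit_treebag(X, y, task)
      treebag_perm_importance(fit, X, y)
    },
    lda = {
      fit <- tryCatch(MASS::lda(X, grouping = factor(y)), error = function(e) NULL)
      if (is.null(fit)) numeric(ncol(X))
      else std_coef_importance(fit$scaling[colnames(X), 1], sds)
    },
    knn = knn_perm_importance(X, y, task),
    ridge = ,
    lasso = {
      a <- if (learner == "ridge") 0 else 1
      cvfit <- glmnet::cv.glmnet(as.matrix(X), y, alpha = a, nfolds = 5)
      beta <- as.numeric(stats::coef(cvfit, s = "lambda.min"))[-1]
      std_coef_importance(beta, sds)
    })
}

#' Ensemble feature importance with repeated cross-validated weighting
#'
#' @param X A `feature_table` or numeric matrix of candidate features.
#' @param y Outcome: 0/1 for classification, numeric for regression.
#' @param task `"classification"` or `"regression"`.
#' @param seed Integer seed; the report is deterministic given the seed.
#' @param cv_repeats,cv_folds Repeated k-fold scheme for the per-learner
#'   error used in the combination weights (defaults 10 x 10). Folds are
#'   reduced with a warning if they would hold fewer than 10 subjects.
#' @param learners Optional subset of learner names.
#' @return An `importance_report` data.frame: one row per feature with its
#'   selection class, per-learner importances (0-100, max 100 per learner),
#'   `combined` score and dense `rank`. Attributes: `weights` (per-learner,
#'   non-negative, summing to 1), `cv_error`, `task`, `cv_scheme`.
#' @export
ensemble_importance <- function(X, y, task = c("classification", "regression"),
                                seed = 1L, cv_repeats = 10L, cv_folds = 10L,
                                learners = NULL) {
  task <- match.arg(task)
  classes <- NULL
  if (inherits(X, "feature_table")) {
    classes <- selection_class(ft_classes(X))
    X <- ft_data(X)
  }
  X <- as.matrix(X)
  if (nrow(X) < 50) stop("ensemble_importance needs at least 50 subjects")
  if (length(y) != nrow(X)) stop("y length mismatch")
  if (task == "classification") {
    y <- as.integer(y)
    if (length(unique(y)) < 2) stop("y is constant")
    if (!all(y %in% c(0L, 1L))) stop("classification y must be binary 0/1")
  } else {
    y <- as.numeric(y)
    if (stats::sd(y) == 0) stop("y is constant")
  }
  if (nrow(X) / cv_folds < 10) {
    cv_folds <- max(2L, floor(nrow(X) / 10))
    warning("reducing cv_folds to ", cv_folds, " to keep >= 10 subjects per fold")
  }
  if (is.null(learners)) learners <- learner_set(task)
  set.seed(as.integer(seed))
  cv_err <- stats::setNames(numeric(length(learners)), learners)
  for (l in learners) {
    errs <- numeric(cv_repeats)
    for (r in seq_len(cv_repeats)) {
      folds <- make_folds(y, cv_folds, stratify = task == "classification")
      errs[r] <- cv_error_one(X, y, task, l, folds, seed + r)
    }
    cv_err[l] <- mean(errs)
  }
  imp <- sapply(learners, function(l) {
    v <- importance_one(X, y, task, l, seed)
    v <- pmax(as.numeric(v), 0)
    if (max(v) > 0) v * 100 / max(v) else v
  })
  rownames(imp) <- colnames(X)
  w <- 1 / pmax(cv_err, 1e-3)
  w <- w / sum(w)
  combined <- as.numeric(imp %*% w)
  ord <- order(-combined, colnames(X))
  rank <- integer(length(combined))
  rank[ord] <- seq_along(ord)
  report <- data.frame(
    feature = colnames(X),
    class = if (is.null(classes)) NA_character_ else unname(classes[colnames(X)]),
    imp, combined = combined, rank = rank,
    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(report) <- NULL
  attr(report, "weights") <- w
  attr(report, "cv_error") <- cv_err
  attr(report, "task") <- task
  attr(report, "cv_scheme") <- c(repeats = cv_repeats, folds = cv_folds)
  class(report) <- c("importance_report", "data.frame")
  report
}

#' Top k features within each selection class
#'
#' Takes the `k` features with the highest combined score inside each of the
#' four selection classes (plasma, brain, corex_plasma, corex_brain); classes
#' with fewer than `k` features contribute all of theirs. Ties at the k-th
#' score break lexicographically on the feature name.
#'
#' @param report An `importance_report` with a `class` column.
#' @param k Features per class (default 10).
#' @return Character vector of selected feature names, with the per-feature
#'   class as the `classes` attribute.
#' @export
top_k_per_class <- function(report, k = 10L) {
  if (all(is.na(report$class))) stop("report carries no selection classes")
  sel <- character(0)
  cls <- character(0)
  for (cl in unique(report$class)) {
    sub <- report[report$class == cl, ]
    sub <- sub[order(-sub$combined, sub$feature), ]
    take <- utils::head(sub$feature, k)
    sel <- c(sel, take)
    cls <- c(cls, rep(cl, length(take)))
  }
  attr(sel, "classes") <- stats::setNames(cls, sel)
  sel
}

#' Re-rank the pooled top-k selection across classes
#'
#' @param selected Character vector from [top_k_per_class()].
#' @param X The `feature_table` the selection came from.
#' @param y,task,seed,cv_repeats,cv_folds,learners As [ensemble_importance()].
#' @return An `importance_report` over the pooled set.
#' @export
joint_rerank <- function(selected, X, y, task = c("classification", "regression"),
                         seed = 1L, cv_repeats = 10L, cv_folds = 10L,
                         learners = NULL) {
  if (!length(selected)) stop("empty selection")
  ensemble_importance(ft_select(X, features = selected), y, task, seed,
                      cv_repeats, cv_folds, learners)
}
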