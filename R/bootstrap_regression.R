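# Stability selection for continuous outcomes: bidirectional stepwise OLS
# (BIC by default; AIC available) refit on bootstrap resamples; a feature's
# selection frequency across resamples measures how stably it predicts the
# outcome. BIC is the default because stability selection is about support
# recovery: AIC's entry threshold (|t| > 1.41) lies below the expected
# largest spurious correlation among even a handful of null features, so the
# luckiest noise feature in any fixed sample is re-selected in most
# resamples; BIC's log(n) penalty clears it.

# bidirectional stepwise OLS from the intercept-only model, penalty-k AIC
# (k = 2 for AIC, log(n) for BIC), matching stats::extractAIC's scale
stepwise_lm <- function(X, y, k_pen = 2) {
  n <- length(y)
  p <- ncol(X)
  rss_for <- function(cols) {
    fit <- stats::.lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
    sum(fit$residuals^2)
  }
  aic_for <- function(rss, n_coef) n * log(rss / n) + k_pen * n_coef
  active <- integer(0)
  cur_aic <- aic_for(rss_for(active), 1)
  repeat {
    best_aic <- cur_aic - 1e-10
    best_move <- NULL
    for (j in setdiff(seq_len(p), active)) {
      aic <- aic_for(rss_for(c(active, j)), length(active) + 2)
      if (aic < best_aic) { best_aic <- aic; best_move <- c(1L, j) }
    }
    for (j in active) {
      aic <- aic_for(rss_for(setdiff(active, j)), length(active))
      if (aic < best_aic) { best_aic <- aic; best_move <- c(-1L, j) }
    }
    if (is.null(best_move)) break
    active <- if (best_move[1] > 0) c(active, best_move[2]) else setdiff(active, best_move[2])
    cur_aic <- best_aic
  }
  coefs <- numeric(0)
  if (length(active)) {
    fit <- stats::.lm.fit(cbind(1, X[, active, drop = FALSE]), y)
    coefs <- stats::setNames(fit$coefficients[-1], colnames(X)[active])
  }
  list(selected = colnames(X)[active], coefficients = coefs, aic = cur_aic)
}

#' Bootstrap stepwise regression stability selection
#'
#' For each of `B` bootstrap resamples (n subjects drawn with replacement), a
#' bidirectional stepwise ordinary least squares starting from the
#' intercept-only model adds and drops features by BIC (or AIC) until no move
#' improves the criterion. The report counts how often each feature was
#' retained and the direction of its effect when retained.
#'
#' @param X Candidate features (`feature_table` or numeric matrix), typically
#'   the pooled post-selection set.
#' @param y Continuous outcome.
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed; deterministic given the seed. Rows are ordered
#'   by subject ID internally so the report does not depend on input row
#'   order.
#' @param criterion `"bic"` (default) or `"aic"`.
#' @return Object of class `bootstrap_selection_report`: data.frame with one
#'   row per feature (`feature`, `count`, `frequency`, `modal_sign`
#'   in `+`/`-`/`mixed`, `mean_beta` over the resamples where selected),
#'   sorted by frequency; attributes `B`, `criterion`.
#' @export
bootstrap_stepwise <- function(X, y, B = 1000L, seed = 1L,
                               criterion = c("bic", "aic")) {
  criterion <- match.arg(criterion)
  classes <- NULL
  if (inherits(X, "feature_table")) {
    classes <- selection_class(ft_classes(X))
    X <- ft_data(X)
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%02d", seq_len(ncol(X)))
  if (length(y) != nrow(X)) stop("y length mismatch")
  if (!is.null(rownames(X))) {
    ord <- order(rownames(X))
    X <- X[ord, , drop = FALSE]
    y <- y[ord]
  }
  dup <- duplicated(t(X))
  if (any(dup)) {
    warning("dropping duplicate column(s): ",
            paste(colnames(X)[dup], collapse = ", "))
    X <- X[, !dup, drop = FALSE]
    if (!is.null(classes)) classes <- classes[colnames(X)]
  }
  n <- nrow(X)
  p <- ncol(X)
  k_pen <- if (criterion == "aic") 2 else log(n)
  set.seed(as.integer(seed))
  count <- stats::setNames(integer(p), colnames(X))
  pos <- neg <- stats::setNames(integer(p), colnames(X))
  beta_sum <- stats::setNames(numeric(p), colnames(X))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    fit <- stepwise_lm(X[idx, , drop = FALSE], y[idx], k_pen = k_pen)
    count[fit$selected] <- count[fit$selected] + 1L
    sg <- sign(fit$coefficients)
    pos[names(sg)[sg > 0]] <- pos[names(sg)[sg > 0]] + 1L
    neg[names(sg)[sg < 0]] <- neg[names(sg)[sg < 0]] + 1L
    beta_sum[names(fit$coefficients)] <- beta_sum[names(fit$coefficients)] +
      fit$coefficients
  }
  modal <- ifelse(count == 0, "",
                  ifelse(pos / pmax(count, 1) >= 0.6, "+",
                         ifelse(neg / pmax(count, 1) >= 0.6, "-", "mixed")))
  report <- data.frame(
    feature = colnames(X),
    class = if (is.null(classes)) NA_character_ else unname(classes[colnames(X)]),
    count = as.integer(count),
    frequency = count / B,
    modal_sign = modal,
    mean_beta = ifelse(count > 0, beta_sum / pmax(count, 1), NA_real_),
    stringsAsFactors = FALSE)
  report <- report[order(-report$frequency, report$feature), ]
  rownames(report) <- NULL
  attr(report, "B") <- as.integer(B)
  attr(report, "criterion") <- criterion
  class(report) <- c("bootstrap_selection_report", "data.frame")
  report
}

#' Features maintained by bootstrap selection
#'
#' @param report A `bootstrap_selection_report`.
#' @param threshold Minimum selection frequency (inclusive, default 0.5).
#' @return Character vector of maintained features; attribute `composition`
#'   gives the fraction of maintained features in each selection class when
#'   class tags are available.
#' @export
maintained_features <- function(report, threshold = 0.5) {
  keep <- report[report$frequency >= threshold, ]
  out <- keep$feature
  if (!all(is.na(keep$class)) && nrow(keep)) {
    attr(out, "composition") <- prop.table(table(keep$class))
  }
  out
}
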