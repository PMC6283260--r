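#' Plug-in Shannon entropy in bits from a count or probability vector
#' @param counts Non-negative counts (or probabilities).
#' @return Entropy in bits.
#' @export
plugin_entropy <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("negative counts")
  total <- sum(counts)
  if (total <= 0) stop("empty distribution")
  p <- counts / total
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Plug-in mutual information between two discrete columns, in bits
#'
#' I(X;Y) = H(X) + H(Y) - H(X,Y), estimated from the empirical joint
#' frequencies. Symmetric in its arguments; equals H(X) when `y` is `x`.
#'
#' @param x,y Discrete vectors of equal length (any atomic type).
#' @return Mutual information in bits (non-negative up to floating point).
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  hx <- plugin_entropy(table(x))
  hy <- plugin_entropy(table(y))
  hxy <- plugin_entropy(table(interaction(x, y, drop = TRUE, lex.order = TRUE)))
  max(hx + hy - hxy, 0)
}

#' Plug-in total correlation of a set of discrete columns, in bits
#'
#' TC(X1,...,XN) = sum_i H(Xi) - H(X1,...,XN), estimated exactly from the
#' empirical joint frequencies by enumerating the observed joint support.
#' For two columns this reduces exactly to their mutual information. The
#' joint support is enumerated directly, so the number of columns is capped.
#'
#' @param data Matrix or data.frame of discrete columns.
#' @param columns Optional subset of column names or indices.
#' @param max_columns Enumeration cap (default 12).
#' @return Total correlation in bits (non-negative up to floating point).
#' @export
total_correlation <- function(data, columns = NULL, max_columns = 12L) {
  data <- as.data.frame(data)
  if (!is.null(columns)) data <- data[, columns, drop = FALSE]
  if (ncol(data) < 2) stop("total correlation needs at least 2 columns")
  if (ncol(data) > max_columns) {
    stop(sprintf(
      "total_correlation enumerates the joint support exactly and is limited to %d columns (got %d)",
      max_columns, ncol(data)))
  }
  h_marg <- vapply(data, function(col) plugin_entropy(table(col)), numeric(1))
  key <- do.call(paste, c(data, sep = "\r"))
  h_joint <- plugin_entropy(table(key))
  max(sum(h_marg) - h_joint, 0)
}

#' Quantile-discretize a feature panel for latent factor training
#'
#' Each numeric column is binned into `n_bins` levels at its empirical
#' quantiles. Ordinal columns that already take `n_bins` or fewer distinct
#' whole-number values pass through unchanged (recoded to 0-based levels);
#' constant columns map to a single level and are flagged.
#'
#' @param features A `feature_table` or numeric matrix.
#' @param n_bins Number of quantile bins (>= 2, default 3).
#' @return An object of class `discrete_panel`: list with `x` (integer matrix
#'   of 0-based levels), `n_levels` (per column), `constant` (logical flags),
#'   and `breaks` (per-column quantile cut points, reusable on new data).
#' @export
discretize <- function(features, n_bins = 3L) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  x <- if (inherits(features, "feature_table")) ft_data(features) else as.matrix(features)
  if (!is.numeric(x)) {
    bad <- colnames(x)[!apply(x, 2, is.numeric)]
    stop("non-numeric column(s): ", paste(bad, collapse = ", "))
  }
  if (anyNA(x)) stop("discretize does not accept missing values")
  p <- ncol(x)
  out <- matrix(0L, nrow(x), p, dimnames = dimnames(x))
  n_levels <- integer(p)
  constant <- logical(p)
  breaks <- vector("list", p)
  names(breaks) <- colnames(x)
  for (i in seq_len(p)) {
    col <- x[, i]
    u <- sort(unique(col))
    if (length(u) == 1) {
      constant[i] <- TRUE
      n_levels[i] <- 1L
      breaks[[i]] <- u
    } else if (length(u) <= n_bins && all(u == round(u))) {
      # ordinal pass-through
      out[, i] <- match(col, u) - 1L
      n_levels[i] <- length(u)
      breaks[[i]] <- u
    } else {
      qs <- stats::quantile(col, probs = seq(0, 1, length.out = n_bins + 1),
                            names = FALSE, type = 7)
      qs <- unique(qs)
      codes <- cut(col, breaks = qs, include.lowest = TRUE, labels = FALSE)
      out[, i] <- as.integer(codes) - 1L
      n_levels[i] <- max(codes)
      breaks[[i]] <- qs
    }
  }
  structure(list(x = out, n_levels = n_levels, constant = constant,
                 breaks = breaks, n_bins = as.integer(n_bins)),
            class = "discrete_panel")
}

#' Apply a fitted discretization to new data
#'
#' Re-uses the quantile cut points (or ordinal level maps) learned by
#' [discretize()] so held-out subjects can be coded without touching the
#' training quantiles.
#'
#' @param panel A `discrete_panel`.
#' @param newdata Numeric matrix or `feature_table` with the same columns.
#' @return Integer matrix of 0-based levels.
#' @export
apply_discretization <- function(panel, newdata) {
  x <- if (inherits(newdata, "feature_table")) ft_data(newdata) else as.matrix(newdata)
  if (!identical(colnames(x), names(panel$breaks))) {
    stop("newdata columns must match the discretized panel")
  }
  out <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  for (i in seq_len(ncol(x))) {
    br <- panel$breaks[[i]]
    if (panel$constant[i]) {
      out[, i] <- 0L
    } else if (panel$n_levels[i] <= length(br) && all(br == round(br)) &&
               length(br) == panel$n_levels[i]) {
      # ordinal map: snap to the nearest trained level
      idx <- vapply(x[, i], function(v) which.min(abs(br - v)), integer(1))
      out[, i] <- idx - 1L
    } else {
      codes <- cut(pmin(pmax(x[, i], br[1]), br[length(br)]),
                   breaks = br, include.lowest = TRUE, labels = FALSE)
      out[, i] <- as.integer(codes) - 1L
    }
  }
  out
}

#' @export
print.discrete_panel <- function(x, ...) {
  cat(sprintf("<discrete_panel> %d subjects x %d columns, %d bins (%d constant)\n",
              nrow(x$x), ncol(x$x), x$n_bins, sum(x$constant)))
  invisible(x)
}
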