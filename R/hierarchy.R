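#' Fit a hierarchy of latent factor layers
#'
#' Layer 1 is trained on the (discretized) observed variables; every
#' subsequent layer is trained on the maximum-likelihood labels of the layer
#' below, so lower layers capture local dependence among variables and upper
#' layers capture dependence among the factors themselves. Edges between
#' consecutive layers carry the plug-in mutual information (bits) between the
#' child's values and the parent factor's labels.
#'
#' @param features A `feature_table`, numeric matrix (discretized
#'   internally), or `discrete_panel`.
#' @param layer_sizes Strictly decreasing integer vector of factor counts per
#'   layer (default 25 for a single layer).
#' @param seed Integer seed.
#' @param n_bins Quantile bins for continuous variables (default 3).
#' @param ... Further arguments passed to [fit_corex()] (cardinality,
#'   restarts, ...).
#' @return An object of class `corex_hierarchy`: `layers` (list of
#'   `corex_layer`), `edges` (data.frame child, parent, layer, mi), and the
#'   fitted discretization.
#' @export
fit_hierarchy <- function(features, layer_sizes = 25L, seed = 1L,
                          n_bins = 3L, ...) {
  layer_sizes <- as.integer(layer_sizes)
  if (any(layer_sizes < 1)) stop("layer sizes must be positive")
  if (length(layer_sizes) > 1 && any(diff(layer_sizes) >= 0)) {
    stop("layer_sizes must be strictly decreasing")
  }
  panel <- if (inherits(features, "discrete_panel")) features else discretize(features, n_bins)
  current <- panel
  child_names <- colnames(panel$x)
  layers <- vector("list", length(layer_sizes))
  edges <- list()
  for (l in seq_along(layer_sizes)) {
    layers[[l]] <- fit_corex(current, n_factors = layer_sizes[l],
                             seed = as.integer(seed) + l, ...)
    labels <- layers[[l]]$labels
    factor_names <- sprintf("L%d_F%02d", l, seq_len(layer_sizes[l]) - 1L)
    colnames(labels) <- factor_names
    xin <- if (inherits(current, "discrete_panel")) current$x else current
    mi <- empirical_mi_matrix(xin, labels)
    edges[[l]] <- data.frame(
      child = rep(child_names, times = layer_sizes[l]),
      parent = rep(factor_names, each = length(child_names)),
      layer = l,
      mi = as.vector(mi),
      stringsAsFactors = FALSE
    )
    current <- labels
    child_names <- factor_names
  }
  structure(list(layers = layers,
                 edges = do.call(rbind, edges),
                 panel = panel,
                 layer_sizes = layer_sizes),
            class = "corex_hierarchy")
}

#' @export
print.corex_hierarchy <- function(x, ...) {
  cat(sprintf("<corex_hierarchy> %d layer(s): %s; %d variables\n",
              length(x$layers), paste(x$layer_sizes, collapse = " -> "),
              ncol(x$panel$x)))
  invisible(x)
}
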