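# Graph export of a trained factor hierarchy: variables and factor nodes,
# child->parent edges weighted by mutual information (bits), with the visual
# semantics stored as attributes (node size = explained TC of the factor,
# edge shade = MI normalized to [0,1] by the layer maximum).

#' Build the attributed factor graph of a hierarchy
#'
#' @param hierarchy A `corex_hierarchy`.
#' @param mi_floor Edges with mutual information below this many bits are
#'   pruned (default 0.01).
#' @param classes Optional named vector of class tags for the observed
#'   variables (stored as a node attribute).
#' @return An `igraph` directed graph, bipartite between consecutive layers.
#' @export
as_factor_graph <- function(hierarchy, mi_floor = 0.01, classes = NULL) {
  vars <- colnames(hierarchy$panel$x)
  nodes <- data.frame(name = vars, kind = "variable", layer = 0L,
                      size = 0, stringsAsFactors = FALSE)
  for (l in seq_along(hierarchy$layers)) {
    ly <- hierarchy$layers[[l]]
    nodes <- rbind(nodes, data.frame(
      name = sprintf("L%d_F%02d", l, seq_len(ly$config$n_factors) - 1L),
      kind = "factor", layer = l,
      size = ly$explained_tc, stringsAsFactors = FALSE))
  }
  nodes$class <- if (is.null(classes)) "" else {
    ifelse(nodes$name %in% names(classes), unname(classes[nodes$name]), "")
  }
  edges <- hierarchy$edges
  edges <- edges[edges$mi >= mi_floor, , drop = FALSE]
  if (nrow(edges)) {
    layer_max <- stats::ave(edges$mi, edges$layer, FUN = max)
    edges$shade <- ifelse(layer_max > 0, edges$mi / layer_max, 0)
  } else {
    edges$shade <- numeric(0)
  }
  igraph::graph_from_data_frame(
    edges[, c("child", "parent", "mi", "shade", "layer")],
    directed = TRUE, vertices = nodes)
}

#' Export a factor hierarchy to GraphML or DOT
#'
#' @param hierarchy A `corex_hierarchy`.
#' @param path Output file path.
#' @param format `"graphml"` (attribute-rich, round-trips through
#'   [igraph::read_graph()]) or `"dot"`.
#' @param mi_floor Minimum edge mutual information in bits (default 0.01).
#' @param classes Optional variable class tags (see [as_factor_graph()]).
#' @return `path`, invisibly.
#' @export
export_graph <- function(hierarchy, path, format = c("graphml", "dot"),
                         mi_floor = 0.01, classes = NULL) {
  format <- match.arg(format)
  g <- as_factor_graph(hierarchy, mi_floor = mi_floor, classes = classes)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
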