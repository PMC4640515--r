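# Network topology metrics reported for gene-sharing networks: local
# clustering coefficient, betweenness centrality, connected components.
# All metrics run on the unweighted skeleton by default, matching the
# defaults of the common interactive network analyzers; a weighted
# betweenness mode (distance = 1/Sig) is available behind a flag.

#' Per-node clustering coefficient and graph mean
#'
#' `CC(v) = 2 e(N(v)) / (deg(v) (deg(v) - 1))` on the unweighted skeleton;
#' nodes of degree < 2 score 0. The mean is taken over all nodes.
#'
#' @param graph An igraph network.
#' @return List with `per_node` (named numeric) and `mean`.
#' @export
clustering_coefficient <- function(graph) {
  cc <- igraph::transitivity(graph, type = "localundirected", isolates = "zero")
  names(cc) <- vertex_ids(graph)
  list(per_node = cc, mean = mean(cc))
}

#' Exact shortest-path betweenness centrality
#'
#' Raw betweenness counts, for every ordered pair of other nodes, the
#' fraction of shortest paths through the node (each unordered pair counted
#' once for undirected graphs). Normalisation divides by `(n-1)(n-2)/2`
#' with the whole-graph `n`; graphs with `n < 3` get normalised BC 0.
#'
#' @param graph An igraph network.
#' @param weighted If `TRUE`, use distance `1/weight` (strong edges are
#'   short); default unweighted.
#' @return List with `raw` and `normalized` named numeric vectors.
#' @export
betweenness_centrality <- function(graph, weighted = FALSE) {
  n <- igraph::vcount(graph)
  w <- if (weighted && "weight" %in% igraph::edge_attr_names(graph))
    1 / igraph::E(graph)$weight else NA
  raw <- igraph::betweenness(graph, weights = w, directed = FALSE)
  names(raw) <- vertex_ids(graph)
  norm <- if (n < 3) setNames(rep(0, n), names(raw))
  else raw * 2 / ((n - 1) * (n - 2))
  list(raw = raw, normalized = norm)
}

#' Connected components of a network
#'
#' @param graph An igraph network.
#' @return List with `count` and `sizes` (sorted decreasing).
#' @export
graph_components <- function(graph) {
  comp <- igraph::components(graph)
  list(count = as.integer(comp$no),
       sizes = sort(as.integer(comp$csize), decreasing = TRUE))
}

#' Full topology report for a network
#'
#' @param graph An igraph network.
#' @param weighted_bc Passed to [betweenness_centrality()].
#' @return Data.frame with `node`, `degree`, `cc`, `bc_raw`, `bc_norm`;
#'   attribute `"summary"` holds `mean_cc`, `n_components`, and component
#'   `sizes`.
#' @export
topology_report <- function(graph, weighted_bc = FALSE) {
  cc <- clustering_coefficient(graph)
  bc <- betweenness_centrality(graph, weighted = weighted_bc)
  comp <- graph_components(graph)
  out <- data.frame(node = vertex_ids(graph),
                    degree = as.integer(igraph::degree(graph)),
                    cc = unname(cc$per_node),
                    bc_raw = unname(bc$raw),
                    bc_norm = unname(bc$normalized),
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- list(mean_cc = cc$mean,
                               n_components = comp$count,
                               sizes = comp$sizes)
  out
}
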