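# Per-node cluster membership: the pie-wedge data quantifying mosaicism.
#
# A node's membership to a cluster is the proportion of its total incident
# edge weight (Sig, or edge count in unweighted mode) carried by edges to
# members of that cluster. A pure cluster member has membership 1 to its
# own cluster; a mosaic genome splits its membership across several.

#' Node x cluster membership matrix
#'
#' `m(n, k) = sum over u in cluster k of w(n, u) / sum over all u of
#' w(n, u)`. Self-loops never contribute (self-similarity is not evidence
#' of affiliation). Rows of connected nodes are exactly row-stochastic.
#' Isolated nodes get membership 1 to their own cluster, are flagged in
#' attribute `"isolated"`, and trigger a warning.
#'
#' @param graph An igraph network with Sig weights in edge attribute
#'   `weight` (absent weights count edges).
#' @param clustering An `mcl_clustering` object or named membership vector
#'   covering the graph's nodes.
#' @param weighted Use Sig weights (`TRUE`, default) or raw edge counts.
#' @return Numeric matrix, nodes x clusters (columns named by cluster id),
#'   with attribute `"isolated"` listing nodes with no incident edges.
#' @export
membership_matrix <- function(graph, clustering, weighted = TRUE) {
  membership <- if (inherits(clustering, "mcl_clustering"))
    clustering$membership else clustering
  ids <- vertex_ids(graph)
  if (!all(ids %in% names(membership)))
    stop("clustering does not cover all graph nodes")
  membership <- membership[ids]
  clusters <- sort(unique(membership))

  el <- igraph::as_edgelist(graph)
  w <- if (weighted && "weight" %in% igraph::edge_attr_names(graph))
    igraph::E(graph)$weight else rep(1, nrow(el))
  keep <- el[, 1] != el[, 2]  # drop self-loops
  el <- el[keep, , drop = FALSE]
  w <- w[keep]

  m <- matrix(0, length(ids), length(clusters),
              dimnames = list(ids, as.character(clusters)))
  if (nrow(el)) {
    # each edge contributes to both endpoints' rows
    long_node <- c(el[, 1], el[, 2])
    long_clu <- as.character(membership[c(el[, 2], el[, 1])])
    long_w <- c(w, w)
    for (r in seq_along(long_node))
      m[long_node[r], long_clu[r]] <- m[long_node[r], long_clu[r]] + long_w[r]
  }
  tot <- rowSums(m)
  isolated <- ids[tot == 0]
  if (length(isolated)) {
    warning(length(isolated), " isolated node(s) assigned membership 1 to ",
            "their own cluster")
    m[cbind(isolated, as.character(membership[isolated]))] <- 1
    tot[isolated] <- 1
  }
  m <- m / tot
  attr(m, "isolated") <- isolated
  m
}

#' Long-form wedge table for pie-chart display
#'
#' Keeps per node only memberships above `display_threshold`, adding an
#' `"other"` row carrying the remainder so each node's retained proportions
#' sum to 1.
#'
#' @param matrix A [membership_matrix()] result.
#' @param display_threshold Strict lower bound for a wedge (default 0.01).
#' @return Data.frame with columns `node`, `cluster`, `proportion`.
#' @export
wedge_table <- function(matrix, display_threshold = 0.01) {
  rows <- lapply(rownames(matrix), function(n) {
    v <- matrix[n, ]
    keep <- which(v > display_threshold)
    out <- data.frame(node = n, cluster = colnames(matrix)[keep],
                      proportion = unname(v[keep]),
                      stringsAsFactors = FALSE)
    rem <- 1 - sum(v[keep])
    if (rem > 1e-12)
      out <- rbind(out, data.frame(node = n, cluster = "other",
                                   proportion = rem))
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count clusters each node is assigned to
#'
#' The number of clusters with membership above `assign_threshold` — the
#' multi-cluster assignment count that flags bridge-like mosaic genomes.
#'
#' @param matrix A [membership_matrix()] result.
#' @param assign_threshold Strict membership threshold (default 0.01).
#' @return Named integer vector, one count per node (>= 1 for connected
#'   nodes).
#' @export
multi_cluster_report <- function(matrix, assign_threshold = 0.01) {
  apply(matrix, 1, function(v) sum(v > assign_threshold))
}

#' Write a membership matrix as TSV (6 decimals)
#'
#' @param matrix A [membership_matrix()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_membership <- function(matrix, path) {
  out <- format(round(matrix, 6), nsmall = 6, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
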