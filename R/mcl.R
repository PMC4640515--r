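# Markov clustering (MCL) of the gene-sharing network.
#
# MCL simulates random flow on the weighted graph: the column-stochastic
# transition matrix is alternately squared (expansion, spreading flow) and
# raised elementwise to the inflation power with column renormalisation
# (inflation, sharpening flow). Flow condenses onto attractors; clusters
# are the attractor systems together with the nodes attracted to them.
# Inflation is the granularity dial: the sweep runs it over a grid and
# keeps the clustering with the highest intra-cluster homogeneity.

#' Parameters for a single MCL run
#'
#' @param inflation Inflation exponent, `> 1`.
#' @param max_iterations Iteration cap (default 200).
#' @param convergence_tol Stop when the max absolute change of the flow
#'   matrix over one expansion+inflation step falls below this.
#' @param prune_tol Entries below this are zeroed (then columns
#'   renormalised) after each inflation.
#' @param self_loop_mode `"max-weight"` gives each node a self-loop equal
#'   to its maximum incident edge weight (1 for isolated nodes);
#'   `"unit"` uses 1 everywhere.
#' @return An object of class `mcl_params`.
#' @export
mcl_params <- function(inflation = 2, max_iterations = 200L,
                       convergence_tol = 1e-8, prune_tol = 1e-6,
                       self_loop_mode = c("max-weight", "unit")) {
  if (inflation <= 1) stop("inflation must be > 1")
  if (convergence_tol <= 0 || prune_tol <= 0) stop("tolerances must be > 0")
  structure(list(inflation = inflation,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 prune_tol = prune_tol,
                 self_loop_mode = match.arg(self_loop_mode)),
            class = "mcl_params")
}

# weighted adjacency with self-loops, as a dense matrix
mcl_matrix <- function(graph, self_loop_mode) {
  has_w <- "weight" %in% igraph::edge_attr_names(graph)
  A <- igraph::as_adjacency_matrix(graph, attr = if (has_w) "weight" else NULL,
                                   sparse = FALSE)
  diag(A) <- 0
  loops <- if (self_loop_mode == "max-weight") {
    mx <- apply(A, 2, max)
    ifelse(mx > 0, mx, 1)
  } else rep(1, nrow(A))
  diag(A) <- loops
  A
}

#' Run Markov clustering on a weighted network
#'
#' @param graph An igraph network; edge attribute `weight` is used when
#'   present, otherwise edges count 1.
#' @param params An [mcl_params()] object.
#' @return An object of class `mcl_clustering`: list with `membership`
#'   (named integer vector; cluster ids are dense integers ordered by
#'   decreasing cluster size, ties by lexicographically smallest member),
#'   `n_clusters`, `inflation`, `homogeneity` (see [icc_homogeneity()]),
#'   `converged`, `iterations`, and `stochasticity_dev` (max deviation of
#'   any column sum from 1 observed after an inflation step).
#' @export
run_mcl <- function(graph, params = mcl_params()) {
  stopifnot(inherits(params, "mcl_params"))
  n <- igraph::vcount(graph)
  if (n == 0L) stop("empty graph")
  ids <- vertex_ids(graph)
  M <- mcl_matrix(graph, params$self_loop_mode)
  M <- sweep(M, 2, colSums(M), "/")

  converged <- FALSE
  iter <- 0L
  stoch_dev <- 0
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    prev <- M
    M <- M %*% M                      # expansion
    M <- M^params$inflation           # inflation
    M <- sweep(M, 2, colSums(M), "/")
    M[M < params$prune_tol] <- 0      # prune small flow, renormalise
    cs <- colSums(M)
    if (any(cs == 0)) stop("flow column vanished; prune_tol too aggressive")
    M <- sweep(M, 2, cs, "/")
    stoch_dev <- max(stoch_dev, max(abs(colSums(M) - 1)))
    if (max(abs(M - prev)) < params$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("MCL did not converge in ", params$max_iterations, " iterations")

  membership <- interpret_flow(M, ids, params$prune_tol)
  res <- structure(list(membership = membership,
                        n_clusters = max(membership),
                        inflation = params$inflation,
                        homogeneity = NA_real_,
                        converged = converged,
                        iterations = iter,
                        stochasticity_dev = stoch_dev),
                   class = "mcl_clustering")
  res$homogeneity <- icc_homogeneity(graph, res)
  res
}

# Read a hard partition off the limit flow matrix. Attractors are nodes
# with residual diagonal mass; attractors connected through nonzero flow
# form one attractor system; every other node joins the system receiving
# the largest share of its column mass (ties: the system with the smaller
# index after ordering). Cluster ids are then densely relabelled by
# decreasing size, ties by smallest member label.
interpret_flow <- function(M, ids, tol) {
  n <- nrow(M)
  attractors <- which(diag(M) > tol)
  if (length(attractors) == 0L) attractors <- seq_len(n)  # degenerate fallback
  S <- (M[attractors, attractors, drop = FALSE] > tol) |
    t(M[attractors, attractors, drop = FALSE] > tol)
  ga <- igraph::graph_from_adjacency_matrix(S, mode = "undirected", diag = TRUE)
  sys_of <- igraph::components(ga)$membership
  n_sys <- max(sys_of)

  cl <- integer(n)
  cl[attractors] <- sys_of
  rest <- setdiff(seq_len(n), attractors)
  for (v in rest) {
    mass <- vapply(seq_len(n_sys), function(s)
      sum(M[attractors[sys_of == s], v]), numeric(1))
    cl[v] <- which.max(mass)  # which.max takes the smaller index on ties
  }

  # dense relabel: by decreasing size, ties by smallest member label
  sizes <- tabulate(cl, nbins = n_sys)
  firsts <- vapply(seq_len(n_sys), function(s)
    if (sizes[s] > 0) min(ids[cl == s]) else "", character(1))
  ord <- order(-sizes, firsts)
  ord <- ord[sizes[ord] > 0]
  relabel <- integer(n_sys)
  relabel[ord] <- seq_along(ord)
  setNames(relabel[cl], ids)
}

#' Intra-cluster clustering-coefficient homogeneity (ICCC)
#'
#' The size-weighted mean, over clusters, of the average unweighted local
#' clustering coefficient of each cluster's induced subgraph; clusters of
#' size < 3 contribute 0. Ranges over `[0, 1]`; 1 means every cluster is a
#' clique-like module.
#'
#' @param graph The network that was clustered.
#' @param clustering An `mcl_clustering` object or a named membership
#'   vector covering the graph's nodes.
#' @return A number in `[0, 1]`.
#' @export
icc_homogeneity <- function(graph, clustering) {
  membership <- if (inherits(clustering, "mcl_clustering"))
    clustering$membership else clustering
  ids <- vertex_ids(graph)
  if (!all(ids %in% names(membership)))
    stop("clustering does not cover all graph nodes")
  total <- 0
  for (k in unique(membership)) {
    members <- names(membership)[membership == k]
    if (length(members) < 3) next
    sub <- igraph::induced_subgraph(graph, match(members, ids))
    cc <- igraph::transitivity(sub, type = "localundirected", isolates = "zero")
    total <- total + length(members) * mean(cc)
  }
  total / length(ids)
}

#' Sweep the MCL inflation parameter and keep the most homogeneous result
#'
#' Runs MCL at each inflation value, scores each clustering by
#' [icc_homogeneity()], and returns the argmax (ties broken towards the
#' lowest inflation) together with the full sweep table.
#'
#' @param graph An igraph network.
#' @param inflations Inflation grid; default 1.2 to 5.0 in steps of 0.2.
#' @param params Base [mcl_params()]; its inflation field is overridden.
#' @return List with `best` (an `mcl_clustering`) and `table` (data.frame
#'   with `inflation`, `n_clusters`, `homogeneity`, `converged`,
#'   `iterations`).
#' @export
inflation_sweep <- function(graph, inflations = seq(1.2, 5.0, by = 0.2),
                            params = mcl_params()) {
  if (length(inflations) < 1) stop("need at least one inflation value")
  runs <- lapply(inflations, function(i) {
    p <- params
    p$inflation <- i
    run_mcl(graph, p)
  })
  tab <- data.frame(inflation = inflations,
                    n_clusters = vapply(runs, `[[`, integer(1), "n_clusters"),
                    homogeneity = vapply(runs, `[[`, numeric(1), "homogeneity"),
                    converged = vapply(runs, `[[`, logical(1), "converged"),
                    iterations = vapply(runs, `[[`, integer(1), "iterations"))
  if (!any(tab$converged))
    warning("no inflation value converged; returning best-effort result")
  best <- runs[[which.max(tab$homogeneity)]]  # which.max: lowest inflation on ties
  list(best = best, table = tab)
}

#' @export
print.mcl_clustering <- function(x, ...) {
  cat("MCL clustering: ", x$n_clusters, " cluster(s), inflation ",
      x$inflation, ", homogeneity ", round(x$homogeneity, 4),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  invisible(x)
}

#' Write a clustering as a two-column TSV (node, cluster)
#'
#' @param clustering An `mcl_clustering` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_clustering <- function(clustering, path) {
  df <- data.frame(node = names(clustering$membership),
                   cluster = unname(clustering$membership))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
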