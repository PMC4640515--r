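# Independent oracles, kept deliberately naive and separate from the
# package's own code paths.

# Hypergeometric upper tail by explicit subset enumeration: successes are
# elements 1..a of 1..N; draw all C(N, b) subsets of size b and count how
# often the overlap reaches c.
enum_hyper_tail <- function(a, b, c, N) {
  if (b == 0) return(if (c == 0) 1 else 0)
  subsets <- utils::combn(N, b)
  overlaps <- colSums(subsets <= a)
  mean(overlaps >= c)
}

# Betweenness by all-pairs shortest-path counting: Floyd-Warshall
# distances, then sigma[s,t] via dynamic programming over nodes ordered by
# distance from s; through-counts use sigma[s,v] * sigma[v,t].
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  D <- ifelse(adj > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  # sigma[s, t] = number of distinct shortest s-t paths
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(D[s, ])
    for (t in ord) {
      if (t == s || !is.finite(D[s, t])) next
      preds <- which(adj[, t] > 0 & D[s, ] == D[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t]) || sigma[s, t] == 0) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
  }
  bc
}

# A second, deliberately simple MCL: no pruning, explicit loops for
# normalisation, clusters read as connected components of the nonzero
# pattern of the limit matrix.
naive_mcl <- function(adj, inflation, self_loop = "max", iters = 200) {
  n <- nrow(adj)
  A <- adj
  diag(A) <- 0
  for (v in seq_len(n)) {
    mx <- max(A[, v])
    A[v, v] <- if (self_loop == "max" && mx > 0) mx else 1
  }
  M <- A
  for (v in seq_len(n)) M[, v] <- M[, v] / sum(M[, v])
  for (it in seq_len(iters)) {
    prev <- M
    M <- M %*% M
    M <- M^inflation
    for (v in seq_len(n)) M[, v] <- M[, v] / sum(M[, v])
    if (max(abs(M - prev)) < 1e-10) break
  }
  pattern <- (M > 1e-6) | t(M > 1e-6)
  comp <- integer(n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0) next
    cur <- cur + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (comp[u] > 0) next
      comp[u] <- cur
      queue <- c(queue, which(pattern[u, ] & comp == 0))
    }
  }
  comp
}

# Partition agreement helpers -------------------------------------------

ari <- function(a, b) {
  skip_if_not_installed("mclust")
  mclust::adjustedRandIndex(a, b)
}

same_partition <- function(a, b) {
  # identical up to label renaming
  all(tapply(b, a, function(v) length(unique(v))) == 1) &&
    all(tapply(a, b, function(v) length(unique(v))) == 1)
}

# Small fixture builders -------------------------------------------------

# Two 3-cliques joined by a single bridge edge, all weights 1.
bridged_cliques_graph <- function() {
  edges <- rbind(c("a1", "a2"), c("a1", "a3"), c("a2", "a3"),
                 c("b1", "b2"), c("b1", "b3"), c("b2", "b3"),
                 c("a1", "b1"))
  igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2], weight = 1),
    directed = FALSE)
}

random_graph <- function(n, p) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  adj
}

graph_from_adj <- function(adj) {
  dimnames(adj) <- list(sprintf("n%02d", seq_len(nrow(adj))),
                        sprintf("n%02d", seq_len(nrow(adj))))
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}
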