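# The hypergeometric gene-sharing ('Sig') network.
#
# For two genomes with a and b families out of a universe of N, sharing c,
# the hypergeometric upper tail P(X >= c) measures how surprising the
# overlap is; the Sig score is the Bonferroni-style -log10 of that p-value
# multiplied by the number of pairwise comparisons, floored at zero. Genome
# pairs with Sig above a threshold (default 1) become weighted edges.

# log10 of the upper-tail hypergeometric probability, summed in log space
# from the largest term downward.
hypergeom_log10p <- function(a, b, c, N) {
  if (N < 1 || a < 0 || b < 0 || a > N || b > N || c < 0 || c > min(a, b))
    stop("hypergeometric bounds violated: a=", a, " b=", b, " c=", c, " N=", N)
  i <- c:min(a, b)
  lt <- lchoose(a, i) + lchoose(N - a, b - i) - lchoose(N, b)
  logsumexp(lt[order(lt, decreasing = TRUE)]) / log(10)
}

#' Hypergeometric upper-tail probability of a shared-family count
#'
#' Probability that two genomes with repertoire sizes `a` and `b`, drawn
#' from a universe of `N` families, share at least `c` families:
#' `sum_{i=c}^{min(a,b)} C(a,i) C(N-a,b-i) / C(N,b)`. Computed in log space
#' for stability; symmetric in `a` and `b`.
#'
#' @param a,b Family repertoire sizes of the two genomes (`<= N`).
#' @param c Observed shared-family count, `0 <= c <= min(a, b)`.
#' @param N Total number of families in the universe.
#' @param log10.p If `TRUE`, return log10 of the probability (exact even
#'   when the probability underflows double precision).
#' @return The tail probability in `(0, 1]`, or its log10.
#' @export
hypergeom_pvalue <- function(a, b, c, N, log10.p = FALSE) {
  lp <- hypergeom_log10p(a, b, c, N)
  if (log10.p) lp else min(1, 10^lp)
}

#' Sig score of a genome pair
#'
#' `Sig = max(0, -log10(p * T))` where `p` is the hypergeometric tail
#' probability and `T` the total number of pairwise comparisons. A zero
#' p-value (underflow) is capped at `sig_max` with a warning.
#'
#' @param p Tail probability in `(0, 1]` (0 tolerated, capped).
#' @param T Number of pairwise comparisons, `>= 1`.
#' @param sig_max Cap applied when `p` underflows to 0.
#' @return Non-negative Sig score (vectorised over `p`).
#' @export
sig_score <- function(p, T, sig_max = 300) {
  if (any(p < 0) || any(p > 1)) stop("p must lie in [0, 1]")
  if (T < 1) stop("T must be >= 1")
  out <- pmax(0, -(log10(p) + log10(T)))
  if (any(p == 0)) {
    warning("p-value underflow: Sig capped at ", sig_max)
    out[p == 0] <- sig_max
  }
  pmin(out, sig_max)
}

#' Build the weighted gene-sharing network from a profile matrix
#'
#' Every unordered genome pair is scored: `c` = shared families, `a`, `b` =
#' repertoire sizes (row sums), `N` = number of profile columns, and by
#' default `T = n(n-1)/2` comparisons among the `n` genomes analysed. Pairs
#' with `Sig > sig_threshold` (strict) become weighted undirected edges; all
#' genomes appear as nodes, connected or not.
#'
#' @param profile Binary genome x family matrix (>= 2 rows).
#' @param sig_threshold Strict edge-inclusion threshold on Sig (default 1).
#' @param n_comparisons Override for the comparison count `T`; defaults to
#'   `n(n-1)/2` over the analysed genomes.
#' @param sig_max Cap for underflowing p-values.
#' @return An [igraph][igraph::graph] object with edge attribute `weight`
#'   (the Sig score) and graph attributes `sig_threshold`, `n_families`,
#'   `n_comparisons`.
#' @export
build_network <- function(profile, sig_threshold = 1, n_comparisons = NULL,
                          sig_max = 300) {
  stopifnot(is.matrix(profile), nrow(profile) >= 2)
  profile <- (profile > 0) + 0L
  n <- nrow(profile)
  N <- ncol(profile)
  T_used <- n_comparisons %||% (n * (n - 1) / 2)
  shared <- tcrossprod(profile)
  sizes <- rowSums(profile)
  src <- character(0); dst <- character(0); w <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cc <- shared[i, j]
      if (cc == 0) next
      lp <- hypergeom_log10p(sizes[i], sizes[j], cc, N)
      sig <- min(max(0, -(lp + log10(T_used))), sig_max)
      if (sig > sig_threshold) {
        src <- c(src, rownames(profile)[i])
        dst <- c(dst, rownames(profile)[j])
        w <- c(w, sig)
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = src, to = dst, weight = w),
    directed = FALSE,
    vertices = data.frame(name = rownames(profile)))
  g <- igraph::set_graph_attr(g, "sig_threshold", sig_threshold)
  g <- igraph::set_graph_attr(g, "n_families", N)
  g <- igraph::set_graph_attr(g, "n_comparisons", T_used)
  g
}

#' Export a Sig network to Cytoscape-readable formats
#'
#' Supported formats: `"edge_tsv"` (`source`, `target`, `sig` to 6
#' decimals; lossless round-trip via [import_graph()]), `"sif"` (simple
#' interaction format, relation `sig`), and `"graphml"`.
#'
#' @param graph An igraph network (edge weights in attribute `weight`).
#' @param path Output path.
#' @param format One of `"edge_tsv"`, `"sif"`, `"graphml"`.
#' @return Invisibly, `path`.
#' @export
export_graph <- function(graph, path, format = "edge_tsv") {
  if (!format %in% c("edge_tsv", "sif", "graphml"))
    stop("unknown format '", format,
         "'; supported formats: edge_tsv, sif, graphml")
  el <- igraph::as_edgelist(graph)
  w <- igraph::E(graph)$weight %||% rep(1, nrow(el))
  if (format == "edge_tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("source\ttarget\tsig", con)
    if (nrow(el))
      writeLines(sprintf("%s\t%s\t%.6f", el[, 1], el[, 2], w), con)
  } else if (format == "sif") {
    lines <- if (nrow(el)) sprintf("%s sig %s", el[, 1], el[, 2]) else character(0)
    # isolated nodes appear as bare node lines, per SIF convention
    iso <- setdiff(vertex_ids(graph), unique(c(el)))
    writeLines(c(lines, iso), path)
  } else {
    igraph::write_graph(graph, path, format = "graphml")
  }
  invisible(path)
}

#' Import a Sig network written by [export_graph()]
#'
#' @param path Input path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @return An igraph object with edge attribute `weight`.
#' @export
import_graph <- function(path, format = "edge_tsv") {
  if (format == "edge_tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = c("character", "character", "numeric"))
    g <- igraph::graph_from_data_frame(
      data.frame(from = df$source, to = df$target, weight = df$sig),
      directed = FALSE)
    g
  } else if (format == "graphml") {
    igraph::read_graph(path, format = "graphml")
  } else {
    stop("unknown format '", format, "'; supported formats: edge_tsv, graphml")
  }
}
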