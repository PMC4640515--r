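# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable log-sum-exp of a vector of log-scale terms.
logsumexp <- function(lx) {
  lx <- lx[is.finite(lx) | lx == -Inf]
  m <- max(lx)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lx - m)))
}

# The 20 standard amino-acid one-letter codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Replace non-standard residues with 'X', warning once per call.
sanitize_protein <- function(seqs) {
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
  if (any(bad)) {
    warning(sum(bad), " sequence(s) contain non-standard residues; mapped to 'X'")
    seqs[bad] <- gsub("[^ACDEFGHIKLMNPQRSTVWYX]", "X", seqs[bad])
  }
  seqs
}

# Vertex names of an igraph, synthesising "v<i>" labels when absent.
vertex_ids <- function(graph) {
  nm <- igraph::V(graph)$name
  if (is.null(nm)) as.character(seq_len(igraph::vcount(graph))) else nm
}
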