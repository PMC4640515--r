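# Pairwise comparative genomics: local protein alignment, reciprocal best
# hits, per-genome-pair average identity, and small genome utilities
# (GC content, direct terminal repeat detection).

.pkg_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_cache$BLOSUM62
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gap costs
#' (opening 11, extension 1 per residue — the standard protein-search
#' defaults). Identity is computed over alignment columns including gaps.
#' When no positive-scoring local alignment exists the empty alignment is
#' returned with score 0.
#'
#' @param seq_a,seq_b Non-empty amino-acid sequences (single strings).
#' @param gap_open,gap_extend Affine gap costs.
#' @return List with `score`, `identity` (percent), `alignment_length`
#'   (columns including gaps), `query_span` and `subject_span`
#'   (`c(start, end)`, `NA` for the empty alignment).
#' @export
align_local <- function(seq_a, seq_b, gap_open = 11, gap_extend = 1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  seq_a <- sanitize_protein(toupper(seq_a))
  seq_b <- sanitize_protein(toupper(seq_b))
  al <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "local",
                                      substitutionMatrix = blosum62(),
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  s <- Biostrings::score(al)
  len <- Biostrings::nchar(al)
  if (s <= 0 || len == 0)
    return(list(score = 0, identity = 0, alignment_length = 0L,
                query_span = c(NA_integer_, NA_integer_),
                subject_span = c(NA_integer_, NA_integer_)))
  pr <- Biostrings::pattern(al)
  sr <- Biostrings::subject(al)
  list(score = s,
       identity = 100 * Biostrings::nmatch(al) / len,
       alignment_length = as.integer(len),
       query_span = c(Biostrings::start(pr), Biostrings::end(pr)),
       subject_span = c(Biostrings::start(sr), Biostrings::end(sr)))
}

#' Reciprocal best hits between two proteomes
#'
#' Every cross pair is aligned locally; a pair (a, b) is kept iff b is a's
#' best-scoring hit in B and a is b's best in A (ties broken towards the
#' lexicographically smaller id), giving a one-to-one ortholog pairing.
#'
#' @param proteome_a,proteome_b Named character vectors of protein
#'   sequences (non-empty).
#' @param min_identity Minimum percent identity for a hit to count.
#' @param min_score Minimum alignment score for a hit to count.
#' @return Data.frame with columns `orf_a`, `orf_b`, `identity`, `score`,
#'   `aln_len` (possibly zero rows).
#' @export
rbh_pairs <- function(proteome_a, proteome_b, min_identity = 0, min_score = 1) {
  if (!length(proteome_a) || !length(proteome_b))
    stop("both proteomes must be non-empty")
  na <- names(proteome_a); nb <- names(proteome_b)
  hits <- expand.grid(a = seq_along(proteome_a), b = seq_along(proteome_b))
  res <- lapply(seq_len(nrow(hits)), function(r) {
    al <- align_local(proteome_a[[hits$a[r]]], proteome_b[[hits$b[r]]])
    c(score = al$score, identity = al$identity, aln_len = al$alignment_length)
  })
  res <- do.call(rbind, res)
  df <- data.frame(orf_a = na[hits$a], orf_b = nb[hits$b],
                   identity = res[, "identity"], score = res[, "score"],
                   aln_len = as.integer(res[, "aln_len"]),
                   stringsAsFactors = FALSE)
  df <- df[df$score >= min_score & df$identity >= min_identity, , drop = FALSE]
  if (!nrow(df)) return(df)

  best_of <- function(d, by, other) {
    ord <- order(d[[by]], -d$score, d[[other]])
    d <- d[ord, , drop = FALSE]
    d[!duplicated(d[[by]]), , drop = FALSE]
  }
  best_a <- best_of(df, "orf_a", "orf_b")  # each a's best b
  best_b <- best_of(df, "orf_b", "orf_a")  # each b's best a
  key_a <- paste(best_a$orf_a, best_a$orf_b, sep = "\r")
  key_b <- paste(best_b$orf_a, best_b$orf_b, sep = "\r")
  out <- best_a[key_a %in% key_b, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise genome similarity from reciprocal-best-hit ORF identities
#'
#' For every unordered genome pair, computes the RBH ORF pairing and the
#' unweighted mean (plus min/max) of the paired identities. Diagonal is
#' 100%; pairs with no RBH pair report mean 0 with `n_pairs` 0.
#'
#' @param proteomes Named list of named character vectors (>= 2 genomes).
#' @param ... Passed to [rbh_pairs()].
#' @return List of symmetric matrices `mean`, `min`, `max`, `n_pairs`,
#'   plus `pairs`: a named list of per-pair RBH tables (`"A|B"` keys).
#' @export
genome_similarity_matrix <- function(proteomes, ...) {
  if (length(proteomes) < 2) stop("need at least 2 proteomes")
  g <- names(proteomes)
  k <- length(g)
  tmpl <- matrix(0, k, k, dimnames = list(g, g))
  out <- list(mean = tmpl, min = tmpl, max = tmpl, n_pairs = tmpl,
              pairs = list())
  diag(out$mean) <- 100; diag(out$min) <- 100; diag(out$max) <- 100
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      rb <- rbh_pairs(proteomes[[i]], proteomes[[j]], ...)
      out$pairs[[paste(g[i], g[j], sep = "|")]] <- rb
      np <- nrow(rb)
      out$n_pairs[i, j] <- out$n_pairs[j, i] <- np
      if (np) {
        out$mean[i, j] <- out$mean[j, i] <- mean(rb$identity)
        out$min[i, j] <- out$min[j, i] <- min(rb$identity)
        out$max[i, j] <- out$max[j, i] <- max(rb$identity)
      }
    }
  }
  out
}

#' GC content of a DNA sequence
#'
#' `100 (G + C) / (A + C + G + T)`, case-insensitive; ambiguity codes are
#' excluded from both numerator and denominator. Reported to 2 decimals.
#'
#' @param seq Non-empty DNA sequence (single string).
#' @return Percent GC, rounded to 2 decimals.
#' @export
gc_content <- function(seq) {
  if (!nzchar(seq)) stop("sequence must be non-empty")
  s <- strsplit(toupper(seq), "")[[1]]
  gc <- sum(s %in% c("G", "C"))
  at <- sum(s %in% c("A", "T"))
  if (gc + at == 0) stop("sequence has no unambiguous bases")
  round(100 * gc / (gc + at), 2)
}

#' Detect an exact direct terminal repeat
#'
#' Returns the largest `L` with `min_len <= L <= floor(len/2)` such that
#' the first `L` bases equal the last `L` bases exactly, or 0 if none.
#' Implemented via the KMP border (prefix-function) chain, so detection is
#' exact and linear in the sequence length.
#'
#' @param seq DNA sequence of length at least `2 * min_len`.
#' @param min_len Minimum repeat length to report (default 20).
#' @return Integer repeat length (0 when absent).
#' @export
detect_dtr <- function(seq, min_len = 20L) {
  n <- nchar(seq)
  if (n < 2 * min_len) stop("sequence shorter than 2 * min_len")
  x <- utf8ToInt(seq)
  # KMP prefix function: fail[i] = length of the longest proper border of
  # the prefix of length i
  fail <- integer(n)
  k <- 0L
  for (i in 2:n) {
    while (k > 0L && x[k + 1L] != x[i]) k <- fail[k]
    if (x[k + 1L] == x[i]) k <- k + 1L
    fail[i] <- k
  }
  # walk the border chain of the full string; the largest border <= n/2
  # that meets min_len is the DTR
  b <- fail[n]
  half <- n %/% 2L
  while (b > 0L) {
    if (b <= half && b >= min_len) return(as.integer(b))
    b <- fail[b]
  }
  0L
}

#' Translate ORF coordinates on a genome to proteins
#'
#' Extracts each feature (1-based inclusive coordinates, strand `+`/`-`),
#' translates it with the standard genetic code, and strips one trailing
#' stop. An internal stop codon is an error naming the feature.
#'
#' @param genome DNA sequence (single string).
#' @param coords Data.frame with columns `id`, `start`, `end`, `strand`.
#' @return Named character vector of protein sequences.
#' @export
translate_orfs <- function(genome, coords) {
  dna <- Biostrings::DNAString(genome)
  out <- vapply(seq_len(nrow(coords)), function(r) {
    sub <- Biostrings::subseq(dna, coords$start[r], coords$end[r])
    if (coords$strand[r] == "-") sub <- Biostrings::reverseComplement(sub)
    aa <- as.character(Biostrings::translate(sub, if.fuzzy.codon = "X"))
    aa <- sub("\\*$", "", aa)
    if (grepl("\\*", aa))
      stop("internal stop codon in feature ", coords$id[r])
    aa
  }, character(1))
  setNames(out, coords$id)
}
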