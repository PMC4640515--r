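# Protein family assignment and the genome x family profile matrix.
#
# Families come from pairwise similarity evidence: either an externally
# computed BLAST tabular file or the built-in scorer. Proteins hitting a
# reference family map adopt that family (best qualifying hit); the rest are
# clustered de novo by single linkage (connected components of the
# sub-threshold-evalue similarity graph); proteins with no qualifying edge
# become singleton families, mirroring "uncharacterized" families.

BLAST_COLS <- c("query_id", "subject_id", "percent_identity", "alignment_length",
                "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
                "evalue", "bitscore")

#' Parse a 12-column BLAST tabular file into similarity edges
#'
#' Expects the classic `-outfmt 6` layout (query, subject, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore),
#' tab-separated. Self-hits (query == subject) are dropped.
#'
#' @param path Path to the tabular file.
#' @return A data.frame of edges with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `evalue`, `bitscore`.
#' @export
parse_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty BLAST tabular file: ", path)
    return(data.frame(query_id = character(0), subject_id = character(0),
                      percent_identity = numeric(0), alignment_length = integer(0),
                      evalue = numeric(0), bitscore = numeric(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1L]
    stop("malformed BLAST tabular row at line ", bad, ": expected 12 columns, got ",
         nf[bad])
  }
  m <- do.call(rbind, parts)
  edges <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                      percent_identity = as.numeric(m[, 3]),
                      alignment_length = as.integer(m[, 4]),
                      evalue = as.numeric(m[, 11]),
                      bitscore = as.numeric(m[, 12]),
                      stringsAsFactors = FALSE)
  bad_num <- which(is.na(edges$percent_identity) | is.na(edges$evalue))
  if (length(bad_num))
    stop("malformed numeric field at line ", bad_num[1L])
  edges[edges$query_id != edges$subject_id, , drop = FALSE]
}

# Karlin-Altschul parameters for the built-in scorer: gapped BLOSUM62
# defaults. Surrogate e-value E = K * m * n * exp(-lambda * S).
KA_K <- 0.041
KA_LAMBDA <- 0.267

#' Score all protein pairs with the built-in aligner
#'
#' A BLAST-free stand-in for pairwise similarity search: every unordered
#' pair of sequences sharing at least one exact 4-mer is aligned locally
#' (BLOSUM62, affine gaps 11/1, see [align_local()]) and reported with a
#' surrogate Karlin-Altschul e-value `E = K m n exp(-lambda S)` using the
#' gapped BLOSUM62 constants K = 0.041, lambda = 0.267, where m and n are
#' the sequence lengths and S the raw alignment score.
#'
#' @param seqs Named character vector of amino-acid sequences (>= 2).
#' @param k Exact k-mer seed length for the pair prefilter.
#' @return A data.frame of edges in the same shape as [parse_blast_tab()]
#'   output, one row per qualifying unordered pair.
#' @export
score_pairs <- function(seqs, k = 4L) {
  if (length(seqs) < 2L) stop("score_pairs needs at least 2 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  seqs <- sanitize_protein(toupper(seqs))

  kmers <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  })
  # invert: k-mer -> sequence indices, then collect co-occurring pairs
  idx <- rep(seq_along(seqs), lengths(kmers))
  by_kmer <- split(idx, unlist(kmers))
  pairs <- unique(do.call(rbind, lapply(by_kmer, function(v) {
    if (length(v) < 2L) return(NULL)
    t(utils::combn(sort(v), 2L))
  })))
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(data.frame(query_id = character(0), subject_id = character(0),
                      percent_identity = numeric(0), alignment_length = integer(0),
                      evalue = numeric(0), bitscore = numeric(0)))

  rows <- apply(pairs, 1L, function(pq) {
    i <- pq[1]; j <- pq[2]
    al <- align_local(seqs[[i]], seqs[[j]])
    if (al$score <= 0) return(NULL)
    mn <- as.numeric(nchar(seqs[[i]])) * nchar(seqs[[j]])
    log_e <- log(KA_K) + log(mn) - KA_LAMBDA * al$score
    data.frame(query_id = names(seqs)[i], subject_id = names(seqs)[j],
               percent_identity = al$identity,
               alignment_length = al$alignment_length,
               evalue = exp(log_e),
               bitscore = (KA_LAMBDA * al$score - log(KA_K)) / log(2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(query_id = character(0), subject_id = character(0),
                      percent_identity = numeric(0), alignment_length = integer(0),
                      evalue = numeric(0), bitscore = numeric(0))
  rownames(out) <- NULL
  out
}

#' Assign proteins to families from similarity edges
#'
#' Proteins whose best qualifying hit (evalue below threshold; ties broken
#' by higher bitscore, then lexicographic subject id) lands on a protein in
#' `reference_map` adopt that reference family. The remaining proteins are
#' clustered by single linkage: connected components of the graph of
#' qualifying edges become de novo families, and proteins with no
#' qualifying edge become singletons.
#'
#' @param edges Edge data.frame ([parse_blast_tab()] / [score_pairs()]
#'   shape); treated as undirected.
#' @param evalue_threshold Qualifying-edge cutoff (strict `<`), default
#'   `1e-4`.
#' @param reference_map Optional named character vector mapping protein ids
#'   (reference database members) to reference family ids.
#' @param proteins Optional character vector naming the full protein
#'   universe; defaults to the ids seen in `edges`. Proteins absent from all
#'   edges become singleton families.
#' @return A data.frame with columns `protein_id`, `family_id`,
#'   `provenance` (`"reference"` or `"de novo"`), carrying the family size
#'   table as attribute `"family_sizes"`.
#' @export
build_families <- function(edges, evalue_threshold = 1e-4,
                           reference_map = NULL, proteins = NULL) {
  if (evalue_threshold <= 0) stop("evalue_threshold must be > 0")
  # the protein universe: as supplied, or everything the edges mention
  # (reference-database subjects are part of the universe only if listed)
  proteins <- if (is.null(proteins))
    sort(unique(c(edges$query_id, edges$subject_id)))
  else sort(unique(proteins))
  qual <- edges[edges$evalue < evalue_threshold, , drop = FALSE]

  assignment <- setNames(rep(NA_character_, length(proteins)), proteins)
  provenance <- setNames(rep("de novo", length(proteins)), proteins)

  if (!is.null(reference_map) && nrow(qual) > 0L) {
    # hits in both directions: a query can match a reference subject or
    # vice versa
    hits <- rbind(
      data.frame(protein = qual$query_id, ref = qual$subject_id,
                 evalue = qual$evalue, bitscore = qual$bitscore),
      data.frame(protein = qual$subject_id, ref = qual$query_id,
                 evalue = qual$evalue, bitscore = qual$bitscore)
    )
    hits <- hits[hits$ref %in% names(reference_map), , drop = FALSE]
    if (nrow(hits)) {
      ord <- order(hits$protein, hits$evalue, -hits$bitscore, hits$ref)
      hits <- hits[ord, , drop = FALSE]
      best <- hits[!duplicated(hits$protein), , drop = FALSE]
      keep <- best$protein %in% proteins & !(best$protein %in% names(reference_map))
      best <- best[keep, , drop = FALSE]
      assignment[best$protein] <- unname(reference_map[best$ref])
      provenance[best$protein] <- "reference"
    }
  }

  # de novo single linkage over the unassigned remainder
  open <- names(assignment)[is.na(assignment)]
  sub <- qual[qual$query_id %in% open & qual$subject_id %in% open, , drop = FALSE]
  comp_of <- setNames(rep(NA_integer_, length(open)), open)
  if (nrow(sub)) {
    g <- igraph::graph_from_data_frame(
      sub[, c("query_id", "subject_id")], directed = FALSE,
      vertices = data.frame(name = open))
    comp_of[] <- igraph::components(g)$membership[open]
  } else if (length(open)) {
    comp_of[] <- seq_along(open)
  }
  if (length(open)) {
    # deterministic dense ids: order components by their smallest member
    first_member <- vapply(split(names(comp_of), comp_of),
                           function(v) min(v), character(1))
    rank <- order(first_member)
    new_id <- setNames(seq_along(rank), names(first_member)[rank])
    assignment[open] <- sprintf("fam.%04d", new_id[as.character(comp_of[open])])
  }

  out <- data.frame(protein_id = names(assignment),
                    family_id = unname(assignment),
                    provenance = unname(provenance),
                    stringsAsFactors = FALSE)
  attr(out, "family_sizes") <- table(out$family_id)
  out
}

#' Build the binary genome x family profile matrix
#'
#' Entry (g, f) is 1 iff genome g carries at least one protein of family f;
#' multi-copy families collapse to presence/absence.
#'
#' @param assignment Data.frame from [build_families()] (or any with
#'   `protein_id`, `family_id`).
#' @param genome_of Named character vector mapping protein id to genome id.
#' @return Integer 0/1 matrix, genomes as rows, families as columns.
#' @export
build_profile <- function(assignment, genome_of) {
  missing <- setdiff(assignment$protein_id, names(genome_of))
  if (length(missing))
    stop("no genome known for protein(s): ", paste(utils::head(missing, 3), collapse = ", "))
  genomes <- sort(unique(unname(genome_of[assignment$protein_id])))
  families <- sort(unique(assignment$family_id))
  m <- matrix(0L, length(genomes), length(families),
              dimnames = list(genomes, families))
  m[cbind(unname(genome_of[assignment$protein_id]), assignment$family_id)] <- 1L
  m
}

#' Profile matrix directly from family-annotated proteomes
#'
#' Convenience for simulated communities where family content is known
#' without sequence-level evidence.
#'
#' @param proteomes Named list as produced by [generate_community()].
#' @return Integer 0/1 matrix, genomes as rows, families as columns.
#' @export
profile_from_proteomes <- function(proteomes) {
  genomes <- names(proteomes)
  families <- sort(unique(unlist(lapply(proteomes, `[[`, "families"))))
  m <- matrix(0L, length(genomes), length(families),
              dimnames = list(genomes, families))
  for (g in genomes) m[g, unique(proteomes[[g]]$families)] <- 1L
  m
}

#' Read/write a profile matrix as TSV
#'
#' @param profile Binary matrix from [build_profile()].
#' @param path File path.
#' @return `write_profile` invisibly returns `path`; `read_profile` returns
#'   the matrix.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}
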