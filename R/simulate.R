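# Synthetic phage communities with planted ground truth.
#
# The generator emulates the structure a gene-sharing analysis exploits:
# clusters of genomes that share a conserved "core" of protein families,
# cluster-specific accessory families carried sporadically, background
# singleton families private to one genome, and mosaic genomes whose core
# content is drawn from several clusters at known proportions (the
# bridge-node phenotype of highly chimeric phages).

#' Configuration for a synthetic phage community
#'
#' @param n_clusters Number of planted genome clusters.
#' @param genomes_per_cluster Non-mosaic genomes per cluster.
#' @param core_families_per_cluster Families carried by every member of a
#'   cluster.
#' @param accessory_families_per_cluster Cluster-specific families carried
#'   independently with probability `accessory_carry_prob`.
#' @param accessory_carry_prob Per-genome carriage probability of each
#'   accessory family, in `[0, 1]`.
#' @param background_families_per_genome Singleton families unique to each
#'   genome (noise shared by nobody).
#' @param n_mosaic Number of mosaic genomes drawing core families from
#'   several clusters.
#' @param mosaic_mixture Numeric vector of length `n_clusters` summing to 1:
#'   the proportions at which each mosaic genome samples core-family slots
#'   from each cluster. Defaults to uniform when `n_mosaic > 0`.
#' @param seed Integer seed; the community is a deterministic function of the
#'   configuration including this seed.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_clusters,
                       genomes_per_cluster,
                       core_families_per_cluster,
                       accessory_families_per_cluster = 0L,
                       accessory_carry_prob = 0.5,
                       background_families_per_genome = 0L,
                       n_mosaic = 0L,
                       mosaic_mixture = NULL,
                       seed = 1L) {
  counts <- c(n_clusters = n_clusters,
              genomes_per_cluster = genomes_per_cluster,
              core_families_per_cluster = core_families_per_cluster,
              accessory_families_per_cluster = accessory_families_per_cluster,
              background_families_per_genome = background_families_per_genome,
              n_mosaic = n_mosaic)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("all counts must be non-negative integers")
  if (accessory_carry_prob < 0 || accessory_carry_prob > 1)
    stop("accessory_carry_prob must lie in [0, 1]")
  if (n_mosaic > 0) {
    if (is.null(mosaic_mixture))
      mosaic_mixture <- rep(1 / n_clusters, n_clusters)
    if (length(mosaic_mixture) != n_clusters)
      stop("mosaic_mixture must have one proportion per cluster (length ",
           n_clusters, "), got length ", length(mosaic_mixture))
    if (any(mosaic_mixture < 0) || abs(sum(mosaic_mixture) - 1) > 1e-9)
      stop("mosaic_mixture proportions must be non-negative and sum to 1")
  }
  structure(list(n_clusters = as.integer(n_clusters),
                 genomes_per_cluster = as.integer(genomes_per_cluster),
                 core_families_per_cluster = as.integer(core_families_per_cluster),
                 accessory_families_per_cluster = as.integer(accessory_families_per_cluster),
                 accessory_carry_prob = accessory_carry_prob,
                 background_families_per_genome = as.integer(background_families_per_genome),
                 n_mosaic = as.integer(n_mosaic),
                 mosaic_mixture = mosaic_mixture,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic phage community with known ground truth
#'
#' Each non-mosaic genome of cluster k carries all of k's core families,
#' each of k's accessory families independently with the configured carriage
#' probability, and its own private background families. Each mosaic genome
#' fills every core-family slot from a cluster drawn at the mixture
#' proportions, so its per-cluster core counts are multinomial.
#'
#' @param config A [sim_config()] object.
#' @return A list with components:
#'   \describe{
#'     \item{proteomes}{Named list; each element is a list with `genome_id`
#'       and `families` (character vector of family ids).}
#'     \item{truth}{Planted ground truth: `partition` (named character vector
#'       genome -> cluster id, mosaics labelled by their majority source
#'       cluster), `mosaic_ids`, and `family_origin` (named character vector
#'       family -> cluster id or `"background"`).}
#'   }
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$n_clusters
  if (k == 0L) {
    return(list(proteomes = list(),
                truth = list(partition = setNames(character(0), character(0)),
                             mosaic_ids = character(0),
                             family_origin = setNames(character(0), character(0)))))
  }
  with_seed(config$seed, {
    cluster_ids <- sprintf("C%d", seq_len(k))
    core <- lapply(seq_len(k), function(i)
      sprintf("C%d.core.%02d", i, seq_len(config$core_families_per_cluster)))
    acc <- lapply(seq_len(k), function(i)
      sprintf("C%d.acc.%02d", i, seq_len(config$accessory_families_per_cluster)))

    proteomes <- list()
    partition <- character(0)
    bg_counter <- 0L

    next_background <- function(n) {
      if (n == 0L) return(character(0))
      ids <- sprintf("bg.%06d", bg_counter + seq_len(n))
      bg_counter <<- bg_counter + n
      ids
    }

    for (i in seq_len(k)) {
      for (g in seq_len(config$genomes_per_cluster)) {
        gid <- sprintf("C%d.g%02d", i, g)
        carry <- if (length(acc[[i]]))
          acc[[i]][stats::runif(length(acc[[i]])) < config$accessory_carry_prob]
        else character(0)
        fams <- c(core[[i]], carry,
                  next_background(config$background_families_per_genome))
        proteomes[[gid]] <- list(genome_id = gid, families = fams)
        partition[gid] <- cluster_ids[i]
      }
    }

    mosaic_ids <- character(0)
    for (m in seq_len(config$n_mosaic)) {
      gid <- sprintf("M%02d", m)
      # one source cluster per core-family slot, at the mixture proportions
      src <- sample.int(k, config$core_families_per_cluster,
                        replace = TRUE, prob = config$mosaic_mixture)
      fams <- sprintf("C%d.core.%02d", src, seq_len(config$core_families_per_cluster))
      carry <- character(0)
      for (i in seq_len(k)) {
        if (length(acc[[i]])) {
          p <- config$mosaic_mixture[i] * config$accessory_carry_prob
          carry <- c(carry, acc[[i]][stats::runif(length(acc[[i]])) < p])
        }
      }
      fams <- c(fams, carry, next_background(config$background_families_per_genome))
      proteomes[[gid]] <- list(genome_id = gid, families = fams)
      counts <- tabulate(src, nbins = k)
      partition[gid] <- cluster_ids[which.max(counts)]
      mosaic_ids <- c(mosaic_ids, gid)
    }

    family_origin <- c(
      setNames(rep(cluster_ids, each = config$core_families_per_cluster),
               unlist(core)),
      setNames(rep(cluster_ids, each = config$accessory_families_per_cluster),
               unlist(acc)),
      setNames(rep("background", bg_counter),
               sprintf("bg.%06d", seq_len(bg_counter)))
    )

    list(proteomes = proteomes,
         truth = list(partition = partition,
                      mosaic_ids = mosaic_ids,
                      family_origin = family_origin))
  })
}

#' Generate protein sequences for a community's families
#'
#' One ancestor sequence is drawn per family (length uniform on 150-400
#' residues, uniform over the 20 standard amino acids); each family member is
#' the ancestor with point substitutions at rate `1 - target_identity`, each
#' substitution replacing the residue with a uniformly chosen *different*
#' residue. Each genome emits one protein per family it carries, with id
#' `"<genome>|<family>"`.
#'
#' Under this model a member's identity to the ancestor is exactly
#' `target_identity` in expectation, and two independent members of the same
#' family match at a site with probability `t^2 + (1-t)^2/19`.
#'
#' @param proteomes Named list as produced by [generate_community()].
#' @param target_identity Expected member-to-ancestor identity, in
#'   `[0.3, 1]`.
#' @param seed Integer seed.
#' @return A data.frame with columns `protein_id`, `genome_id`, `family_id`,
#'   `sequence` — the true family map plus sequences.
#' @export
generate_sequences <- function(proteomes, target_identity = 0.8, seed = 1L) {
  if (target_identity < 0.3 || target_identity > 1)
    stop("target_identity must lie in [0.3, 1]")
  fams <- sort(unique(unlist(lapply(proteomes, `[[`, "families"))))
  with_seed(seed, {
    ancestors <- lapply(fams, function(f) {
      len <- sample(150:400, 1L)
      sample(AA20, len, replace = TRUE)
    })
    names(ancestors) <- fams
    p_mut <- 1 - target_identity
    rows <- lapply(proteomes, function(pr) {
      seqs <- vapply(pr$families, function(f) {
        a <- ancestors[[f]]
        hit <- stats::runif(length(a)) < p_mut
        if (any(hit)) {
          # uniformly chosen *different* residue: shift within the alphabet
          idx <- match(a[hit], AA20)
          a[hit] <- AA20[((idx - 1L + sample.int(19L, sum(hit), replace = TRUE)) %% 20L) + 1L]
        }
        paste(a, collapse = "")
      }, character(1))
      data.frame(protein_id = paste0(pr$genome_id, "|", pr$families),
                 genome_id = pr$genome_id,
                 family_id = pr$families,
                 sequence = unname(seqs),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic phage genome with a planted direct terminal repeat
#'
#' Bases are drawn independently: G/C with probability `gc` (split evenly),
#' A/T otherwise; the first `dtr_length` bases are then copied onto the end
#' of the sequence, planting an exact direct terminal repeat.
#'
#' @param length Genome length in bp.
#' @param dtr_length Planted repeat length, at most `length / 2`.
#' @param gc Target GC fraction in (0, 1).
#' @param seed Integer seed.
#' @return A single character string of A/C/G/T.
#' @export
generate_genome <- function(length, dtr_length = 0L, gc = 0.5, seed = 1L) {
  if (dtr_length < 0 || dtr_length > length / 2)
    stop("dtr_length must lie in [0, length/2]")
  if (gc <= 0 || gc >= 1) stop("gc must lie strictly in (0, 1)")
  with_seed(seed, {
    is_gc <- stats::runif(length) < gc
    base <- ifelse(is_gc,
                   ifelse(stats::runif(length) < 0.5, "G", "C"),
                   ifelse(stats::runif(length) < 0.5, "A", "T"))
    if (dtr_length > 0)
      base[(length - dtr_length + 1L):length] <- base[seq_len(dtr_length)]
    paste(base, collapse = "")
  })
}

#' Write community ground truth as TSV files
#'
#' @param truth The `truth` component of [generate_community()].
#' @param genomes_path,families_path Output paths for the genome table
#'   (`genome_id`, `cluster_id`, `is_mosaic`) and the family table
#'   (`family_id`, `origin`).
#' @return Invisibly, the two paths.
#' @export
write_truth <- function(truth, genomes_path, families_path) {
  gt <- data.frame(genome_id = names(truth$partition),
                   cluster_id = unname(truth$partition),
                   is_mosaic = names(truth$partition) %in% truth$mosaic_ids)
  ft <- data.frame(family_id = names(truth$family_origin),
                   origin = unname(truth$family_origin))
  utils::write.table(gt, genomes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ft, families_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(genomes_path, families_path))
}

#' Write protein sequences as FASTA with `genome|protein` headers
#'
#' @param sequences Data.frame from [generate_sequences()].
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_protein_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences$sequence)
  names(set) <- sequences$protein_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
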