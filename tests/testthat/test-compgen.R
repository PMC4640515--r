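# Comparative genomics: local alignment, RBH pairing, genome similarity,
# GC content, direct terminal repeats.

test_that("local alignment: exact self-match, empty alignment, symmetry", {
  al <- align_local("ACDE", "ACDE")
  expect_equal(al$score, 24)           # BLOSUM62 diagonal 4 + 9 + 6 + 5
  expect_equal(al$identity, 100)
  expect_identical(al$alignment_length, 4L)

  none <- align_local("ACDE", "WWWW")
  expect_equal(none$score, 0)
  expect_identical(none$alignment_length, 0L)

  set.seed(3)
  a <- paste(sample(c("A","C","D","E","F","G","H","I","K","L"), 80, TRUE),
             collapse = "")
  b <- paste(sample(c("M","N","P","Q","R","S","T","V","W","Y"), 80, TRUE),
             collapse = "")
  expect_equal(align_local(a, b)$score, align_local(b, a)$score)
  expect_error(align_local("", "ACDE"), "non-empty")
})

test_that("self-alignment of any sequence scores the diagonal sum", {
  set.seed(21)
  aas <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")
  for (i in 1:5) {
    s <- paste(sample(aas, sample(30:120, 1), TRUE), collapse = "")
    al <- align_local(s, s)
    expect_equal(al$identity, 100)
    expect_identical(al$alignment_length, nchar(s))
  }
})

test_that("planted-identity pairs are recovered within the expected band", {
  com <- generate_community(sim_config(1, 2, 100, 0, 0, 0, 0, seed = 5))
  seqs <- generate_sequences(com$proteomes, 0.8, seed = 6)
  by_fam <- split(seqs$sequence, seqs$family_id)
  ids <- vapply(by_fam, function(v) align_local(v[1], v[2])$identity, numeric(1))
  expect_true(all(ids >= 55 & ids <= 95))
  expect_lt(abs(mean(ids) - 100 * (0.8^2 + 0.2^2 / 19)), 3)
})

test_that("reciprocal best hits are one-to-one and exclude duplicates", {
  set.seed(12)
  aas <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")
  mk <- function(n) paste(sample(aas, n, TRUE), collapse = "")
  mutate <- function(s, p) {
    v <- strsplit(s, "")[[1]]
    hit <- runif(length(v)) < p
    v[hit] <- sample(aas, sum(hit), TRUE)
    paste(v, collapse = "")
  }
  prots <- setNames(vapply(1:3, function(i) mk(200), character(1)),
                    c("o1", "o2", "o3"))
  ortho <- setNames(vapply(prots, mutate, character(1), p = 0.15),
                    c("p1", "p2", "p3"))

  # identical proteomes: each protein matches itself
  self <- rbh_pairs(prots, setNames(prots, names(prots)))
  expect_identical(nrow(self), 3L)
  expect_identical(self$orf_a, self$orf_b)
  expect_true(all(self$identity == 100))

  # one close and one unrelated candidate
  b <- c(y1 = mutate(prots[["o1"]], 0.1), y2 = mk(200))
  rb <- rbh_pairs(prots["o1"], b)
  expect_identical(rb$orf_b, "y1")

  # lineage-specific duplication: the extra copy is excluded by reciprocality
  dup <- c(ortho, p1b = mutate(prots[["o1"]], 0.16))
  rb2 <- rbh_pairs(prots, dup)
  expect_identical(nrow(rb2), 3L)
  expect_false("p1b" %in% rb2$orf_b)
  expect_identical(anyDuplicated(rb2$orf_a), 0L)
  expect_identical(anyDuplicated(rb2$orf_b), 0L)
})

test_that("genome similarity matrix recovers planted divergence", {
  set.seed(31)
  aas <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")
  mutate <- function(s, p) {
    v <- strsplit(s, "")[[1]]
    hit <- runif(length(v)) < p
    if (any(hit)) {
      idx <- match(v[hit], aas)
      v[hit] <- aas[((idx - 1 + sample(19, sum(hit), TRUE)) %% 20) + 1]
    }
    paste(v, collapse = "")
  }
  anc <- setNames(vapply(1:12, function(i)
    paste(sample(aas, 250, TRUE), collapse = ""), character(1)),
    sprintf("orf%02d", 1:12))
  gA <- anc
  gB <- setNames(vapply(anc, mutate, character(1), p = 0.2), names(anc))
  gC <- setNames(vapply(anc, mutate, character(1), p = 0.4), names(anc))
  sim <- genome_similarity_matrix(list(A = gA, B = gB, C = gC))

  # expected identities from the substitution model: A-B 80, A-C 60,
  # B-C 100 * (0.8 * 0.6 + 0.2 * 0.4 / 19) = 48.4
  expect_lt(abs(sim$mean["A", "B"] - 80), 5)
  expect_lt(abs(sim$mean["A", "C"] - 60), 5)
  expect_lt(abs(sim$mean["B", "C"] - 48.4), 5)
  expect_identical(sim$mean, t(sim$mean))
  expect_equal(unname(diag(sim$mean)), rep(100, 3))
  expect_true(all(sim$mean <= sim$max & sim$mean >= sim$min))
  expect_true(all(sim$n_pairs[upper.tri(sim$n_pairs)] == 12))
})

test_that("disjoint random proteomes yield no RBH pairs and mean 0", {
  set.seed(41)
  aas <- c("A","C","D","E","F","G","H","I","K","L")
  zas <- c("M","N","P","Q","R","S","T","V","W","Y")
  a <- setNames(vapply(1:3, function(i) paste(sample(aas, 60, TRUE), collapse = ""),
                       character(1)), paste0("a", 1:3))
  b <- setNames(vapply(1:3, function(i) paste(sample(zas, 60, TRUE), collapse = ""),
                       character(1)), paste0("b", 1:3))
  sim <- genome_similarity_matrix(list(A = a, B = b), min_score = 30)
  expect_identical(unname(sim$n_pairs["A", "B"]), 0)
  expect_identical(unname(sim$mean["A", "B"]), 0)
})

test_that("GC content follows the stated conventions", {
  expect_identical(gc_content("ATGC"), 50)
  expect_identical(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATGN"), 33.33)      # N excluded
  expect_identical(gc_content("atgc"), 50)     # case-insensitive
  expect_error(gc_content("NNNN"), "unambiguous")
  expect_error(gc_content(""), "non-empty")
})

test_that("direct terminal repeat detection is exact", {
  set.seed(17)
  mid <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  s <- paste0("ATGC", mid, "ATGC")
  expect_identical(detect_dtr(s, min_len = 4), 4L)

  g <- generate_genome(45403, 208, 0.4589, seed = 7)
  expect_identical(detect_dtr(g), 208L)

  # a single mismatch inside the repeat truncates the detection
  broken <- g
  substr(broken, 100, 100) <- if (substr(g, 100, 100) == "A") "C" else "A"
  expect_lt(detect_dtr(broken, min_len = 1), 100)

  plain <- generate_genome(1000, 0, 0.5, seed = 19)
  expect_identical(detect_dtr(plain), 0L)
  expect_error(detect_dtr("ACGT", min_len = 20), "shorter")
})

test_that("ORF translation honors strand and rejects internal stops", {
  # protein "MKW" forward, "MD" reverse
  genome <- paste0("ATGAAATGGTAA", "GG", "TTAGTCCAT")
  coords <- data.frame(id = c("f1", "r1"),
                       start = c(1, 15), end = c(12, 23),
                       strand = c("+", "-"))
  prots <- translate_orfs(genome, coords)
  expect_identical(unname(prots["f1"]), "MKW")   # trailing stop stripped
  expect_identical(unname(prots["r1"]), "MD")

  bad <- data.frame(id = "x", start = 1, end = 12, strand = "+")
  genome_bad <- "ATGTAATGGTAA"
  expect_error(translate_orfs(genome_bad, bad), "internal stop.*x")
})
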