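# Family assignment from similarity evidence and the profile matrix.

blast_row <- function(q, s, pid = 80, len = 100, ev = 1e-30, bits = 200) {
  paste(q, s, pid, len, 20, 0, 1, len, 1, len,
        format(ev, scientific = TRUE), bits, sep = "\t")
}

test_that("BLAST tabular parsing: fields, self-hits, malformed rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(blast_row("p1", "p2"),
               blast_row("p2", "p2"),
               blast_row("p2", "p3", ev = 1e-3)), path)
  edges <- parse_blast_tab(path)
  expect_identical(nrow(edges), 2L)           # self-hit dropped
  expect_identical(edges$query_id, c("p1", "p2"))
  expect_equal(edges$evalue, c(1e-30, 1e-3))
  expect_equal(edges$percent_identity, c(80, 80))

  writeLines(c(blast_row("p1", "p2"), "p1\tp2\tbroken"), path)
  expect_error(parse_blast_tab(path), "line 2")

  writeLines(character(0), path)
  expect_warning(empty <- parse_blast_tab(path), "empty")
  expect_identical(nrow(empty), 0L)
})

test_that("single-linkage families: transitivity, threshold, singletons", {
  ed <- function(q, s, ev) data.frame(query_id = q, subject_id = s,
                                      percent_identity = 90,
                                      alignment_length = 100L,
                                      evalue = ev, bitscore = 100)
  fam <- build_families(rbind(ed("a", "b", 1e-10), ed("b", "c", 1e-10)))
  expect_identical(length(unique(fam$family_id)), 1L)

  fam2 <- build_families(ed("a", "b", 1e-3), evalue_threshold = 1e-4)
  expect_identical(length(unique(fam2$family_id)), 2L)

  # proteins absent from all edges become singletons
  fam3 <- build_families(ed("a", "b", 1e-10), proteins = c("a", "b", "z"))
  expect_identical(sum(fam3$family_id == "fam.0002"), 1L)
  expect_identical(fam3$family_id[fam3$protein_id == "z"], "fam.0002")
  expect_identical(nrow(fam3), 3L)
  expect_true(all(fam3$provenance == "de novo"))
})

test_that("families are invariant under edge-order permutation", {
  set.seed(42)
  ids <- sprintf("p%02d", 1:12)
  ed <- data.frame(query_id = c("p01", "p02", "p04", "p05", "p08", "p10"),
                   subject_id = c("p02", "p03", "p05", "p06", "p09", "p11"),
                   percent_identity = 90, alignment_length = 100L,
                   evalue = 1e-9, bitscore = 100)
  base <- build_families(ed, proteins = ids)
  for (i in 1:5) {
    perm <- ed[sample(nrow(ed)), ]
    expect_identical(build_families(perm, proteins = ids), base,
                     ignore_attr = TRUE)
  }
})

test_that("reference-map adoption takes the best qualifying hit", {
  refs <- c(r1 = "vir:14", r2 = "f:v:81")
  ed <- data.frame(query_id = c("a", "a", "b"),
                   subject_id = c("r1", "r2", "r2"),
                   percent_identity = 90, alignment_length = 100L,
                   evalue = c(1e-20, 1e-10, 1e-3), bitscore = c(150, 90, 40))
  fam <- build_families(ed, reference_map = refs, proteins = c("a", "b"))
  got <- setNames(fam$family_id, fam$protein_id)
  expect_identical(unname(got["a"]), "vir:14")      # lower evalue wins
  expect_identical(fam$provenance[fam$protein_id == "a"], "reference")
  # b's only hit misses the 1e-4 cutoff -> de novo singleton
  expect_identical(fam$provenance[fam$protein_id == "b"], "de novo")

  # evalue tie -> higher bitscore wins
  tie <- data.frame(query_id = c("a", "a"), subject_id = c("r1", "r2"),
                    percent_identity = 90, alignment_length = 100L,
                    evalue = 1e-20, bitscore = c(50, 90))
  fam_tie <- build_families(tie, reference_map = refs, proteins = "a")
  expect_identical(fam_tie$family_id, "f:v:81")
})

test_that("profile matrix is binary presence/absence with exact shape", {
  asn <- data.frame(protein_id = c("x1", "x2", "x3"),
                    family_id = c("f1", "f1", "f2"))
  gmap <- c(x1 = "G1", x2 = "G1", x3 = "G1")
  prof <- build_profile(asn, gmap)
  expect_identical(dim(prof), c(1L, 2L))
  expect_true(all(prof == 1L))                      # multi-copy collapses

  asn2 <- data.frame(protein_id = c("a1", "a2", "b1", "b2"),
                     family_id = c("f1", "f2", "f1", "f3"))
  gmap2 <- c(a1 = "GA", a2 = "GA", b1 = "GB", b2 = "GB")
  prof2 <- build_profile(asn2, gmap2)
  expect_identical(rowSums(prof2), c(GA = 2, GB = 2))
  expect_identical(sum(colSums(prof2) == 2), 1L)

  expect_error(build_profile(asn2, gmap2[-1]), "no genome known")

  # duplicating a protein record leaves the matrix unchanged
  expect_identical(build_profile(rbind(asn2, asn2[1, ]), gmap2), prof2)
})

test_that("built-in scorer produces BLAST-like evalues", {
  set.seed(7)
  aas <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")
  s <- paste(sample(aas, 200, TRUE), collapse = "")
  edges <- score_pairs(c(x = s, y = s))
  expect_identical(nrow(edges), 1L)
  expect_lt(edges$evalue, 1e-50)
  expect_equal(edges$percent_identity, 100)

  # unrelated random pairs rarely reach the family threshold
  below <- vapply(1:100, function(i) {
    p <- paste(sample(aas, 200, TRUE), collapse = "")
    q <- paste(sample(aas, 200, TRUE), collapse = "")
    e <- score_pairs(c(a = p, b = q))
    nrow(e) > 0 && any(e$evalue < 1e-4)
  }, logical(1))
  expect_lte(sum(below), 5)

  expect_error(score_pairs(c(only = s)), "at least 2")
})

test_that("profile of a simulated community reflects the planted clusters", {
  com <- generate_community(sim_config(3, 10, 20, 10, 0.5, 3, 0, seed = 1))
  prof <- profile_from_proteomes(com$proteomes)
  part <- com$truth$partition[rownames(prof)]
  shared <- tcrossprod(prof)
  same <- outer(part, part, "==")
  diag(same) <- NA
  expect_true(all(shared[which(same)] >= 20))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, path)
  expect_identical(read_profile(path), prof)
})
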