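---
title: "Gene-sharing networks for phage classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-sharing networks for phage classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagenet)
```

## The problem

Bacteriophage genomes evolve under pervasive horizontal gene transfer, so a
single gene tree rarely reflects a phage's overall relationships, and strict
hierarchical taxonomy fits them poorly. A reticulate alternative treats each
genome as a node in a network whose edges measure *shared gene content*: two
phages are linked when they carry significantly more protein families in
common than chance would allow. Dense regions of this network correspond to
genus-like groups; nodes wired into several groups expose genomic mosaicism.
`phagenet` implements this analysis end to end — protein-family assignment,
significance-weighted network construction, Markov clustering with an
inflation sweep, per-node cluster membership, topology metrics, and pairwise
comparative genomics — together with a synthetic community generator that
provides planted ground truth for every stage.

## From proteins to families

Families are built from pairwise similarity evidence, either a 12-column
BLAST tabular file (`parse_blast_tab()`) or the built-in scorer
(`score_pairs()`), which seeds on exact 4-mers, aligns locally under
BLOSUM62 with affine gaps 11/1, and converts raw scores to surrogate
expectation values with the gapped Karlin–Altschul constants
($E = K m n e^{-\lambda S}$, $K = 0.041$, $\lambda = 0.267$). Proteins whose
best qualifying hit (E < 10⁻⁴) lands in a user-supplied reference family map
adopt that family — ties broken by higher bitscore, then lexicographic
subject id, so the assignment is deterministic. The remainder are clustered
de novo by single linkage: connected components of the qualifying-edge graph.
Single linkage is the minimal assumption consistent with "group everything
linked by a significant hit", and it is order-independent; its known failure
mode — chaining through a single spurious hit — is real and visible in our
own analysis runs (`analysis/02_build_families.R` reports one chance merge
of two independently drawn ancestor families). Multi-copy families collapse
to presence/absence because the downstream hypergeometric model needs sets,
not multisets.

## The Sig network

For genomes with $a$ and $b$ families out of a universe of $N$, sharing
$c$, the surprise of the overlap is the hypergeometric upper tail

$$P = \sum_{i=c}^{\min(a,b)} \frac{\binom{a}{i}\binom{N-a}{b-i}}{\binom{N}{b}},$$

and the edge weight is the Bonferroni-style score
$\mathrm{Sig} = \max(0, -\log_{10}(P \cdot T))$ with $T$ the number of
pairwise comparisons. Pairs with $\mathrm{Sig} > 1$ (strict) become edges.
Numerical choices:

* the tail is summed in log space from the largest term downward
  (`lchoose` + log-sum-exp), so it is exact to ~1e-15 relative error even
  when $P$ underflows doubles; `hypergeom_pvalue(..., log10.p = TRUE)`
  exposes the log-scale value directly;
* $N$ is the column count of the supplied profile matrix — the analysed
  universe, not some external database constant — and $T = n(n-1)/2$ over
  the analysed genomes, the smallest self-contained reading of "all
  pairwise comparisons". Both are recorded on the graph object and $T$ can
  be overridden (`n_comparisons`) when the network is meant to inherit a
  larger comparison universe;
* a $P$ that underflows to exactly 0 is capped at `sig_max` (default 300,
  i.e. $10^{-300}$, near the double floor) with a warning rather than
  propagating `Inf` weights.

A consequence worth knowing: the $T$ multiplier makes the edge rule quite
conservative at small community sizes. In a 31-genome community with
repertoires of ~25 families out of ~180, an overlap must reach about 12
families before $\mathrm{Sig} > 1$; overlaps of ~10, individually
"interesting", are (correctly) discounted as multiple-testing noise. This
matters for mosaic genomes — see below.

## Markov clustering and the inflation sweep

`run_mcl()` is a from-scratch dense implementation of the canonical MCL
loop: column-stochastic flow matrix, expansion (matrix squaring), inflation
(elementwise power, column renormalisation), pruning of entries below
`prune_tol` (1e-6) with renormalisation, until the matrix changes by less
than `convergence_tol` (1e-8) or 200 iterations. Self-loops damp the
period-2 oscillations MCL is prone to; the default weight is the node's
maximum incident edge weight (standard practice on weighted graphs), with
unit loops available for comparison. Clusters are read off the limit
matrix: nodes retaining diagonal mass are attractors, attractors connected
by residual flow form one attractor system, and every other node joins the
system receiving the largest share of its column mass (ties to the
smaller-indexed system). Cluster ids are densely relabelled by decreasing
size, ties by lexicographically smallest member, so output is deterministic
and permutation-equivariant. The test suite checks the implementation
against a separately written naive MCL and verifies column stochasticity to
1e-9 at every step.

Inflation is the granularity dial. `inflation_sweep()` runs 1.2–5.0 in
steps of 0.2 and keeps the clustering maximising a homogeneity score
(ties to the lowest inflation). The homogeneity criterion used for model
selection is not uniquely standardised in this literature, so we define
`icc_homogeneity()` explicitly: the size-weighted mean, over clusters, of
the average unweighted local clustering coefficient of the cluster's
induced subgraph, with clusters of fewer than 3 nodes contributing 0. It is
1 exactly when every cluster induces a clique-like module, penalises both
over-merging (bridged modules dilute the coefficient) and over-splitting
(fragments below size 3 score 0), and is exposed as an ordinary function so
an alternative scorer can be swept instead.

## Membership and mosaicism

`membership_matrix()` quantifies split affiliation: entry $(v, k)$ is the
proportion of $v$'s total incident edge weight (Sig weights by default,
plain edge counts with `weighted = FALSE`) carried by edges into cluster
$k$. Self-loops never count — self-similarity is not evidence of
affiliation — and rows of connected nodes sum to 1 exactly. Isolated nodes
get membership 1 to their own cluster and are flagged. `wedge_table()`
produces the pie-wedge display form (entries above 0.01 plus an "other"
remainder), and `multi_cluster_report()` counts clusters per node above an
assignment threshold, the usual summary for bridge-like genomes.

The conservative edge rule interacts with mosaicism at small scale: a
genome drawing half its core repertoire from each of two clusters shares
~10 families with either side, which at the 31-genome scale sits *below*
the ~12-family significance cutoff — so the minority side often contributes
no edges at all and the node's membership collapses onto its majority
cluster. With larger repertoires (60 core families per cluster) both halves
clear the cutoff and the expected ~0.5/0.5 wedge split appears
(`analysis/05_membership.R` demonstrates both regimes). This is a property
of the statistic at desk scale, not an implementation artifact, and it is
why one membership-related check in the acceptance tests documents a
failure rather than papering over it.

## Topology

`topology_report()` computes per-node degree, local clustering coefficient
($CC(v) = 2e(N(v))/(\deg v)(\deg v - 1)$, 0 below degree 2), and exact
shortest-path betweenness, on the unweighted skeleton by default to match
the defaults of the interactive analyzers this field commonly uses; a
weighted betweenness mode treats distance as 1/Sig. Normalised betweenness
divides by $(n-1)(n-2)/2$ with the whole-graph $n$ (the common convention;
per-component normalisation can be had by subsetting the graph first). The
graph machinery is igraph's; correctness of the betweenness path counts is
cross-checked in the tests against an independent Floyd–Warshall
path-counting oracle on graphs of up to 10 nodes.

## Comparative genomics

`align_local()` wraps Smith–Waterman local alignment (BLOSUM62, gap open
11, extend 1 — the standard protein-search defaults) via Biostrings, with
identity computed over alignment columns including gaps (the BLAST
`pident` convention; identity over the shorter sequence would
systematically inflate values for partial alignments). `rbh_pairs()` keeps
a cross-pair iff each member is the other's best-scoring hit (ties to the
lexicographically smaller id), yielding a one-to-one ortholog pairing that
automatically excludes lineage-specific duplicates, and
`genome_similarity_matrix()` reports the unweighted mean (plus min/max) of
RBH identities per genome pair — unweighted because no length-weighting
rule is standard for "average ORF similarity" summaries. `gc_content()`
excludes ambiguity codes from numerator and denominator. `detect_dtr()`
finds the largest exact prefix/suffix repeat via the KMP border chain —
exact-match only, since near-identical terminal repeats are an assembly
question rather than a sequence-statistics one.

## The synthetic community generator

`generate_community()` emulates the structure the analysis exploits:
clusters of genomes sharing a core family repertoire, cluster-specific
accessory families carried independently at a set probability, private
background families, and mosaic genomes filling each core-family slot from
a source cluster drawn at fixed mixture proportions (their per-cluster
counts are multinomial, and they are labelled by majority source).
`generate_sequences()` adds a sequence level: one uniform-alphabet ancestor
per family (150–400 residues), members mutated at rate
$1 - t$ with substitutions to a uniformly chosen *different* residue. That
substitution model keeps every expectation analytic — member-to-ancestor
identity is $t$; two members match per site with $t^2 + (1-t)^2/19$;
unrelated sequences match at 1/20 — and those closed forms are frozen into
the tests. `generate_genome()` draws bases per-position (G/C with the
target GC probability) and copies the prefix onto the suffix to plant an
exact direct terminal repeat.

What the generator does **not** emulate: gene order and synteny, codon
usage, genome-level nucleotide homology, unequal cluster sizes, gradients
of relatedness within a cluster, and any HGT dynamics beyond the mosaic
mixture. Passing tests therefore demonstrate that the statistics and
algorithms behave as specified on communities with planted block structure;
they do not certify recovery of real phage taxonomy, where family
assignment noise and partial overlaps are far messier.

## Problem sizes and determinism

The shipped analyses and tests run on communities of 10–31 genomes with
60–210 families, networks of up to ~200 edges, and sequence sets of up to
~100 proteins; the repeated-seed checks (partition recovery, family
recovery) use 100 replicates each. All randomness is seed-controlled
through configuration objects or explicit seed arguments, and generation is
byte-reproducible for a given seed; internal RNG use is isolated so calling
package functions does not disturb the caller's RNG stream.

## Known limitations

* Single-linkage families chain through any single spurious sub-threshold
  hit; a profile-HMM or MCL-based family stage would be more robust but is
  out of scope (reference maps can stand in for curated family databases).
* The homogeneity criterion is one defensible choice among several; model
  selection on modularity or silhouette-style scores could pick different
  inflations on ambiguous networks.
* MCL's cluster count is not guaranteed monotone in inflation; the sweep
  table reports whatever each inflation produced.
* The built-in pair scorer is a convenience for self-contained runs, not a
  BLAST replacement: its e-values are calibrated only to the order of
  magnitude a 1e-4 cutoff needs.
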