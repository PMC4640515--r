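#!/usr/bin/env Rscript
# Build the synthetic study inputs: a phage community with three planted
# clusters plus one 50/50 mosaic bridge genome, protein sequences for a
# compact two-cluster community (used for sequence-level family recovery),
# and one phage-sized genome with a planted 208 bp direct terminal repeat.

suppressMessages(library(phagenet))
dir.create("results", showWarnings = FALSE)

## community for the network analyses: 3 clusters x 10 genomes,
## 20 core + 10 accessory (carried at 0.5) + 3 background families each
cfg <- sim_config(n_clusters = 3, genomes_per_cluster = 10,
                  core_families_per_cluster = 20,
                  accessory_families_per_cluster = 10,
                  accessory_carry_prob = 0.5,
                  background_families_per_genome = 3,
                  n_mosaic = 1, mosaic_mixture = c(0.5, 0.5, 0),
                  seed = 20150101)
com <- generate_community(cfg)
cat("community:", length(com$proteomes), "genomes,",
    length(com$truth$family_origin), "families,",
    length(com$truth$mosaic_ids), "mosaic\n")

prof <- profile_from_proteomes(com$proteomes)
write_profile(prof, "results/profile.tsv")
write_truth(com$truth, "results/truth_genomes.tsv", "results/truth_families.tsv")

## compact community with sequences: 2 clusters x 5 genomes, 8 core each
seq_com <- generate_community(sim_config(2, 5, 8, 0, 0, 1, 0, seed = 42))
seqs <- generate_sequences(seq_com$proteomes, target_identity = 0.85, seed = 42)
write_protein_fasta(seqs, "results/proteins.faa")
utils::write.table(seqs[, c("protein_id", "genome_id", "family_id")],
                   "results/protein_truth.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("sequences:", nrow(seqs), "proteins for",
    length(seq_com$proteomes), "genomes\n")

## one phage-sized genome: 45,403 bp, 208 bp DTR, 45.89% GC target
genome <- generate_genome(45403, dtr_length = 208, gc = 0.4589, seed = 7)
writeLines(c(">synthetic_phage_genome", genome), "results/genome.fa")
cat("genome:", nchar(genome), "bp, GC", gc_content(genome), "%\n")
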