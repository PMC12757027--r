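#!/usr/bin/env Rscript
# Build the synthetic study inputs every later step consumes: a 50-kb genome
# with four convergent-gene safe-site candidates, a planted CAST target in
# the second gap, and the delivery vector. Writes standard interchange files
# (FASTA/GFF3/FASTQ/TSV) under results/.

suppressPackageStartupMessages(library(castworks))
dir.create("results", showWarnings = FALSE)

seed <- 20260101
genome0 <- make_genome(length = 50000, n_converging_pairs = 4, seed = seed)
planted <- plant_target(genome0, site_index = 2, seed = seed + 1)
genome <- planted$genome
target <- planted$target
vec <- make_cast_vector(seed = seed + 2)

write_genome_fasta(genome, "results/sim_genome.fasta")
write_genes_gff3(genome, "results/sim_genes.gff3")
write.table(genome$intergenic, "results/sim_intergenic.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- simulate_insertions(genome, target, n_events = 200,
                             cointegrate_rate = 0.12,
                             orientation_probs = c(RL = 0.9, LR = 0.1),
                             seed = seed + 3)
reads <- simulate_long_reads(genome, truth, vec, n_reads = 100,
                             per_base_error = 0.05, seed = seed + 4)
write_reads_fastq(reads, "results/sim_reads.fastq")
write.table(truth$events, "results/sim_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("genome: %d bp, %d genes, %d convergent gaps\n",
            genome$length, nrow(genome$genes), nrow(genome$intergenic)))
cat(sprintf("target: %s PAM %s at %d (protospacer 3' end %d)\n",
            target$protospacer, target$pam, target$pam_start, target$proto3p))
cat(sprintf("events: %d (%.0f%% cointegrate planted), reads: %d\n",
            nrow(truth$events), 100 * mean(truth$events$cointegrate),
            nrow(reads)))
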