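#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study system - a community of AMF-like
# species whose strains carry 6-11 divergent rDNA operon copies (per-locus
# divergence lowest in SSU, highest in ITS) plus three low-variability
# protein-coding genes - and simulate a HiFi amplicon run over it.
# Sequence files go to scratch/ (bulky, regenerable); truth tables to results/.

library(rdnapoly)

dir.create("results", showWarnings = FALSE)
dir.create("scratch/sim", showWarnings = FALSE, recursive = TRUE)

spec <- community_spec(seed = 42)
truth <- simulate_community(spec)
print(truth)

reads <- simulate_hifi_reads(truth, read_sim_spec(depth = 30, seed = 43))
message(length(reads$reads), " HiFi-like reads (",
        sum(reads$truth$class == "chimera"), " chimeras, ",
        sum(reads$truth$class == "contaminant"), " contaminants)")

write_fasta(setNames(truth$copies$sequence, truth$copies$copy_id),
            "scratch/sim/true_copies.fasta")
write_fasta(setNames(truth$genes$sequence, truth$genes$id),
            "scratch/sim/genes.fasta")
write_fastq(reads$reads, "scratch/sim/hifi_reads.fastq", reads$phred)
write_locus_map(truth$root_map, "scratch/sim/root_locus_map.tsv")

copies_tbl <- truth$copies[, c("copy_id", "species", "strain", "chromosome",
                               "weight")]
copies_tbl$length <- nchar(truth$copies$sequence)
readr::write_tsv(copies_tbl, "results/truth_copies.tsv")
readr::write_tsv(reads$truth, "results/truth_reads.tsv")

# copies per chromosome (the uneven distribution of operon copies)
chrom <- dplyr::count(truth$copies, strain, chromosome)
readr::write_tsv(chrom, "results/copies_per_chromosome.tsv")
message("wrote results/truth_copies.tsv, results/truth_reads.tsv, ",
        "results/copies_per_chromosome.tsv")
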