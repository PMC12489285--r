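#!/usr/bin/env Rscript

# Stage 5: SNP density profiling. Reads of one strain are mapped to a single
# copy chosen as reference; intragenomic SNPs are called from the pileup
# (depth >= 20, alternate fraction >= 5%, count >= 3) and summarized as a
# 100 bp / 10 bp sliding-window density track. With ITS copy divergence set
# 10x the SSU divergence, the density track concentrates over the ITS loci.

library(rdnapoly)
dir.create("results", showWarnings = FALSE)

truth <- simulate_community(community_spec(
  n_species = 1, strains_per_species = 1, copies_per_strain = c(8, 8),
  per_locus_copy_divergence = c(SSU = 0.004, ITS1 = 0.04, "5.8S" = 0.01,
                                ITS2 = 0.04, LSU = 0.01),
  seed = 201))
sim <- simulate_hifi_reads(truth, read_sim_spec(depth = 25, seed = 202))
trm <- trim_primers(sim$reads, recovery_config())$trimmed
ref <- truth$copies$sequence[1]

pileup <- map_reads(trm, ref, band = 100)
print(pileup)
snps <- call_snps(pileup)
track <- density_track(snps, nchar(ref))
per_locus <- locus_density(track, truth$copies$map[[1]])

readr::write_tsv(snps, "results/snp_calls.tsv")
readr::write_tsv(track, "results/snp_density_track.tsv")
readr::write_tsv(per_locus, "results/snp_density_per_locus.tsv")
print(per_locus)
its <- mean(per_locus$mean_density[per_locus$locus %in% c("ITS1", "ITS2")])
ssu <- per_locus$mean_density[per_locus$locus == "SSU"]
message(sprintf("%d SNPs called; mean windowed density ITS/SSU = %.1f",
                nrow(snps), its / ssu))
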