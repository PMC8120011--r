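#!/usr/bin/env Rscript
# Generate the synthetic study cohort all downstream analyses consume:
# a two-species, four-population sample (8 NSO, 3 CSO, 12 EBO, 13 WBO)
# with three constructed F1 hybrids and two F1 x WBO backcrosses, per-call
# GQ noise, a per-scaffold depth table with ZW dosage, and an mtDNA
# control-region alignment. Everything is written under results/data/ in
# the same formats a real call set would arrive in (VCF + TSV + FASTA).

library(strixpop)

seed <- 20260919L
n_segments <- 2000L           # 20 Mb in independent 10-kb segments
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

spec <- cohort_spec(n_nso = 8, n_cso = 3, n_ebo = 12, n_wbo = 13,
                    n_f1 = 3, n_backcross = 2, seed = seed)
gm <- simulate_two_species_cohort(spec, n_segments = n_segments)
n <- nrow(gm$genotypes)
message(sprintf("cohort: %d samples, %d variant sites over %.0f Mb",
                n, ncol(gm$genotypes), gm$total_length / 1e6))

set.seed(seed + 1L)
gm$samples$sex <- rep(c("male", "female"), length.out = n)
# GQ noise: ~3% of calls fall below the GQ >= 40 mask
gm$gq <- matrix(pmin(99L, pmax(0L, as.integer(rnorm(length(gm$genotypes),
                                                    75, 19)))),
                n, ncol(gm$genotypes))

write_vcf(gm, "results/data/cohort.vcf")
write_sample_metadata(gm, "results/data/metadata.tsv")
cat(gm$total_length, file = "results/data/total_length.txt")

scaffolds <- data.frame(
  name = c(sprintf("auto%02d", 1:8), "scafZ1", "scafZ2", "scafW1", "scafW2"),
  length = c(rep(5e6, 8), 4e6, 3e6, 2e6, 8e4),
  class = c(rep("autosome", 8), "Z", "Z", "W", "W"))
dt <- simulate_depth_table(gm$samples, scaffolds, base_depth = 30,
                           noise_cv = 0.08, seed = seed + 2L)
write_depth_table(dt, "results/data/depth.tsv")

# mtDNA: one haplotype per cohort sample, clustered by maternal species
# (constructed hybrids carry their mother's lineage)
maternal <- gm$samples$maternal_species
mt <- simulate_mtdna(n_so = sum(maternal == "SO"),
                     n_bo = sum(maternal == "BO"),
                     divergence = 0.05, length = 1200, seed = seed + 3L,
                     ids = c(gm$samples$sample_id[maternal == "SO"],
                             gm$samples$sample_id[maternal == "BO"]))
write_fasta_alignment(mt$alignment, "results/data/mtdna.fasta")

message("wrote results/data/{cohort.vcf, metadata.tsv, depth.tsv, mtdna.fasta}")
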