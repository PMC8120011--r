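#!/usr/bin/env Rscript
# Diversity and differentiation: per-population pi, segregating sites and
# Tajima's D; Weir-Cockerham and Hudson F_ST for the NSO/CSO and EBO/WBO
# pairs and between species; MAF + LD pruning followed by PCA.

library(strixpop)

# pi / S / D on the GQ-masked matrix (pairwise-complete per site);
# F_ST and PCA on the complete-data matrix
gmm <- read_vcf("results/data/cohort_masked.vcf",
                metadata = "results/data/metadata.tsv")
gmm$total_length <- scan("results/data/total_length.txt", quiet = TRUE)
gm <- read_vcf("results/data/cohort_filtered.vcf",
               metadata = "results/data/metadata.tsv")
excl <- readLines("results/excluded_samples.txt")
keep <- setdiff(gm$samples$sample_id, excl)
gm <- gm_subset(gm, samples = keep)
gmm <- gm_subset(gmm, samples = keep)
lab <- gm$samples$label
ids_of <- function(...) gm$samples$sample_id[lab %in% c(...)]

rows <- list()
for (p in c("NSO", "CSO", "EBO", "WBO")) {
  dv <- nucleotide_diversity_within(gmm, ids_of(p))
  rows[[p]] <- data.frame(population = p, pi = dv$pi, S = dv$S,
                          tajima_d = tajimas_d(gmm, ids_of(p)),
                          n_samples = dv$n_samples)
}
div <- do.call(rbind, rows)
div$pi_fmt <- signif(div$pi, 3)
print(div[, c("population", "pi_fmt", "S", "tajima_d", "n_samples")])
write.table(div[, 1:5], "results/diversity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

pairs <- list(c("NSO", "CSO"), c("EBO", "WBO"))
frows <- lapply(pairs, function(pr) {
  f <- fst(gm, ids_of(pr[1]), ids_of(pr[2]))
  h <- fst(gm, ids_of(pr[1]), ids_of(pr[2]), method = "hudson")
  data.frame(pop_a = pr[1], pop_b = pr[2], fst_wc = f$fst, fst_hudson = h$fst,
             n_sites = f$n_sites_used)
})
species <- fst(gm, ids_of("NSO", "CSO"), ids_of("EBO", "WBO"))
frows <- c(frows, list(data.frame(pop_a = "SO", pop_b = "BO",
                                  fst_wc = species$fst, fst_hudson = NA,
                                  n_sites = species$n_sites_used)))
fsts <- do.call(rbind, frows)
print(fsts)
write.table(fsts, "results/fst.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("between-species divergence: %.4g",
                nucleotide_diversity_between(gmm, ids_of("NSO", "CSO"),
                                             ids_of("EBO", "WBO"))))

kept <- ld_prune(gm, maf_min = 0.01, r2_max = 0.2, window = 50, step = 5)
message(sprintf("LD pruning kept %d of %d sites", length(kept),
                ncol(gm$genotypes)))
pc <- pca_coords(gm, kept, k = 2)
write.table(pc$coords, "results/pca.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("PC1/PC2 explain %.1f%% / %.1f%% of variance",
                100 * pc$explained[1], 100 * pc$explained[2]))
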