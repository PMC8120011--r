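# Independent oracles used across the suite. These deliberately take the
# slow, literal route (explicit per-site loops, full enumeration) so they
# share no code path with the vectorized implementations they check.

# Private-allele counts by brute force: for every site complete in the
# group and every member, check each of the two alleles for
# presence/absence in the other members and add the member's dosage of
# any allele nobody else carries.
oracle_private_counts <- function(geno, members) {
  counts <- integer(length(members))
  for (s in seq_len(ncol(geno))) {
    g <- geno[members, s]
    if (anyNA(g)) next
    for (i in seq_along(members)) {
      for (allele in c("ref", "alt")) {
        dos <- if (allele == "alt") g[i] else 2L - g[i]
        if (dos == 0L) next
        others <- if (allele == "alt") g[-i] else 2L - g[-i]
        if (all(others == 0L)) counts[i] <- counts[i] + dos
      }
    }
  }
  counts
}

# Exact HWE tail by enumerating every genotype-count triple compatible
# with the conditional allele counts, weighted by the number of distinct
# allele-to-diploid assignments (multinomial x 2^het).
oracle_hwe_excess <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2L * n_AA + n_Aa
  grid <- expand.grid(x = 0:n, y = 0:n)
  grid$z <- n - grid$x - grid$y
  grid <- grid[grid$z >= 0 & 2L * grid$x + grid$y == nA, ]
  lw <- lgamma(n + 1) - lgamma(grid$x + 1) - lgamma(grid$y + 1) -
    lgamma(grid$z + 1) + grid$y * log(2)
  w <- exp(lw - max(lw))
  sum(w[grid$y >= n_Aa]) / sum(w)
}

# For tiny cohorts, enumerate the actual allele-slot assignments: choose
# which of the 2n allele slots carry the A allele, pair consecutive slots
# into diploids, and tabulate heterozygote counts.
oracle_hwe_tiny <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2L * n_AA + n_Aa
  slots <- combn(2L * n, nA)
  hets <- apply(slots, 2, function(which_a) {
    x <- integer(2L * n)
    x[which_a] <- 1L
    sum(x[seq(1, 2 * n, 2)] != x[seq(2, 2 * n, 2)])
  })
  mean(hets >= n_Aa)
}

# Genotype matrix with ref/alt roles swapped at a set of sites.
swap_alleles <- function(gm, sites = seq_len(ncol(gm$genotypes))) {
  gm$genotypes[, sites] <- 2L - gm$genotypes[, sites]
  r <- gm$sites$ref[sites]
  gm$sites$ref[sites] <- gm$sites$alt[sites]
  gm$sites$alt[sites] <- r
  if (!is.null(gm$haplotypes))
    gm$haplotypes[, sites] <- 1L - gm$haplotypes[, sites]
  gm
}

# Small hand-assembled genotype matrix.
toy_gm <- function(geno, gq = NULL, ...) {
  genotype_matrix(geno, gq = gq, ...)
}
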