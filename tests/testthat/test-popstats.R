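test_that("pi and S are zero on monomorphic data", {
  gm <- genotype_matrix(matrix(0L, 4, 10))
  dv <- nucleotide_diversity_within(gm)
  expect_equal(dv$pi, 0)
  expect_equal(dv$S, 0)
})

test_that("within-pi matches brute-force enumeration of allele pairs", {
  set.seed(14)
  for (r in 1:5) {
    geno <- matrix(sample(0:2, 4 * 30, replace = TRUE, prob = c(.5, .3, .2)),
                   4, 30)
    gm <- genotype_matrix(geno, total_length = 100)
    dv <- nucleotide_diversity_within(gm, total_length = 100)
    # brute force: mean difference over all distinct allele pairs, which
    # the per-site unbiased estimator 2p(1-p) n/(n-1) equals exactly
    oracle <- 0
    for (s in 1:30) {
      g <- geno[, s]
      alle <- unlist(lapply(g, function(d) c(rep(1, d), rep(0, 2 - d))))
      pairs <- combn(8, 2)
      oracle <- oracle + mean(alle[pairs[1, ]] != alle[pairs[2, ]])
    }
    expect_equal(dv$pi, oracle / 100, tolerance = 1e-12)
  }
  # 2 diploids differing at one singleton over 100 sites
  geno <- matrix(0L, 2, 100)
  geno[1, 1] <- 1L
  gm <- genotype_matrix(geno, total_length = 100)
  # one het in 4 alleles: p = 1/4, unbiased 2pq * 4/3 = 0.5 at that site
  expect_equal(nucleotide_diversity_within(gm)$pi, 0.5 / 100)
})

test_that("between-group diversity follows its definition", {
  # all fixed differences at k of L sites -> k / L
  ga <- matrix(2L, 3, 10)
  ga[, 6:10] <- 0L
  gb <- matrix(0L, 3, 10)
  gm <- genotype_matrix(rbind(ga, gb), total_length = 10)
  expect_equal(nucleotide_diversity_between(gm, 1:3, 4:6), 5 / 10)
  # duplicated genotypes across sets: between equals within without the
  # n/(n-1) correction
  set.seed(2)
  g <- matrix(sample(0:2, 3 * 40, replace = TRUE), 3, 40)
  gm2 <- genotype_matrix(rbind(g, g), total_length = 40)
  btw <- nucleotide_diversity_between(gm2, 1:3, 4:6)
  ac <- colSums(g) / 6
  expect_equal(btw, sum(2 * ac * (1 - ac)) / 40, tolerance = 1e-12)
  expect_error(nucleotide_diversity_between(gm2, 1:3, 3:6), "disjoint")
})

test_that("Tajima's D reproduces a hand-computed toy and sign properties", {
  # 2 diploids (4 alleles), 3 segregating sites, dosages (1,0) (1,0) (1,1)
  geno <- matrix(c(1L, 0L, 1L, 0L, 1L, 1L), 2, 3)
  # hand computation with the canonical constants gives 0.1676558
  expect_equal(tajimas_d(genotype_matrix(geno)), 0.1676558,
               tolerance = 1e-6)
  # all singletons in a large sample: D < 0
  gs <- matrix(0L, 20, 30)
  for (s in 1:30) gs[(s %% 20) + 1, s] <- 1L
  expect_lt(tajimas_d(genotype_matrix(gs)), 0)
  expect_error(tajimas_d(genotype_matrix(matrix(0L, 4, 5))), "undefined")
})

test_that("Tajima's D is near zero under the neutral model", {
  ds <- vapply(1:6, function(r) {
    gm <- simulate_split_cohort(demographic_model(T_split = 0), 5, 5,
                                seed = 500 + r, n_segments = 400)
    tajimas_d(gm)
  }, numeric(1))
  expect_lt(abs(mean(ds)), 3 * sd(ds) / sqrt(length(ds)) + 0.15)
})

test_that("F_ST estimators behave at the boundaries and match hand values", {
  # no differentiation: two samples of one panmictic population -> ~ 0
  pan <- simulate_split_cohort(demographic_model(T_split = 0), 10, 10,
                               seed = 83, n_segments = 400)
  expect_equal(fst(pan, 1:10, 11:20, method = "hudson")$fst, 0,
               tolerance = 0.02)
  expect_lt(abs(fst(pan, 1:10, 11:20, method = "weir_cockerham")$fst), 0.02)
  # all sites fixed-different -> hudson F_ST = 1
  gfix <- rbind(matrix(2L, 3, 20), matrix(0L, 3, 20))
  expect_equal(fst(genotype_matrix(gfix), 1:3, 4:6, "hudson")$fst, 1)
  # one-site Weir-Cockerham hand computation: pop1 = (2,1), pop2 = (0,0)
  g1 <- matrix(c(2L, 1L, 0L, 0L), 4, 1)
  expect_equal(fst(genotype_matrix(g1), 1:2, 3:4, "weir_cockerham")$fst,
               0.6666667, tolerance = 1e-6)
  expect_error(fst(genotype_matrix(matrix(1L, 4, 2)), 1:2, 2:4), "disjoint")
  expect_error(fst(genotype_matrix(matrix(0L, 4, 3)), 1:2, 3:4),
               "monomorphic")
})

test_that("hudson and weir_cockerham agree on balanced cohorts", {
  gm <- cached("fst_pair", function()
    simulate_split_cohort(demographic_model(T_split = 0.02), 10, 10,
                          seed = 41, n_segments = 800))
  a <- gm$samples$sample_id[1:10]
  b <- gm$samples$sample_id[11:20]
  wc <- fst(gm, a, b, "weir_cockerham")$fst
  hu <- fst(gm, a, b, "hudson")$fst
  expect_equal(wc, hu, tolerance = 0.1)
})

test_that("differentiation increases with split time", {
  deep <- cached("fst_pair", function()
    simulate_split_cohort(demographic_model(T_split = 0.02), 10, 10,
                          seed = 41, n_segments = 800))
  shallow <- simulate_split_cohort(demographic_model(T_split = 0.002), 10, 10,
                                   seed = 42, n_segments = 800)
  f_deep <- fst(deep, 1:10, 11:20)$fst
  f_shallow <- fst(shallow, 1:10, 11:20)$fst
  expect_gt(f_deep, f_shallow)
})

test_that("estimators are invariant to sample order and allele swap", {
  gm <- two_species_small()
  ids <- gm$samples$sample_id[gm$samples$label == "EBO"]
  base_pi <- nucleotide_diversity_within(gm, ids)$pi
  base_d <- tajimas_d(gm, ids)
  base_f <- fst(gm, gm$samples$sample_id[gm$samples$label == "WBO"], ids)$fst
  # allele swap at odd sites
  gsw <- swap_alleles(gm, seq(1, ncol(gm$genotypes), by = 2))
  expect_equal(nucleotide_diversity_within(gsw, ids)$pi, base_pi)
  expect_equal(tajimas_d(gsw, ids), base_d)
  expect_equal(fst(gsw, gm$samples$sample_id[gm$samples$label == "WBO"],
                   ids)$fst, base_f)
  # sample order within the set
  expect_equal(nucleotide_diversity_within(gm, rev(ids))$pi, base_pi)
})

test_that("ld_prune removes duplicates and respects the r2 bound", {
  set.seed(55)
  base <- matrix(sample(0:2, 200 * 10, replace = TRUE), 200, 10)
  dup <- cbind(base, base[, 1:5])  # 5 exact duplicates (r2 = 1)
  gm <- genotype_matrix(dup)
  kept <- ld_prune(gm, maf_min = 0, r2_max = 0.2, window = 20, step = 5)
  # exhaustive pairwise verification of the retained set
  cm <- cor(gm$genotypes[, kept, drop = FALSE])^2
  diag(cm) <- 0
  expect_lt(max(cm, na.rm = TRUE), 0.2 + 1e-9)
  for (s in 1:5)  # each duplicated pair contributes exactly one survivor
    expect_equal(sum(kept %in% c(s, 10 + s)), 1L)
  # MAF gate: monomorphic/rare sites go away entirely
  rare <- matrix(0L, 200, 10)
  rare[1, ] <- 1L  # MAF = 1/400 < 0.01
  expect_length(ld_prune(genotype_matrix(rare)), 0L)
})

test_that("PCA separates species and reports sane spectra", {
  gm <- two_species_small()
  pc <- pca_coords(gm, k = 2)
  so <- pc$coords$label %in% c("NSO", "CSO")
  # PC1 separates the species (sign-invariant: compare group ranges)
  expect_true(max(pc$coords$PC1[so]) < min(pc$coords$PC1[!so]) ||
                min(pc$coords$PC1[so]) > max(pc$coords$PC1[!so]))
  expect_true(sum(pc$explained) <= 1)
  expect_error(pca_coords(gm, k = 100), "rank")
  # identical samples collapse to one point
  same <- genotype_matrix(matrix(rep(c(0L, 1L, 2L, 1L), 4), 4, 4,
                                 byrow = TRUE))
  pcs <- pca_coords(same, k = 1)
  expect_equal(sd(pcs$coords$PC1), 0)
})
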