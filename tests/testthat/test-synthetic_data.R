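test_that("generators are reproducible given a seed", {
  a <- simulate_split_cohort(demographic_model(), 2, 2, seed = 5,
                             n_segments = 50)
  b <- simulate_split_cohort(demographic_model(), 2, 2, seed = 5,
                             n_segments = 50)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$sites, b$sites)
  d1 <- simulate_depth_table(data.frame(sample_id = "x", sex = "female"),
                             data.frame(name = "s", length = 1e6,
                                        class = "Z"), seed = 3)
  d2 <- simulate_depth_table(data.frame(sample_id = "x", sex = "female"),
                             data.frame(name = "s", length = 1e6,
                                        class = "Z"), seed = 3)
  expect_identical(d1$mean_depth, d2$mean_depth)
})

test_that("a zero mutation rate yields zero variant sites", {
  m <- demographic_model(mu = 0)
  gm <- simulate_split_cohort(m, 1, 1, seed = 1, n_segments = 20)
  expect_equal(ncol(gm$genotypes), 0L)
  expect_error(simulate_split_cohort(demographic_model(), 0, 2),
               ">= 1")
})

test_that("within-population diversity matches the neutral expectation", {
  m <- demographic_model(T_split = 0)
  pis <- vapply(1:4, function(r) {
    gm <- simulate_split_cohort(m, 5, 5, seed = 100 + r, n_segments = 2500)
    nucleotide_diversity_within(gm)$pi
  }, numeric(1))
  expected <- 4 * m$Ne * m$mu
  se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - expected), 3 * se + 0.02 * expected)
})

test_that("samples are exchangeable at split time zero", {
  # per-sample private-allele means are equal within Monte-Carlo error
  m <- demographic_model(T_split = 0)
  counts <- vapply(1:12, function(r) {
    gm <- simulate_split_cohort(m, 1, 12, seed = 300 + r, n_segments = 600)
    des <- group_design(gm$samples$sample_id[1], gm$samples$sample_id[-1])
    tab <- private_allele_counts(gm, des)
    c(tab$count[tab$is_focal], mean(tab$count[!tab$is_focal]))
  }, numeric(2))
  focal <- counts[1, ]
  refmean <- counts[2, ]
  se <- sd(focal - refmean) / sqrt(ncol(counts))
  expect_lt(abs(mean(focal - refmean)), 3.5 * se + 0.01 * mean(refmean))
})

test_that("two-species cohort realizes its calibration targets", {
  gm <- cached("ts_calib", function()
    simulate_two_species_cohort(cohort_spec(seed = 5), n_segments = 1500,
                                haplotypes = FALSE))
  so <- gm$samples$sample_id[gm$samples$label %in% c("NSO", "CSO")]
  bo <- gm$samples$sample_id[gm$samples$label %in% c("EBO", "WBO")]
  expect_equal(nucleotide_diversity_between(gm, so, bo), 0.007,
               tolerance = 0.08)
  expect_equal(nucleotide_diversity_within(gm, so)$pi, 1.4e-4,
               tolerance = 0.25)
  expect_equal(nucleotide_diversity_within(gm, bo)$pi, 2.3e-3,
               tolerance = 0.1)
  # fixed differences exist and are homozygous-opposite by construction
  panel <- fixed_differences(gm, so, bo)
  expect_gt(panel$n_sites, 0)
  ga <- gm$genotypes[match(so, gm$samples$sample_id), panel$site_idx]
  gb <- gm$genotypes[match(bo, gm$samples$sample_id), panel$site_idx]
  expect_true(all(ga %in% c(0L, 2L)) && all(gb %in% c(0L, 2L)))
  expect_true(all(colMeans(ga) / 2 + colMeans(gb) / 2 == 1))
  expect_error(
    simulate_two_species_cohort(cohort_spec(), pi_so = 0.008, pi_bo = 0.008),
    "below the between-species divergence")
})

test_that("F1 construction is Mendelian at fixed differences", {
  gm <- two_species_small()
  so <- gm$samples$sample_id[gm$samples$label %in% c("NSO", "CSO")]
  bo <- gm$samples$sample_id[gm$samples$label %in% c("EBO", "WBO")]
  panel <- fixed_differences(gm, so, bo)
  f1 <- make_f1(gm, so[1], bo[1], seed = 8)
  expect_true(all(f1$genotype %in% c(0L, 1L, 2L)))
  dos_a <- ifelse(panel$a_is_alt, f1$genotype[panel$site_idx],
                  2L - f1$genotype[panel$site_idx])
  expect_true(all(dos_a == 1L))  # heterozygous at every fixed difference
  # selfing a fully homozygous parent returns the parent
  hom <- genotype_matrix(matrix(c(0L, 2L, 0L, 2L), 1, 4),
                         sites = data.frame(scaffold = "s", position = 1:4,
                                            ref = "A", alt = "G"))
  child <- make_f1(hom, 1, 1, seed = 2)
  expect_equal(child$genotype, c(0L, 2L, 0L, 2L))
})

test_that("backcrosses average 25% minor-parent ancestry with no A homozygotes", {
  gm <- two_species_small()
  so <- gm$samples$sample_id[gm$samples$label %in% c("NSO", "CSO")]
  bo <- gm$samples$sample_id[gm$samples$label %in% c("EBO", "WBO")]
  panel <- fixed_differences(gm, so, bo)
  expect_gt(panel$n_sites, 1000)
  set.seed(12)
  f1 <- make_f1(gm, so[1], bo[1])
  stats <- vapply(1:150, function(r) {
    bc <- make_backcross(gm, f1, bo[2])
    dos <- ifelse(panel$a_is_alt, bc$genotype[panel$site_idx],
                  2L - bc$genotype[panel$site_idx])
    c(mean(dos) / 2, sum(dos == 2L))
  }, numeric(2))
  expect_equal(mean(stats[1, ]), 0.25, tolerance = 0.05)
  expect_equal(max(stats[2, ]), 0)
  expect_true(all(stats[1, ] >= 0 & stats[1, ] <= 0.5))
})

test_that("depth simulation reproduces ZW dosage exactly without noise", {
  samples <- data.frame(sample_id = c("m1", "f1"), sex = c("male", "female"))
  scaffolds <- data.frame(name = c("a1", "z1", "w1"),
                          length = c(2e6, 1e6, 1e6),
                          class = c("autosome", "Z", "W"))
  dt <- simulate_depth_table(samples, scaffolds, base_depth = 30,
                             noise_cv = 0, seed = 1)
  expect_equal(dt$mean_depth["z1", "f1"], 15)
  expect_equal(dt$mean_depth["z1", "m1"], 30)
  expect_equal(dt$mean_depth["w1", "m1"], 0)
  expect_equal(dt$missingness["w1", "m1"], 1)
  expect_equal(dt$mean_depth["a1", "f1"], 30)
})

test_that("mtDNA clusters separate at the requested divergence", {
  mt <- simulate_mtdna(n_so = 4, n_bo = 4, divergence = 0.05, length = 1000,
                       seed = 6)
  d_between <- mean(sapply(1:4, function(i) sapply(5:8, function(j)
    sum(mt$alignment[i, ] != mt$alignment[j, ]))))
  expect_equal(d_between, 50, tolerance = 0.4)
  single <- simulate_mtdna(n_so = 0, n_bo = 3, divergence = 0.05,
                           length = 500, seed = 7)
  expect_equal(unname(unique(single$labels)), "BO")
  d_within <- sum(single$alignment[1, ] != single$alignment[2, ])
  expect_lt(d_within, 15)
})

test_that("constructed genotypes never leave {0, 1, 2, missing}", {
  gm <- two_species_small()
  set.seed(3)
  for (r in 1:5) {
    f1 <- make_f1(gm, sample(gm$samples$sample_id, 1),
                  sample(gm$samples$sample_id, 1))
    expect_true(all(f1$genotype %in% c(0L, 1L, 2L, NA_integer_)))
    bc <- make_backcross(gm, f1, sample(gm$samples$sample_id, 1))
    expect_true(all(bc$genotype %in% c(0L, 1L, 2L, NA_integer_)))
  }
})
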