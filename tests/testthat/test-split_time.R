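test_that("private-allele counting matches the brute-force oracle exhaustively", {
  set.seed(90)
  for (r in 1:25) {
    n <- sample(3:13, 1)
    S <- 200
    geno <- matrix(sample(c(0:2, NA), n * S, replace = TRUE,
                          prob = c(.45, .25, .25, .05)), n, S)
    rownames(geno) <- sprintf("s%02d", seq_len(n))
    gm <- genotype_matrix(geno)
    des <- group_design(gm$samples$sample_id[1], gm$samples$sample_id[-1])
    tab <- private_allele_counts(gm, des)
    expect_equal(tab$count, unname(oracle_private_counts(geno, seq_len(n))))
  }
})

test_that("hand examples of the private-allele definition hold", {
  # member het where the other 12 are opposite homozygotes -> +1
  g1 <- matrix(2L, 13, 1); g1[1, 1] <- 1L
  # member hom-ref where all others are hom-alt -> +2 (ref can be private)
  g2 <- matrix(2L, 13, 1); g2[1, 1] <- 0L
  # two members share the minor allele -> +0 for both
  g3 <- matrix(0L, 13, 1); g3[1:2, 1] <- 1L
  gm <- genotype_matrix(cbind(g1, g2, g3))
  des <- group_design(gm$samples$sample_id[1], gm$samples$sample_id[-1])
  tab <- private_allele_counts(gm, des)
  expect_equal(tab$count[tab$is_focal], 3L)          # 1 + 2 + 0
  expect_equal(sum(tab$count[!tab$is_focal]), 0L)
  # a site with a missing call is skipped for the group
  gmiss <- gm
  gmiss$genotypes[5, 2] <- NA_integer_
  expect_equal(private_allele_counts(gmiss, des)$count[1], 1L)
})

test_that("ratio statistic is plain arithmetic over groups", {
  tab <- data.frame(group = rep(c("a", "b", "c"), each = 3),
                    member = letters[1:9],
                    is_focal = rep(c(TRUE, FALSE, FALSE), 3),
                    count = c(10, 8, 12, 20, 10, 10, 30, 15, 25))
  # group ratios: 10/10, 20/10, 30/20 -> mean = (1 + 2 + 1.5) / 3
  expect_equal(ratio_statistic(tab), 1.5)
  same <- tab; same$count <- 7
  expect_equal(ratio_statistic(same), 1)
  scaled <- tab
  scaled$count[scaled$is_focal] <- 1.14 * c(10, 10, 20)
  expect_equal(ratio_statistic(scaled), 1.14)
  zero <- tab; zero$count[!zero$is_focal] <- 0
  expect_error(ratio_statistic(zero), "zero")
})

test_that("permutation machinery: counts, exhaustive mode, monotonicity", {
  expect_equal(assignment_count(25, 13), choose(25, 13))
  expect_equal(1 / assignment_count(25, 13), 1.9e-7, tolerance = 0.02)
  # engineered data where the observed assignment is the unique extreme
  set.seed(50)
  geno <- matrix(sample(0:1, 7 * 300, replace = TRUE), 7, 300)
  geno[1:3, ] <- geno[1:3, ] + matrix(sample(0:1, 3 * 300, replace = TRUE,
                                             prob = c(.3, .7)), 3, 300)
  geno <- pmin(geno, 2L)
  rownames(geno) <- letters[1:7]
  gm <- genotype_matrix(geno)
  des <- group_design(letters[1:3], letters[4:7])
  ex <- permutation_test(gm, des, exhaustive = TRUE)
  expect_equal(ex$n_assignments, choose(7, 3))
  expect_gte(ex$p_value, 1 / choose(7, 3))
  expect_equal(ex$p_value, mean(ex$null >= ex$observed - 1e-12))
  # loading each focal sample with private singletons makes the observed
  # assignment the unique extreme: p hits the exhaustive floor 1/C(7,3)
  extra <- matrix(0L, 7, 600)
  for (k in 1:3) extra[k, (k - 1) * 200 + 1:200] <- 1L
  gm2 <- genotype_matrix(cbind(geno, extra))
  ex2 <- permutation_test(gm2, des, exhaustive = TRUE)
  expect_lte(ex2$p_value, ex$p_value)
  expect_equal(ex2$p_value, 1 / choose(7, 3))
  expect_error(permutation_test(gm, des, n_perm = 10), "at least 100")
})

test_that("permutation p-values are calibrated under the panmictic null", {
  ps <- null_pvalues()
  # p-values sit on a discrete grid of 1/101, so ties are expected
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.001)
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
})

test_that("the ratio curve starts at 1, increases, and inverts correctly", {
  curve <- shared_curve()
  # exchangeability at T = 0 (3.5 sigma band on the replicate mean)
  expect_equal(curve$expected_ratio[1], 1, tolerance = 0.03)
  expect_true(all(curve$ci_lo < curve$ci_hi))
  # monotone nondecreasing within CI resolution
  expect_true(all(diff(curve$expected_ratio) > -
                    (curve$ci_hi - curve$ci_lo)[-1]))
  expect_gt(curve$expected_ratio[nrow(curve)], curve$expected_ratio[1])
  # interpolation contracts
  expect_equal(estimate_split_time(curve$expected_ratio[3], curve),
               curve$T[3])
  mid <- (curve$expected_ratio[3] + curve$expected_ratio[4]) / 2
  expect_equal(estimate_split_time(mid, curve),
               (curve$T[3] + curve$T[4]) / 2, tolerance = 1e-10)
  expect_error(estimate_split_time(10, curve), "outside")
  # a curve pinned at 1 for T = 0 inverts R = 1 to T = 0
  flat <- curve; flat$expected_ratio[1] <- 1
  expect_equal(estimate_split_time(1, flat), 0)
})

test_that("the moment estimator recovers a known split time within 15%", {
  rec <- recovery_result()
  expect_equal(rec$t_hat, rec$t_star, tolerance = 0.15)
})

test_that("a post-split focal bottleneck leaves the ratio unchanged within CI", {
  b <- bottleneck_result()
  expect_lt(abs(b$plain$mean - b$bottl$mean),
            2.2 * sqrt(b$plain$se^2 + b$bottl$se^2) + 0.01)
})

test_that("excluding a random tenth of segments leaves the ratio unchanged", {
  gm <- simulate_split_cohort(demographic_model(T_split = 0.003), 1, 12,
                              seed = 321, n_segments = 5000)
  des <- group_design(gm$samples$sample_id[1], gm$samples$sample_id[-1])
  r_full <- ratio_statistic(private_allele_counts(gm, des))
  set.seed(5)
  segs <- unique(gm$sites$scaffold)
  drop <- sample(segs, length(segs) %/% 10)
  gm_red <- gm_subset(gm, sites = !(gm$sites$scaffold %in% drop))
  r_red <- ratio_statistic(private_allele_counts(gm_red, des))
  expect_equal(r_red, r_full, tolerance = 0.04)
})

test_that("unit conversions reproduce the published arithmetic", {
  # 0.0029 x 4Ne generations at Ne = 120,000 and 5 y/gen -> ~7,000 y
  y <- split_time_to_years(0.0029, 120000, 5)
  expect_equal(y$years, 6960)
  expect_equal(y$years_rounded, 7000)
  expect_equal(split_time_to_years(0, 120000, 5)$years, 0)
  # Ne from diversity
  expect_equal(ne_from_diversity(2.15e-3, 4.6e-9), 116847.8, tolerance = 1e-6)
  expect_equal(round(ne_from_diversity(2.15e-3, 4.6e-9), -4), 120000)
  expect_equal(ne_from_diversity(4 * 1e-8, 1e-8), 1)
  expect_equal(ne_from_diversity(2.15e-3, 1.34e-7), 4011.194, tolerance = 1e-6)
  # the 140-year scenario: g = 3, mu = 1.34e-7
  ne140 <- ne_from_diversity(2.15e-3, 1.34e-7)
  y140 <- split_time_to_years(0.0029, ne140, 3)$years
  expect_equal(y140, 140, tolerance = 0.05)
  # fold-uncertainty interval
  iv <- uncertainty_interval(7000, 5)
  expect_equal(unname(iv), c(1400, 35000))
  expect_equal(unname(uncertainty_interval(123, 1)), c(123, 123))
  expect_true(iv["low"] <= 7000 && 7000 <= iv["high"])
})
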