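# Shared simulated fixtures, built once per test run. Seeds are fixed so
# every run sees the same cohorts.
.cohort_cache <- new.env(parent = emptyenv())

cached <- function(name, create) {
  if (!exists(name, envir = .cohort_cache))
    assign(name, create(), envir = .cohort_cache)
  get(name, envir = .cohort_cache)
}

# Four-population two-species cohort with haplotypes, desk scale.
two_species_small <- function() {
  cached("ts_small", function()
    simulate_two_species_cohort(
      cohort_spec(n_nso = 4, n_cso = 2, n_ebo = 5, n_wbo = 5, seed = 11),
      n_segments = 150))
}

# Panmictic 13 + 12 cohort (split time zero) for null-calibration work.
panmictic_cohort <- function(seed = 77, n_segments = 400) {
  simulate_split_cohort(demographic_model(T_split = 0), n_w = 13, n_e = 12,
                        seed = seed, n_segments = n_segments)
}

# On-disk fixture bundle from the pipeline generator.
fixture_bundle <- function() {
  cached("bundle", function() make_fixtures(seed = 42, n_segments = 250))
}

# Expected ratio curve shared by the split-time property tests: modest
# replication over a grid spanning the estimation range.
shared_curve <- function() {
  cached("curve", function()
    expected_ratio_curve(demographic_model(),
                         T_grid = c(0, 0.001, 0.002, 0.003, 0.004, 0.005,
                                    0.006),
                         n_replicates = 25, seed = 19, n_ref = 12,
                         n_segments = 2500))
}

# Gene-dropping pedigree over simulated founder haplotypes: children are
# built with the gamete-level constructor, so relatedness is known.
pedigree_cohort <- function() {
  cached("pedigree", function() {
    gm <- simulate_split_cohort(demographic_model(T_split = 0), 4, 4,
                                seed = 23, n_segments = 600,
                                haplotypes = TRUE)
    set.seed(24)
    child <- make_f1(gm, 1, 2)              # offspring of founders 1 and 2
    gm <- gm_append_sample(gm, child, "child1")
    grand <- make_f1(gm, "child1", 3)       # grandchild of founders 1, 2
    gm <- gm_append_sample(gm, grand, "grand1")
    dup <- gm$genotypes[1, ]                # duplicate of founder 1
    gm <- gm_append_sample(gm, structure(list(genotype = dup,
                                              haplotypes = gm$haplotypes[1:2, ],
                                              mother = NA, father = NA),
                                         class = "constructed_sample"),
                           "dup1")
    gm
  })
}

# Heavier shared computations, cached so the acceptance checks and the
# module tests measure the same runs.
recovery_result <- function() {
  cached("recovery", function() {
    t_star <- 0.003
    obs <- mean_ratio_over_reps(demographic_model(T_split = t_star),
                                n_reps = 20, n_segments = 10000,
                                seed0 = 8000)
    list(t_star = t_star, r_obs = obs$mean,
         t_hat = estimate_split_time(obs$mean, shared_curve()))
  })
}

bottleneck_result <- function() {
  cached("bottleneck", function() {
    m <- demographic_model(T_split = 0.003)
    t_gen <- 0.003 * 4 * m$Ne
    list(plain = mean_ratio_over_reps(m, 12, 5000, 8100),
         bottl = mean_ratio_over_reps(m, 12, 5000, 8200,
                                      focal_bottleneck = list(start = 0,
                                                              end = t_gen,
                                                              factor = 0.05)))
  })
}

null_pvalues <- function() {
  cached("null_ps", function()
    vapply(1:30, function(r) {
      gm <- panmictic_cohort(seed = 700 + r, n_segments = 60)
      des <- group_design(gm$samples$sample_id[1:13],
                          gm$samples$sample_id[14:25])
      permutation_test(gm, des, n_perm = 100, seed = r)$p_value
    }, numeric(1)))
}

# Mean single-group focal/reference ratio over replicate cohorts.
mean_ratio_over_reps <- function(model, n_reps, n_segments, seed0,
                                 focal_bottleneck = NULL) {
  rs <- vapply(seq_len(n_reps), function(r) {
    gm <- simulate_split_cohort(model, 1, 12, seed = seed0 + r,
                                n_segments = n_segments,
                                focal_bottleneck = focal_bottleneck)
    des <- group_design(gm$samples$sample_id[1], gm$samples$sample_id[-1])
    ratio_statistic(private_allele_counts(gm, des))
  }, numeric(1))
  list(mean = mean(rs), se = sd(rs) / sqrt(n_reps), ratios = rs)
}
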