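#' Asymmetric group design for private-allele counting
#'
#' For each focal sample, a group is formed of that one focal sample plus
#' all reference samples (e.g. 13 groups of 1 WBO + 12 EBO). The
#' asymmetry makes mutations accumulated on the focal side since a split
#' visible as private alleles of the single focal member, while being
#' insensitive to focal-side demography after the split.
#'
#' @param focal_samples,reference_samples disjoint sample id vectors.
#' @return a `group_design` list.
#' @export
group_design <- function(focal_samples, reference_samples) {
  if (length(intersect(focal_samples, reference_samples)))
    stop("focal and reference samples must be disjoint")
  if (!length(focal_samples) || length(reference_samples) < 1)
    stop("need at least one focal and one reference sample")
  structure(list(focal = focal_samples, reference = reference_samples),
            class = "group_design")
}

# Private-allele counts for one explicit group of sample indices.
# An allele (reference or alternate, by presence/absence) carried by one
# member and absent from all others contributes 1 if heterozygous, 2 if
# homozygous. Sites with a missing call in the group are skipped.
count_private_group <- function(geno, members) {
  g <- geno[members, , drop = FALSE]
  ok <- colSums(is.na(g)) == 0L
  g <- g[, ok, drop = FALSE]
  m <- length(members)
  altc <- .colSums(g, m, ncol(g))
  refc <- 2L * m - altc
  alt_priv <- sweep(g, 2, altc, "==") & g > 0L          # member carries all alt copies
  ref_priv <- sweep(2L - g, 2, refc, "==") & g < 2L     # member carries all ref copies
  counts <- .rowSums(g * alt_priv, m, ncol(g)) +
    .rowSums((2L - g) * ref_priv, m, ncol(g))
  as.integer(counts)
}

#' Private-allele counts in asymmetric groups
#'
#' For each group (one focal + all reference samples), counts per member
#' the allele copies carried by that member and absent from the other
#' members: singletons count 1, private homozygotes 2. Privacy is by
#' presence/absence of either allele — a reference allele can be private.
#' Sites with any missing call within a group are skipped for that group
#' only.
#'
#' @param gm a [genotype_matrix()].
#' @param design a [group_design()].
#' @return a `private_allele_table` data frame: `group` (focal id),
#'   `member`, `is_focal`, `count`.
#' @export
private_allele_counts <- function(gm, design) {
  fi <- resolve_samples(gm, design$focal)
  ri <- resolve_samples(gm, design$reference)
  if (length(ri) + 1L < 2L) stop("groups must have at least 2 members")
  ids <- gm$samples$sample_id
  out <- vector("list", length(fi))
  for (k in seq_along(fi)) {
    members <- c(fi[k], ri)
    counts <- count_private_group(gm$genotypes, members)
    out[[k]] <- data.frame(group = ids[fi[k]], member = ids[members],
                           is_focal = c(TRUE, rep(FALSE, length(ri))),
                           count = counts, stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, out), class = c("private_allele_table",
                                           "data.frame"))
}

#' Observed mean focal/reference private-allele ratio
#'
#' Per group, the ratio of the focal member's private-allele count to the
#' mean count over the reference members; averaged over groups.
#'
#' @param table a [private_allele_counts()] table.
#' @return the mean ratio (scalar).
#' @export
ratio_statistic <- function(table) {
  groups <- unique(table$group)
  if (!length(groups)) stop("empty private-allele table")
  r <- vapply(groups, function(gname) {
    tg <- table[table$group == gname, ]
    ref_mean <- mean(tg$count[!tg$is_focal])
    if (ref_mean == 0) stop("reference mean private-allele count is zero in group ",
                            gname)
    tg$count[tg$is_focal] / ref_mean
  }, numeric(1))
  mean(r)
}

#' Count of distinct focal/reference label assignments
#' @param n_total,n_focal cohort and focal-set sizes.
#' @return `choose(n_total, n_focal)`.
#' @export
assignment_count <- function(n_total, n_focal) choose(n_total, n_focal)

#' Permutation test of focal/reference exchangeability
#'
#' Null hypothesis: the focal and reference samples are draws from one
#' panmictic population, so the focal/reference labels are exchangeable.
#' Each permutation reassigns which samples are focal, rebuilds all
#' groups, and recomputes the mean ratio. One-sided Monte-Carlo p-value
#' `(1 + #{R_perm >= R_obs}) / (1 + n_perm)`; in exhaustive mode all
#' `choose(n, k)` assignments are enumerated and the p-value is the exact
#' tail fraction (the smallest attainable value is `1 / choose(n, k)`,
#' reached when the observed assignment is the unique maximum).
#'
#' @param gm a [genotype_matrix()].
#' @param design a [group_design()].
#' @param n_perm number of Monte-Carlo permutations (>= 100).
#' @param exhaustive enumerate all assignments (guarded to <= `max_exhaustive`).
#' @param max_exhaustive refusal threshold for exhaustive enumeration.
#' @param seed optional RNG seed.
#' @return list: `p_value`, `observed`, `n_assignments`, `mode`, and a
#'   summary of the null distribution.
#' @export
permutation_test <- function(gm, design, n_perm = 1000, exhaustive = FALSE,
                             max_exhaustive = 2e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  all_ids <- c(design$focal, design$reference)
  idx <- resolve_samples(gm, all_ids)
  n <- length(idx)
  k <- length(design$focal)
  obs <- ratio_statistic(private_allele_counts(gm, design))
  stat_for <- function(f_idx) {
    r_idx <- setdiff(idx, f_idx)
    r <- vapply(f_idx, function(f) {
      counts <- count_private_group(gm$genotypes, c(f, r_idx))
      counts[1] / mean(counts[-1])
    }, numeric(1))
    mean(r)
  }
  n_assign <- assignment_count(n, k)
  if (exhaustive) {
    if (n_assign > max_exhaustive)
      stop("exhaustive mode would enumerate ", format(n_assign, big.mark = ","),
           " assignments; use Monte-Carlo mode")
    combs <- combn(idx, k)
    null <- apply(combs, 2, stat_for)
    p <- mean(null >= obs - 1e-12)
    list(p_value = p, observed = obs, n_assignments = n_assign,
         mode = "exhaustive",
         null_summary = summary(null), null = null)
  } else {
    if (n_perm < 100) stop("n_perm must be at least 100")
    null <- vapply(seq_len(n_perm), function(i)
      stat_for(sample(idx, k)), numeric(1))
    p <- (1 + sum(null >= obs - 1e-12)) / (1 + n_perm)
    list(p_value = p, observed = obs, n_assignments = n_assign,
         mode = "monte_carlo",
         null_summary = summary(null), null = null)
  }
}

#' Expected private-allele ratio curve over split times
#'
#' For each split time on the grid, simulates replicate cohorts of one
#' focal plus `n_ref` reference diploids under the isolation model,
#' counts private alleles exactly as for observed data
#' ([private_allele_counts()]), and records the mean focal/reference
#' ratio with a 95% confidence interval of the mean across replicates.
#' The expected ratio is 1 at T = 0 (exchangeability) and increases with
#' isolation time.
#'
#' @param model a [demographic_model()].
#' @param T_grid increasing split times in `4 Ne` generations.
#' @param n_replicates replicates per grid point.
#' @param seed integer seed; replicate r at grid point i uses a seed
#'   derived deterministically from it.
#' @param n_ref reference diploids per group (default 12).
#' @param n_segments segments per replicate (default from `model`).
#' @return a `ratio_curve` data frame: `T`, `expected_ratio`, `ci_lo`,
#'   `ci_hi`, `n_replicates`; the model is attached as an attribute.
#' @export
expected_ratio_curve <- function(model = demographic_model(),
                                 T_grid = seq(0, 0.006, by = 0.0005),
                                 n_replicates = 20, seed = 1L, n_ref = 12,
                                 n_segments = model$n_segments) {
  stopifnot(length(T_grid) >= 1, !is.unsorted(T_grid, strictly = TRUE))
  rows <- vector("list", length(T_grid))
  for (i in seq_along(T_grid)) {
    m <- model
    m$T_split <- T_grid[i]
    ratios <- vapply(seq_len(n_replicates), function(r) {
      set.seed((seed * 1009L + i * 131L + r) %% .Machine$integer.max)
      gm <- simulate_split_cohort(m, n_w = 1, n_e = n_ref,
                                  n_segments = n_segments)
      des <- group_design(gm$samples$sample_id[1],
                          gm$samples$sample_id[-1])
      ratio_statistic(private_allele_counts(gm, des))
    }, numeric(1))
    se <- sd(ratios) / sqrt(n_replicates)
    tq <- if (n_replicates > 1) qt(0.975, n_replicates - 1) else NA_real_
    rows[[i]] <- data.frame(T = T_grid[i], expected_ratio = mean(ratios),
                            ci_lo = mean(ratios) - tq * se,
                            ci_hi = mean(ratios) + tq * se,
                            n_replicates = n_replicates)
  }
  out <- do.call(rbind, rows)
  attr(out, "model") <- model
  class(out) <- c("ratio_curve", "data.frame")
  out
}

#' Moment estimate of the split time from the ratio curve
#'
#' Linear interpolation of the simulated expected-ratio curve at the
#' observed mean ratio. Errors if the observed ratio falls outside the
#' curve's range (the grid must bracket it) or if the curve is not
#' monotone around the crossing (more replicates needed).
#'
#' @param r_obs observed mean ratio from [ratio_statistic()].
#' @param curve a [expected_ratio_curve()].
#' @return `T_hat` in `4 Ne` generations.
#' @export
estimate_split_time <- function(r_obs, curve) {
  er <- curve$expected_ratio
  if (r_obs < min(er) || r_obs > max(er))
    stop("observed ratio ", signif(r_obs, 4), " outside simulated range [",
         signif(min(er), 4), ", ", signif(max(er), 4),
         "]; extend the T grid to bracket it")
  exact <- which(abs(er - r_obs) < 1e-12)
  if (length(exact)) return(curve$T[exact[1]])
  bracket <- which(er[-length(er)] < r_obs & er[-1] > r_obs)
  if (!length(bracket))
    stop("ratio curve non-monotone around the observed value; ",
         "increase n_replicates")
  i <- bracket[1]
  curve$T[i] + (r_obs - er[i]) / (er[i + 1] - er[i]) *
    (curve$T[i + 1] - curve$T[i])
}

#' Convert a coalescent-scaled split time to years
#'
#' `years = T_hat * 4 * Ne * gen_time`, with T in units of `4 Ne`
#' generations.
#'
#' @param T_hat split time in `4 Ne` generations.
#' @param Ne diploid effective population size.
#' @param gen_time years per generation.
#' @return list: `years` (raw) and `years_rounded` (nearest thousand).
#' @export
split_time_to_years <- function(T_hat, Ne, gen_time) {
  stopifnot(T_hat >= 0, Ne > 0, gen_time > 0)
  years <- T_hat * 4 * Ne * gen_time
  list(years = years, years_rounded = round(years, -3))
}

#' Effective population size from nucleotide diversity
#'
#' Neutral-equilibrium identity `Ne = pi / (4 mu)`.
#'
#' @param pi per-site nucleotide diversity.
#' @param mu mutation rate per site per generation.
#' @return diploid Ne.
#' @export
ne_from_diversity <- function(pi, mu) {
  stopifnot(pi > 0, mu > 0)
  pi / (4 * mu)
}

#' Fold-uncertainty interval around a point estimate
#'
#' `(years / fold, years * fold)` — the multiplicative band used to
#' propagate total uncertainty in Ne, mu and generation time onto the
#' divergence-time estimate.
#'
#' @param years point estimate in years.
#' @param fold total fold-uncertainty (>= 1).
#' @return numeric `c(low, high)`.
#' @export
uncertainty_interval <- function(years, fold) {
  stopifnot(fold >= 1)
  c(low = years / fold, high = years * fold)
}
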