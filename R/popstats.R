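#' Within-population nucleotide diversity and segregating sites
#'
#' Per-site unbiased pairwise diversity `2 p (1 - p) n / (n - 1)` with `n`
#' the non-missing allele count at the site, summed over sites and divided
#' by the surveyed length. When the matrix records the total number of
#' base pairs simulated or surveyed (`total_length`), diversity is per
#' base pair (the scale on which genome-wide pi is reported); otherwise it
#' is per analyzed variant site.
#'
#' @param gm a [genotype_matrix()].
#' @param samples sample subset (ids, logical, or indices; default all).
#' @param total_length denominator in base pairs; defaults to
#'   `gm$total_length`, else the number of analyzed sites.
#' @return a `diversity_result` list: `pi`, `S`, `theta_pi_sum` (summed
#'   per-site heterozygosity, the mean pairwise difference count),
#'   `n_samples`, `n_sites_used`, `denominator`.
#' @export
nucleotide_diversity_within <- function(gm, samples = NULL,
                                        total_length = gm$total_length) {
  idx <- if (is.null(samples)) seq_len(nrow(gm$genotypes)) else
    resolve_samples(gm, samples)
  if (length(idx) < 2) stop("need at least 2 samples")
  ac <- allele_counts(gm, idx)
  use <- ac$n >= 2L
  if (!any(use) && ncol(gm$genotypes) > 0L && all(ac$n < 2L))
    stop("fewer than 2 non-missing alleles at every site")
  p <- ac$alt[use] / ac$n[use]
  n <- ac$n[use]
  site_pi <- 2 * p * (1 - p) * n / (n - 1)
  S <- sum(ac$alt[use] > 0L & ac$alt[use] < ac$n[use])
  denom <- if (!is.null(total_length)) total_length else max(1L, sum(use))
  structure(list(pi = sum(site_pi) / denom, S = S,
                 theta_pi_sum = sum(site_pi),
                 n_samples = length(idx), n_sites_used = sum(use),
                 denominator = denom),
            class = "diversity_result")
}

#' Between-group nucleotide diversity
#'
#' Mean per-site probability that a random allele from `set_a` differs
#' from a random allele from `set_b`: `p_a (1 - p_b) + p_b (1 - p_a)`,
#' summed over sites and divided by the surveyed length (see
#' [nucleotide_diversity_within()] for the denominator convention).
#'
#' @param gm a [genotype_matrix()].
#' @param set_a,set_b disjoint sample subsets.
#' @param total_length denominator in base pairs.
#' @return between-group diversity (d_xy).
#' @export
nucleotide_diversity_between <- function(gm, set_a, set_b,
                                         total_length = gm$total_length) {
  ia <- resolve_samples(gm, set_a)
  ib <- resolve_samples(gm, set_b)
  if (length(intersect(ia, ib))) stop("sample sets must be disjoint")
  if (!length(ia) || !length(ib)) stop("both sample sets must be non-empty")
  aa <- allele_counts(gm, ia)
  ab <- allele_counts(gm, ib)
  use <- aa$n >= 1L & ab$n >= 1L
  pa <- aa$alt[use] / aa$n[use]
  pb <- ab$alt[use] / ab$n[use]
  dxy <- sum(pa * (1 - pb) + pb * (1 - pa))
  denom <- if (!is.null(total_length)) total_length else max(1L, sum(use))
  dxy / denom
}

#' Tajima's D
#'
#' Standard Tajima (1989) statistic comparing the mean pairwise difference
#' estimator of theta with the segregating-sites estimator, using the
#' canonical a1, a2, b1, b2, c1, c2, e1, e2 constants. With missing data
#' the constants use the modal non-missing allele count across analyzed
#' sites; running on complete-data matrices (see
#' [drop_incomplete_sites()]) avoids the approximation.
#'
#' @param gm a [genotype_matrix()].
#' @param samples sample subset (default all).
#' @return Tajima's D (error if no segregating sites).
#' @export
tajimas_d <- function(gm, samples = NULL) {
  idx <- if (is.null(samples)) seq_len(nrow(gm$genotypes)) else
    resolve_samples(gm, samples)
  ac <- allele_counts(gm, idx)
  use <- ac$n >= 2L
  seg <- use & ac$alt > 0L & ac$alt < ac$n
  S <- sum(seg)
  if (S == 0) stop("Tajima's D undefined: no segregating sites")
  nvals <- ac$n[seg]
  n <- as.integer(names(sort(table(nvals), decreasing = TRUE))[1])  # modal
  p <- ac$alt[seg] / ac$n[seg]
  k_hat <- sum(2 * p * (1 - p) * ac$n[seg] / (ac$n[seg] - 1))
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' F_ST between two sample sets
#'
#' Weir-Cockerham (1984) variance-components estimator (the default,
#' matching common PLINK usage) or the Hudson estimator in the
#' Bhatia et al. (2013) ratio-of-sums form. Both aggregate as a ratio of
#' sums over sites, the standard low-bias choice. Hudson is less sensitive
#' to unequal sample sizes.
#'
#' @param gm a [genotype_matrix()].
#' @param set_a,set_b disjoint sample subsets (>= 2 samples each).
#' @param method `"weir_cockerham"` or `"hudson"`.
#' @return an `fst_result` list: `fst`, `method`, `n_sites_used`.
#' @export
fst <- function(gm, set_a, set_b,
                method = c("weir_cockerham", "hudson")) {
  method <- match.arg(method)
  ia <- resolve_samples(gm, set_a)
  ib <- resolve_samples(gm, set_b)
  if (length(intersect(ia, ib))) stop("sample sets must be disjoint")
  if (length(ia) < 2 || length(ib) < 2) stop("need >= 2 samples per set")
  aa <- allele_counts(gm, ia)
  ab <- allele_counts(gm, ib)
  use <- aa$n >= 2L & ab$n >= 2L
  p1 <- aa$alt[use] / aa$n[use]
  p2 <- ab$alt[use] / ab$n[use]
  poly <- (aa$alt[use] + ab$alt[use]) > 0L &
    (aa$alt[use] + ab$alt[use]) < (aa$n[use] + ab$n[use])
  if (!any(poly)) stop("all sites monomorphic across the two sets")
  if (method == "hudson") {
    n1 <- aa$n[use]
    n2 <- ab$n[use]
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    val <- sum(num[poly]) / sum(den[poly])
  } else {
    # Weir & Cockerham 1984, two populations, per-site a/b/c components
    g1 <- gm$genotypes[ia, use, drop = FALSE]
    g2 <- gm$genotypes[ib, use, drop = FALSE]
    n1 <- colSums(!is.na(g1))
    n2 <- colSums(!is.na(g2))
    h1 <- colSums(g1 == 1L, na.rm = TRUE) / n1
    h2 <- colSums(g2 == 1L, na.rm = TRUE) / n2
    r <- 2
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    ok <- poly & is.finite(a) & is.finite(b) & is.finite(cc)
    val <- sum(a[ok]) / sum((a + b + cc)[ok])
  }
  structure(list(fst = val, method = method, n_sites_used = sum(poly)),
            class = "fst_result")
}

#' MAF and LD pruning of sites
#'
#' Removes sites with minor allele frequency below `maf_min`, then applies
#' greedy windowed LD pruning: sliding windows of `window` sites advancing
#' by `step`, dropping the later site of any retained pair with genotype
#' correlation `r^2 > r2_max` (pairwise-complete dosage correlation).
#'
#' @param gm a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param r2_max maximum allowed pairwise r^2 (default 0.2).
#' @param window,step window size and slide step, in sites.
#' @return integer vector of retained site indices (relative to `gm`).
#' @export
ld_prune <- function(gm, maf_min = 0.01, r2_max = 0.2, window = 50L,
                     step = 5L) {
  ac <- allele_counts(gm)
  maf <- pmin(ac$alt, ac$n - ac$alt) / pmax(ac$n, 1L)
  keepable <- which(ac$n >= 2L & maf >= maf_min)
  if (!length(keepable)) return(integer(0))
  alive <- rep(TRUE, length(keepable))
  g <- gm$genotypes[, keepable, drop = FALSE]
  start <- 1L
  repeat {
    end <- min(start + window - 1L, length(keepable))
    idx <- start:end
    live <- idx[alive[idx]]
    if (length(live) > 1) {
      cm <- suppressWarnings(cor(g[, live, drop = FALSE],
                                 use = "pairwise.complete.obs"))
      cm[is.na(cm)] <- 0
      for (a in seq_along(live)) {
        if (!alive[live[a]]) next
        for (b in seq_len(a - 1L)) {
          if (alive[live[b]] && cm[a, b]^2 > r2_max) {
            alive[live[a]] <- FALSE
            break
          }
        }
      }
    }
    if (end >= length(keepable)) break
    start <- start + step
  }
  keepable[alive]
}

#' Principal components of the genotype matrix
#'
#' Mean-imputes missing dosages, standardizes each site by
#' `sqrt(2 p (1 - p))` (frequency standardization), and eigendecomposes
#' the sample covariance. Returns the top `k` sample coordinates and the
#' explained-variance fractions.
#'
#' @param gm a [genotype_matrix()].
#' @param pruned_sites optional site subset (e.g. from [ld_prune()]).
#' @param k number of components.
#' @return list with `coords` (data frame: sample_id, label, PC1..PCk) and
#'   `explained` (length-k fractions).
#' @export
pca_coords <- function(gm, pruned_sites = NULL, k = 2L) {
  g <- gm$genotypes
  if (!is.null(pruned_sites)) g <- g[, pruned_sites, drop = FALSE]
  n <- nrow(g)
  if (n < 2) stop("need >= 2 samples")
  p <- colMeans(g, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  g <- g[, keep, drop = FALSE]
  p <- p[keep]
  x <- sweep(g, 2, 2 * p)
  x[is.na(x)] <- 0
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  rank <- min(n - 1L, ncol(x))
  if (k > rank) stop("k exceeds the rank of the standardized matrix (", rank, ")")
  sv <- svd(x, nu = k, nv = 0)
  coords <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  colnames(coords) <- paste0("PC", seq_len(k))
  explained <- (sv$d^2 / sum(sv$d^2))[seq_len(k)]
  list(coords = data.frame(sample_id = gm$samples$sample_id,
                           label = gm$samples$label, coords,
                           stringsAsFactors = FALSE),
       explained = explained)
}
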