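#' Pairwise robust kinship coefficients
#'
#' KING-robust within-cohort estimator from unphased genotypes. For each
#' pair, over the sites complete in both samples:
#' `phi = (N_het_het - 2 N_opp_hom) / (N_het_i + N_het_j)`, where
#' `N_het_het` counts sites heterozygous in both, `N_opp_hom` counts
#' opposite homozygotes, and `N_het_i` is the heterozygote count of sample
#' i at the compared sites. `ibs0 = N_opp_hom / n_sites_used` is the
#' fraction of compared sites sharing zero alleles. Expected phi: 0.5 for
#' duplicates, 0.25 for first-degree relatives, 0.125 for second degree;
#' ibs0 near zero separates parent-offspring from full siblings.
#'
#' @param gm a [genotype_matrix()].
#' @param set sample subset (default all).
#' @return data frame with one row per unordered pair: `sample_i`,
#'   `sample_j`, `phi` (`NA` when no jointly heterozygous information),
#'   `ibs0`, `n_sites_used`.
#' @export
pairwise_kinship <- function(gm, set = NULL) {
  idx <- if (is.null(set)) seq_len(nrow(gm$genotypes)) else
    resolve_samples(gm, set)
  if (length(idx) < 2) stop("need >= 2 samples")
  g <- gm$genotypes[idx, , drop = FALSE]
  ids <- gm$samples$sample_id[idx]
  n <- length(idx)
  out <- vector("list", n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) {
    gi <- g[i, ]
    for (j in (i + 1):n) {
      gj <- g[j, ]
      ok <- !is.na(gi) & !is.na(gj)
      nuse <- sum(ok)
      a <- gi[ok]
      b <- gj[ok]
      n_hh <- sum(a == 1L & b == 1L)
      n_opp <- sum((a == 0L & b == 2L) | (a == 2L & b == 0L))
      n_het_i <- sum(a == 1L)
      n_het_j <- sum(b == 1L)
      phi <- if (n_het_i + n_het_j > 0)
        (n_hh - 2 * n_opp) / (n_het_i + n_het_j) else NA_real_
      k <- k + 1L
      out[[k]] <- data.frame(sample_i = ids[i], sample_j = ids[j],
                             phi = phi,
                             ibs0 = if (nuse > 0) n_opp / nuse else NA_real_,
                             n_sites_used = nuse,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Flag first-degree relative pairs and build an exclusion set
#'
#' Pairs with `phi` in `[phi_lo, phi_hi)` are flagged as first degree
#' (conventional band `2^-5/2` to `2^-3/2`). The exclusion set keeps the
#' lexicographically lowest sample id in each connected component of
#' flagged pairs and excludes the rest, so that no flagged pair survives
#' intact — the deterministic analogue of hand-removing relatives before
#' demographic analyses.
#'
#' @param results data frame from [pairwise_kinship()].
#' @param phi_lo,phi_hi first-degree phi band (default 0.177-0.354).
#' @return list with `pairs` (the input plus a logical `first_degree`
#'   column) and `exclude` (character vector of sample ids).
#' @export
flag_first_degree <- function(results, phi_lo = 0.177, phi_hi = 0.354) {
  flag <- !is.na(results$phi) & results$phi >= phi_lo & results$phi < phi_hi
  results$first_degree <- flag
  exclude <- character(0)
  if (any(flag)) {
    edges <- results[flag, c("sample_i", "sample_j")]
    nodes <- sort(unique(c(edges$sample_i, edges$sample_j)))
    comp <- seq_along(nodes)
    names(comp) <- nodes
    find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
    for (r in seq_len(nrow(edges))) {
      ri <- find(match(edges$sample_i[r], nodes))
      rj <- find(match(edges$sample_j[r], nodes))
      if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
    }
    roots <- vapply(seq_along(nodes), find, integer(1))
    for (root in unique(roots)) {
      members <- nodes[roots == root]
      exclude <- c(exclude, setdiff(members, min(members)))
    }
  }
  list(pairs = results, exclude = sort(exclude))
}
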