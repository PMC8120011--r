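#' Apparent fixed differences between two groups
#'
#' Sites at which every `group_a` sample is one homozygote and every
#' `group_b` sample the opposite homozygote, with complete data among the
#' panel-defining samples at the site. Optionally removes sites that are
#' polymorphic within a third subset (e.g. NSO/CSO differences not
#' segregating in barred owls). The panel records, per site, which allele
#' is the "A-species" allele, so profiles can be oriented.
#'
#' @param gm a [genotype_matrix()].
#' @param group_a,group_b disjoint, non-empty sample subsets.
#' @param exclude_segregating_in optional subset; sites polymorphic there
#'   are dropped from the panel.
#' @return a `fixed_difference_set`: `site_idx` (site indices in `gm`),
#'   `a_is_alt` (logical per panel site), `n_sites`, group metadata.
#' @export
fixed_differences <- function(gm, group_a, group_b,
                              exclude_segregating_in = NULL) {
  ia <- resolve_samples(gm, group_a)
  ib <- resolve_samples(gm, group_b)
  if (length(intersect(ia, ib))) stop("groups must be disjoint")
  if (!length(ia) || !length(ib)) stop("groups must be non-empty")
  ga <- gm$genotypes[ia, , drop = FALSE]
  gb <- gm$genotypes[ib, , drop = FALSE]
  complete <- colSums(is.na(ga)) == 0L & colSums(is.na(gb)) == 0L
  a_alt <- colSums(ga) == 2L * length(ia)   # all hom-alt in A
  a_ref <- colSums(ga) == 0L
  b_alt <- colSums(gb) == 2L * length(ib)
  b_ref <- colSums(gb) == 0L
  fixed <- complete & ((a_alt & b_ref) | (a_ref & b_alt))
  fixed[is.na(fixed)] <- FALSE
  excl_carries_alt <- NULL
  if (!is.null(exclude_segregating_in)) {
    ix <- resolve_samples(gm, exclude_segregating_in)
    gx <- gm$genotypes[ix, , drop = FALSE]
    alt <- colSums(gx, na.rm = TRUE)
    n <- 2L * colSums(!is.na(gx))
    segregating <- n > 0L & alt > 0L & alt < n
    fixed <- fixed & !segregating
    # record which (monomorphic) allele the excluded group carries, so
    # profiles can subtract its gamete contribution in hybrids
    excl_carries_alt <- ifelse(n == 0L, NA, alt == n)
  }
  idx <- which(fixed)
  structure(list(site_idx = idx,
                 a_is_alt = unname(a_alt[idx]),
                 excl_carries_a = if (is.null(excl_carries_alt)) NULL else
                   unname(excl_carries_alt[idx] == a_alt[idx]),
                 n_sites = length(idx),
                 group_a = gm$samples$sample_id[ia],
                 group_b = gm$samples$sample_id[ib]),
            class = "fixed_difference_set")
}

#' Write a fixed-difference panel as TSV
#' @param fds a [fixed_differences()] panel.
#' @param gm the `genotype_matrix` it was built from.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(fds, gm, path) {
  sites <- gm$sites[fds$site_idx, , drop = FALSE]
  a_allele <- ifelse(fds$a_is_alt, sites$alt, sites$ref)
  b_allele <- ifelse(fds$a_is_alt, sites$ref, sites$alt)
  write.table(data.frame(scaffold = sites$scaffold, position = sites$position,
                         a_allele = a_allele, b_allele = b_allele),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ancestry profile of one sample at a diagnostic panel
#'
#' Tabulates the sample's genotypes at the panel sites, oriented to the
#' A-species allele: `frac_A` is the fraction of A alleles,
#' `frac_het` the heterozygous fraction, `n_hom_A` the count of A-allele
#' homozygotes. The identity
#' `frac_A = (2 n_hom_A + n_het) / (2 n_sites_used)` holds exactly;
#' panel sites missing in the sample are skipped and counted.
#'
#' @param gm a [genotype_matrix()].
#' @param sample one sample id or index.
#' @param fds a [fixed_differences()] panel.
#' @return an `ancestry_profile` list.
#' @export
ancestry_profile <- function(gm, sample, fds) {
  if (fds$n_sites == 0) stop("empty fixed-difference panel")
  i <- resolve_samples(gm, sample)
  stopifnot(length(i) == 1)
  g <- gm$genotypes[i, fds$site_idx]
  dos_a <- ifelse(fds$a_is_alt, g, 2L - g)   # A-allele dosage
  ok <- !is.na(dos_a)
  n_used <- sum(ok)
  if (n_used == 0) stop("all panel sites missing in sample")
  n_hom_A <- sum(dos_a[ok] == 2L)
  n_het <- sum(dos_a[ok] == 1L)
  structure(list(sample_id = gm$samples$sample_id[i],
                 frac_A = (2 * n_hom_A + n_het) / (2 * n_used),
                 frac_het = n_het / n_used,
                 n_hom_A = n_hom_A, n_het = n_het,
                 n_sites_used = n_used,
                 n_sites_missing = fds$n_sites - n_used),
            class = "ancestry_profile")
}

#' Classify a hybrid from its ancestry profile
#'
#' Rule-based assignment against a species diagnostic panel:
#' `pure_B` when the A-allele fraction is at most `pure_max`; `F1` when
#' nearly all sites are heterozygous (`frac_het >= f1_het_min`) and the
#' A fraction sits near one half; `backcross_B` when the A fraction lies
#' in the first-backcross band (centred on the 25% expectation, widened
#' for recombination variance) with essentially no A homozygotes;
#' otherwise `complex`.
#'
#' @param profile an [ancestry_profile()].
#' @param min_sites minimum usable panel sites (default 100).
#' @param pure_max,f1_het_min,f1_band,backcross_band,hom_a_max thresholds.
#' @return one of `"pure_B"`, `"F1"`, `"backcross_B"`, `"complex"`.
#' @export
classify_hybrid <- function(profile, min_sites = 100L, pure_max = 0.01,
                            f1_het_min = 0.95, f1_band = c(0.45, 0.55),
                            backcross_band = c(0.15, 0.40),
                            hom_a_max = 0.01) {
  if (profile$n_sites_used < min_sites)
    stop("panel too small: ", profile$n_sites_used, " usable sites")
  fa <- profile$frac_A
  if (fa <= pure_max) return("pure_B")
  if (profile$frac_het >= f1_het_min && fa >= f1_band[1] && fa <= f1_band[2])
    return("F1")
  if (fa >= backcross_band[1] && fa <= backcross_band[2] &&
      profile$n_hom_A / profile$n_sites_used <= hom_a_max)
    return("backcross_B")
  "complex"
}

#' Subspecies ancestry profile at an NSO/CSO panel
#'
#' Same tabulation as [ancestry_profile()], restricted to a panel of
#' fixed differences between the two spotted-owl subspecies (built with
#' `exclude_segregating_in` = the barred-owl samples). Assuming one parent
#' of a hybrid is a barred owl, `frac_A` estimates the NSO share of the
#' spotted-owl-derived alleles: ~1 for an NSO parent, ~0 for a CSO parent,
#' intermediate for admixed spotted-owl ancestry.
#'
#' At each panel site the barred-owl parent's gamete carries the allele
#' fixed in barred owls (recorded by the panel's `exclude_segregating_in`
#' bookkeeping); subtracting it isolates the spotted-owl-derived allele.
#'
#' @inheritParams ancestry_profile
#' @param nso_cso_panel a [fixed_differences()] panel oriented NSO vs CSO
#'   and built with `exclude_segregating_in` = the barred-owl samples.
#' @return an `ancestry_profile`; `frac_A` is the NSO share of the
#'   spotted-owl-derived alleles.
#' @export
subspecies_profile <- function(gm, sample, nso_cso_panel) {
  if (is.null(nso_cso_panel$excl_carries_a))
    stop("panel must be built with exclude_segregating_in = the barred-owl samples")
  pr <- ancestry_profile(gm, sample, nso_cso_panel)
  i <- resolve_samples(gm, sample)
  g <- gm$genotypes[i, nso_cso_panel$site_idx]
  dos_a <- ifelse(nso_cso_panel$a_is_alt, g, 2L - g)
  ok <- !is.na(dos_a) & !is.na(nso_cso_panel$excl_carries_a)
  if (!any(ok)) stop("no usable panel sites with barred-owl background")
  so_derived <- dos_a[ok] - as.integer(nso_cso_panel$excl_carries_a[ok])
  pr$frac_A <- mean(pmin(1L, pmax(0L, so_derived)))
  pr$n_sites_used <- sum(ok)
  pr
}

#' Assign a mitochondrial haplotype to a maternal lineage
#'
#' Nearest-cluster assignment by Hamming distance against labeled
#' reference haplotypes (equal-length alignment). The margin is the
#' difference between the best distances of the runner-up cluster and the
#' winning cluster; assignments with margin below `min_margin` sites
#' return `"unknown"`.
#'
#' @param haplotype character vector (one sequence) of the query.
#' @param references character matrix of aligned reference sequences
#'   (rows) with `labels` per row.
#' @param labels cluster label per reference sequence.
#' @param min_margin minimum distance margin in sites (default 3).
#' @return list: `label`, `margin`, `best_distance`.
#' @export
assign_mtdna_lineage <- function(haplotype, references, labels,
                                 min_margin = 3L) {
  if (length(haplotype) != ncol(references))
    stop("query length does not match reference alignment")
  stopifnot(nrow(references) == length(labels))
  hq <- tolower(haplotype)
  d <- apply(references, 1, function(r) sum(tolower(r) != hq))
  best_per <- tapply(d, labels, min)
  ord <- order(best_per)
  margin <- if (length(best_per) > 1)
    best_per[ord[2]] - best_per[ord[1]] else Inf
  label <- if (margin < min_margin) "unknown" else names(best_per)[ord[1]]
  list(label = label, margin = unname(margin),
       best_distance = unname(best_per[ord[1]]))
}
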