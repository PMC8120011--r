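#' Exact Hardy-Weinberg test, excess-heterozygosity orientation
#'
#' Conditional exact test of Hardy-Weinberg proportions at one biallelic
#' site. Given the observed genotype counts, the distribution of the
#' heterozygote count conditional on the allele counts is enumerated
#' (Levene's conditional distribution), and the one-sided tail probability
#' of observing at least as many heterozygotes is returned. This is the
#' orientation used to flag excess-heterozygosity artifacts (e.g. mapping
#' collapse of paralogs) in joint call sets; a phred-scaled threshold on
#' this p-value is equivalent to GATK's ExcessHet annotation filter.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (hom-ref, het, hom-alt).
#' @param alternative `"excess_het"` (default): `P(het >= observed)`;
#'   `"two_sided"`: sum of all outcomes no more probable than the observed
#'   one.
#' @return the exact p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa,
                           alternative = c("excess_het", "two_sided")) {
  alternative <- match.arg(alternative)
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotyped diploid is required")
  nA <- 2L * n_AA + n_Aa
  minor <- min(nA, 2L * n - nA)
  # heterozygote counts share the parity of the minor allele count
  h <- seq(minor %% 2L, minor, by = 2L)
  # log P(n_Aa = h | n, nA) up to a constant:
  #   n! / (nAA! h! naa!) * 2^h, with nAA = (nA - h)/2 etc.
  ha <- (pmin(nA, 2L * n - nA) - h) / 2
  hb <- n - h - ha
  lp <- h * log(2) - lgamma(ha + 1) - lgamma(h + 1) - lgamma(hb + 1)
  lp <- lp - max(lp)
  p <- exp(lp) / sum(exp(lp))
  obs <- n_Aa
  if (alternative == "excess_het") {
    min(1, sum(p[h >= obs]))
  } else {
    min(1, sum(p[p <= p[match(obs, h)] * (1 + 1e-12)]))
  }
}

#' Phred-scale a probability
#'
#' `-10 * log10(p)`; e.g. p = 3.4e-6 maps to 54.69, the scale on which
#' HWE-filter thresholds are expressed in VCF annotations.
#'
#' @param p probability in (0, 1].
#' @return phred-scaled value.
#' @export
phred_from_p <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p must be in (0, 1]")
  -10 * log10(p)
}

#' Site and genotype filter configuration
#'
#' Defaults reproduce a GATK-style hard-filter pass for joint-called SNPs:
#' annotation thresholds `QD < 2.0 || FS > 60.0 || MQ < 40.0 ||
#' MQRankSum < -12.5 || ReadPosRankSum < -8.0 || SOR > 3.0`, a total-depth
#' cap at mean + 5 SD, an excess-heterozygosity HWE filter at p = 3.4e-6
#' (phred 54.69), and per-call GQ masking below 40.
#'
#' @param gq_min minimum genotype quality; calls below it are set missing.
#' @param hwe_p_threshold HWE excess-het p-value below which a site is
#'   removed.
#' @param depth_sd_multiplier sites with total depth above
#'   mean + multiplier * SD are removed.
#' @param hard_filter_thresholds named list of `list(op, cutoff)` per INFO
#'   annotation; a site failing any is removed. Sites lacking the
#'   annotation pass that rule.
#' @param drop_sites_with_missing if `TRUE`, [apply_site_filters()] ends by
#'   dropping sites with any missing genotype.
#' @param hwe_two_sided use the two-sided HWE exact test instead of the
#'   excess-heterozygosity orientation.
#' @return a `filter_config` list.
#' @export
filter_config <- function(gq_min = 40L,
                          hwe_p_threshold = 3.4e-6,
                          depth_sd_multiplier = 5,
                          hard_filter_thresholds = list(
                            QD = list("<", 2.0),
                            FS = list(">", 60.0),
                            MQ = list("<", 40.0),
                            MQRankSum = list("<", -12.5),
                            ReadPosRankSum = list("<", -8.0),
                            SOR = list(">", 3.0)),
                          drop_sites_with_missing = FALSE,
                          hwe_two_sided = FALSE) {
  stopifnot(gq_min >= 0, is.finite(hwe_p_threshold),
            is.finite(depth_sd_multiplier))
  structure(list(gq_min = as.integer(gq_min),
                 hwe_p_threshold = hwe_p_threshold,
                 depth_sd_multiplier = depth_sd_multiplier,
                 hard_filter_thresholds = hard_filter_thresholds,
                 drop_sites_with_missing = isTRUE(drop_sites_with_missing),
                 hwe_two_sided = isTRUE(hwe_two_sided)),
            class = "filter_config")
}

#' Apply site-level filters
#'
#' Removes sites in a fixed order: (1) non-biallelic / non-SNP records;
#' (2) hard annotation thresholds; (3) total-depth cap at
#' mean + k SD, with mean and SD computed over the sites retained after
#' steps 1-2; (4) HWE excess-heterozygosity filter; (5) optionally, sites
#' with any missing genotype. A per-rule attrition report is attached.
#'
#' @param gm a [genotype_matrix()].
#' @param cfg a [filter_config()].
#' @return the filtered `genotype_matrix`, with the report as a data frame
#'   in attribute `"filter_report"` (also retrievable via
#'   [filter_report()]).
#' @export
apply_site_filters <- function(gm, cfg = filter_config()) {
  report <- data.frame(rule = character(0), n_removed = integer(0),
                       stringsAsFactors = FALSE)
  note <- function(rule, n) rbind(report, data.frame(rule = rule, n_removed = n))

  keep <- rep(TRUE, ncol(gm$genotypes))
  if (!is.null(gm$sites$is_biallelic_snp)) {
    drop <- !gm$sites$is_biallelic_snp
    report <- note("biallelic_snp", sum(drop))
    keep <- keep & !drop
  } else report <- note("biallelic_snp", 0L)

  drop <- rep(FALSE, length(keep))
  for (ann in names(cfg$hard_filter_thresholds)) {
    v <- gm$sites[[ann]]
    if (is.null(v)) next
    thr <- cfg$hard_filter_thresholds[[ann]]
    fail <- if (thr[[1]] == "<") v < thr[[2]] else v > thr[[2]]
    fail[is.na(fail)] <- FALSE   # missing annotation passes (GATK convention)
    drop <- drop | fail
  }
  report <- note("hard_annotations", sum(drop & keep))
  keep <- keep & !drop

  dp <- gm$sites$total_depth
  if (!is.null(dp) && any(keep & !is.na(dp))) {
    m <- mean(dp[keep], na.rm = TRUE)
    s <- sd(dp[keep], na.rm = TRUE)
    cap <- m + cfg$depth_sd_multiplier * s
    drop <- keep & !is.na(dp) & dp > cap
    report <- note("depth_cap", sum(drop))
    keep <- keep & !drop
  } else report <- note("depth_cap", 0L)

  alt_side <- if (cfg$hwe_two_sided) "two_sided" else "excess_het"
  idx <- which(keep)
  if (length(idx)) {
    g <- gm$genotypes[, idx, drop = FALSE]
    n_aa <- colSums(g == 0L, na.rm = TRUE)
    n_het <- colSums(g == 1L, na.rm = TRUE)
    n_bb <- colSums(g == 2L, na.rm = TRUE)
    pv <- vapply(seq_along(idx), function(i) {
      if (n_aa[i] + n_het[i] + n_bb[i] < 1) return(1)
      hwe_exact_test(n_aa[i], n_het[i], n_bb[i], alternative = alt_side)
    }, numeric(1))
    drop_hwe <- idx[pv < cfg$hwe_p_threshold]
    report <- note("hwe_excess_het", length(drop_hwe))
    keep[drop_hwe] <- FALSE
  } else report <- note("hwe_excess_het", 0L)

  if (cfg$drop_sites_with_missing) {
    drop <- keep & colSums(is.na(gm$genotypes)) > 0L
    report <- note("missing_data", sum(drop))
    keep <- keep & !drop
  }

  out <- gm_subset(gm, sites = keep)
  attr(out, "filter_report") <- report
  out
}

#' Retrieve the attrition report left by [apply_site_filters()]
#' @param gm a filtered `genotype_matrix`.
#' @return data frame with columns `rule`, `n_removed`.
#' @export
filter_report <- function(gm) attr(gm, "filter_report")

#' Mask low-quality genotype calls
#'
#' Sets individual calls with GQ below `gq_min` to missing; sites are kept.
#'
#' @param gm a [genotype_matrix()] with GQ present.
#' @param gq_min minimum genotype quality (default 40).
#' @return the masked `genotype_matrix`.
#' @export
mask_low_gq <- function(gm, gq_min = 40L) {
  if (gq_min > 0 && is.null(gm$gq)) stop("genotype matrix has no GQ values")
  if (gq_min <= 0 || ncol(gm$genotypes) == 0L) return(gm)
  g <- gm$genotypes
  g[!is.na(gm$gq) & gm$gq < gq_min] <- NA_integer_
  g[is.na(gm$gq)] <- NA_integer_
  gm$genotypes <- g
  gm
}

#' Drop sites with any missing genotype
#' @param gm a [genotype_matrix()].
#' @return the `genotype_matrix` restricted to complete sites.
#' @export
drop_incomplete_sites <- function(gm) {
  gm_subset(gm, sites = colSums(is.na(gm$genotypes)) == 0L)
}

#' Exclude sites overlapping BED regions
#'
#' Removes sites falling inside user-supplied regions (e.g. repeats or
#' annotated exons). BED coordinates are 0-based half-open and converted to
#' the 1-based inclusive convention of the site table at the boundary.
#'
#' @param gm a [genotype_matrix()].
#' @param bed a data frame with columns chrom/start/end, or a path to a
#'   headerless 3+ column BED file.
#' @return the `genotype_matrix` with overlapping sites removed.
#' @export
exclude_bed_regions <- function(gm, bed) {
  if (is.character(bed)) {
    bed <- read.delim(bed, header = FALSE, stringsAsFactors = FALSE)[, 1:3]
  }
  names(bed)[1:3] <- c("chrom", "start", "end")
  drop <- rep(FALSE, ncol(gm$genotypes))
  for (chr in unique(bed$chrom)) {
    b <- bed[bed$chrom == chr, , drop = FALSE]
    on_chr <- which(gm$sites$scaffold == chr)
    if (!length(on_chr)) next
    pos <- gm$sites$position[on_chr]
    hit <- rep(FALSE, length(pos))
    for (k in seq_len(nrow(b)))
      hit <- hit | (pos > b$start[k] & pos <= b$end[k])
    drop[on_chr[hit]] <- TRUE
  }
  gm_subset(gm, sites = !drop)
}
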