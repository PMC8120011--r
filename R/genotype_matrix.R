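#' Genotype matrix container
#'
#' The central data structure of the package: a cohort of diploid samples
#' typed at biallelic SNPs. Genotypes are stored as alt-allele dosages
#' (0, 1, 2) with `NA` for missing calls, samples in rows and sites in
#' columns. Per-call genotype qualities (GQ) and per-site metadata
#' (scaffold, position, alleles, INFO annotations, total depth) ride along.
#'
#' @param genotypes integer matrix, samples x sites, values in
#'   `{0, 1, 2, NA}`. Row names are taken as sample ids if `samples` is
#'   missing.
#' @param samples data frame with columns `sample_id`, `label`, `sex`,
#'   `location` (one row per sample). Extra columns (e.g. simulation truth)
#'   are preserved.
#' @param sites data frame with columns `scaffold`, `position`, `ref`,
#'   `alt`; optional columns `total_depth`, `is_biallelic_snp`, and INFO
#'   annotations such as `QD`, `FS`, `MQ`.
#' @param gq optional integer matrix of genotype qualities, same shape as
#'   `genotypes`.
#' @param total_length optional total number of base pairs surveyed
#'   (variant + invariant); used as the denominator for per-base diversity.
#' @param haplotypes optional 0/1 integer matrix, `2 * n_samples` rows
#'   (haplotypes `2i - 1`, `2i` belong to sample `i`), same columns as
#'   `genotypes`. Carried by the simulators so that gamete-level operations
#'   (F1 and backcross construction) can respect phase.
#'
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, samples = NULL, sites = NULL, gq = NULL,
                            total_length = NULL, haplotypes = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  n <- nrow(genotypes)
  S <- ncol(genotypes)
  if (is.null(samples)) {
    ids <- rownames(genotypes)
    if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
    samples <- data.frame(sample_id = ids, label = "unknown", sex = "unknown",
                          location = "", stringsAsFactors = FALSE)
  }
  stopifnot(nrow(samples) == n)
  if (anyDuplicated(samples$sample_id))
    stop("sample ids must be unique within a cohort")
  if (is.null(sites)) {
    sites <- data.frame(scaffold = rep("chr1", S), position = seq_len(S),
                        ref = rep("A", S), alt = rep("T", S),
                        stringsAsFactors = FALSE)
  }
  stopifnot(nrow(sites) == S)
  if (!is.null(gq)) {
    gq <- as.matrix(gq)
    storage.mode(gq) <- "integer"
    stopifnot(all(dim(gq) == dim(genotypes)))
  }
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotypes must be alt-allele dosages in {0, 1, 2} or NA")
  rownames(genotypes) <- samples$sample_id
  structure(
    list(genotypes = genotypes, samples = samples, sites = sites, gq = gq,
         total_length = total_length, haplotypes = haplotypes),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d sites\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing calls: %.2f%%; GQ: %s; haplotypes: %s\n",
              100 * miss, if (is.null(x$gq)) "absent" else "present",
              if (is.null(x$haplotypes)) "absent" else "present"))
  if (!is.null(x$total_length))
    cat(sprintf("  surveyed length: %.3g bp\n", x$total_length))
  tab <- table(x$samples$label)
  cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

#' Subset a genotype matrix by samples and/or sites
#'
#' @param gm a [genotype_matrix()].
#' @param samples sample ids, logical mask, or integer indices (default all).
#' @param sites logical mask or integer indices of sites (default all).
#' @return a `genotype_matrix` restricted to the selection.
#' @export
gm_subset <- function(gm, samples = NULL, sites = NULL) {
  si <- seq_len(nrow(gm$genotypes))
  vi <- seq_len(ncol(gm$genotypes))
  if (!is.null(samples)) si <- resolve_samples(gm, samples)
  if (!is.null(sites)) vi <- vi[sites]
  hap <- gm$haplotypes
  if (!is.null(hap)) {
    hrows <- as.vector(rbind(2L * si - 1L, 2L * si))
    hap <- hap[hrows, vi, drop = FALSE]
  }
  genotype_matrix(gm$genotypes[si, vi, drop = FALSE],
                  samples = gm$samples[si, , drop = FALSE],
                  sites = gm$sites[vi, , drop = FALSE],
                  gq = if (is.null(gm$gq)) NULL else gm$gq[si, vi, drop = FALSE],
                  total_length = gm$total_length,
                  haplotypes = hap)
}

# Map a sample selector (ids, logical, or integer) to row indices.
resolve_samples <- function(gm, samples) {
  if (is.character(samples)) {
    idx <- match(samples, gm$samples$sample_id)
    if (anyNA(idx))
      stop("unknown sample id(s): ",
           paste(samples[is.na(idx)], collapse = ", "))
    idx
  } else {
    seq_len(nrow(gm$genotypes))[samples]
  }
}

# Alt-allele and total non-missing allele counts per site over a sample set.
allele_counts <- function(gm, samples = NULL) {
  g <- gm$genotypes
  if (!is.null(samples)) g <- g[resolve_samples(gm, samples), , drop = FALSE]
  nm <- colSums(!is.na(g))
  list(alt = colSums(g, na.rm = TRUE), n = 2L * nm, n_samples = nm)
}
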