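#' Pipeline configuration
#'
#' Bundles the file paths, filter settings, demographic model, group
#' labels and seeds for an end-to-end run. Files are validated at
#' construction; seeds are recorded in every output header.
#'
#' @param vcf path to the cohort VCF.
#' @param metadata path to the sample-metadata TSV.
#' @param depth path to a per-scaffold depth TSV (optional; skips the
#'   genome-partition stage when absent).
#' @param mtdna path to an mtDNA reference FASTA plus query haplotypes
#'   (optional).
#' @param exclude_bed optional BED of regions to exclude.
#' @param out_dir output directory (created).
#' @param filter a [filter_config()].
#' @param model a [demographic_model()].
#' @param groups named list of label vectors: `species_a` (e.g.
#'   NSO + CSO), `species_b`, `focal` (e.g. WBO), `reference` (e.g. EBO),
#'   `subspecies_a`, `subspecies_b`.
#' @param total_length total base pairs surveyed by the VCF (variant +
#'   invariant); sets the denominator of per-base diversity statistics.
#'   `NULL` reports diversity per analyzed variant site.
#' @param seed integer master seed.
#' @param T_grid split-time grid for the ratio curve.
#' @param n_replicates replicates per grid point.
#' @param n_perm Monte-Carlo permutations.
#' @param curve_segments segments per curve replicate.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(vcf, metadata, depth = NULL, mtdna = NULL,
                            exclude_bed = NULL, out_dir = "results",
                            filter = filter_config(),
                            model = demographic_model(),
                            groups = list(species_a = c("NSO", "CSO"),
                                          species_b = c("EBO", "WBO"),
                                          focal = "WBO", reference = "EBO",
                                          subspecies_a = "NSO",
                                          subspecies_b = "CSO"),
                            total_length = NULL,
                            seed = 1L,
                            T_grid = seq(0, 0.006, by = 0.001),
                            n_replicates = 10, n_perm = 200,
                            curve_segments = 2000) {
  for (p in c(vcf, metadata, depth, mtdna, exclude_bed))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  structure(list(vcf = vcf, metadata = metadata, depth = depth,
                 mtdna = mtdna, exclude_bed = exclude_bed,
                 out_dir = out_dir, filter = filter, model = model,
                 groups = groups, total_length = total_length,
                 seed = as.integer(seed), T_grid = T_grid,
                 n_replicates = n_replicates, n_perm = n_perm,
                 curve_segments = curve_segments),
            class = "pipeline_config")
}

# Provenance-headed TSV writer: every pipeline output records the package
# version, the config hash and the seed.
write_tsv_prov <- function(df, path, cfg_hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# strixpop %s | config=%s | seed=%d",
                     as.character(utils::packageVersion("strixpop")),
                     cfg_hash, seed), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

# Stage cache: recompute only when the stage's config slice changed.
stage_cached <- function(cache_dir, stage, key, compute) {
  path <- file.path(cache_dir, paste0(stage, "-", key, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  val <- compute()
  saveRDS(val, path)
  val
}

#' Run the end-to-end analysis pipeline
#'
#' Stages, in order: site/genotype filtering; scaffold classification and
#' sex inference (when a depth table is supplied); kinship screening with
#' first-degree exclusions; diversity and differentiation statistics;
#' hybrid panels and classification; private-allele split-time estimation
#' (permutation test, simulated ratio curve, moment estimate, year
#' conversion). Each stage writes a provenance-headed TSV under
#' `cfg$out_dir`; the expensive ratio-curve stage is cached by config
#' hash so estimator reruns reuse it.
#'
#' @param cfg a [pipeline_config()].
#' @return (invisibly) a list with every stage's result tables.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cache_dir <- file.path(cfg$out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  cfg_hash <- substr(rlang::hash(cfg[setdiff(names(cfg), "out_dir")]), 1, 12)
  stage <- function(name) message("[strixpop] stage: ", name)
  res <- list(config_hash = cfg_hash)

  stage("filter")
  gm <- read_vcf(cfg$vcf, metadata = cfg$metadata)
  gm$total_length <- cfg$total_length
  if (!is.null(cfg$exclude_bed)) gm <- exclude_bed_regions(gm, cfg$exclude_bed)
  if (!is.null(gm$gq)) gm <- mask_low_gq(gm, cfg$filter$gq_min)
  gm <- apply_site_filters(gm, cfg$filter)
  res$filter_report <- filter_report(gm)
  write_tsv_prov(res$filter_report, file.path(cfg$out_dir, "filter_report.tsv"),
                 cfg_hash, cfg$seed)
  gm_complete <- drop_incomplete_sites(gm)

  if (!is.null(cfg$depth)) {
    stage("genome_partition")
    dt <- read_depth_table(cfg$depth)
    sexes <- setNames(gm$samples$sex, gm$samples$sample_id)
    known <- sexes[sexes %in% c("male", "female")]
    if (length(unique(known)) == 2) {
      dt_known <- dt
      dt_known$mean_depth <- dt$mean_depth[, names(known), drop = FALSE]
      dt_known$missingness <- dt$missingness[, names(known), drop = FALSE]
      res$scaffold_classes <- classify_autosome_z(dt_known, known)
      res$w_scaffolds <- identify_w(dt_known, known)
      zc <- res$scaffold_classes
      z_marker <- zc$scaffold[zc$class == "Z"][1]
      if (!is.na(z_marker) && length(res$w_scaffolds)) {
        res$sex_calls <- infer_sex(dt, z_marker, res$w_scaffolds[1])
        write_tsv_prov(res$sex_calls, file.path(cfg$out_dir, "sex_calls.tsv"),
                       cfg_hash, cfg$seed)
      }
      write_tsv_prov(res$scaffold_classes,
                     file.path(cfg$out_dir, "scaffold_classes.tsv"),
                     cfg_hash, cfg$seed)
    }
  }

  stage("kinship")
  labels <- gm$samples$label
  demog_ids <- gm$samples$sample_id[labels %in%
                                      unlist(cfg$groups[c("species_a", "species_b",
                                                          "focal", "reference")])]
  kin <- pairwise_kinship(gm_complete, demog_ids)
  fd <- flag_first_degree(kin)
  res$kinship <- fd$pairs
  res$excluded <- fd$exclude
  write_tsv_prov(fd$pairs, file.path(cfg$out_dir, "kinship.tsv"),
                 cfg_hash, cfg$seed)
  writeLines(fd$exclude, file.path(cfg$out_dir, "excluded_samples.txt"))
  keep <- setdiff(gm$samples$sample_id, fd$exclude)
  gmk <- gm_subset(gm_complete, samples = keep)

  stage("popstats")
  lab <- gmk$samples$label
  pops <- intersect(c(cfg$groups$subspecies_a, cfg$groups$subspecies_b,
                      cfg$groups$focal, cfg$groups$reference),
                    unique(lab))
  stat_rows <- list()
  for (p in pops) {
    ids <- gmk$samples$sample_id[lab == p]
    if (length(ids) < 2) next
    dv <- nucleotide_diversity_within(gmk, ids)
    td <- tryCatch(tajimas_d(gmk, ids), error = function(e) NA_real_)
    stat_rows[[p]] <- data.frame(population = p, pi = dv$pi, S = dv$S,
                                 tajima_d = td, n_samples = dv$n_samples,
                                 n_sites_used = dv$n_sites_used)
  }
  res$diversity <- do.call(rbind, stat_rows)
  fst_rows <- list()
  pairs <- list(c(cfg$groups$subspecies_a, cfg$groups$subspecies_b),
                c(cfg$groups$focal, cfg$groups$reference))
  for (pr in pairs) {
    ia <- gmk$samples$sample_id[lab == pr[1]]
    ib <- gmk$samples$sample_id[lab == pr[2]]
    if (length(ia) < 2 || length(ib) < 2) next
    f <- tryCatch(fst(gmk, ia, ib), error = function(e) NULL)
    if (!is.null(f))
      fst_rows[[paste(pr, collapse = "_")]] <-
        data.frame(pop_a = pr[1], pop_b = pr[2], fst = f$fst,
                   method = f$method, n_sites_used = f$n_sites_used)
  }
  res$fst <- do.call(rbind, fst_rows)
  if (!is.null(res$diversity))
    write_tsv_prov(res$diversity, file.path(cfg$out_dir, "diversity.tsv"),
                   cfg_hash, cfg$seed)
  if (!is.null(res$fst))
    write_tsv_prov(res$fst, file.path(cfg$out_dir, "fst.tsv"),
                   cfg_hash, cfg$seed)

  stage("hybrids")
  so_ids <- gmk$samples$sample_id[lab %in% cfg$groups$species_a]
  bo_ids <- gmk$samples$sample_id[lab %in% cfg$groups$species_b]
  hyb_ids <- gm_complete$samples$sample_id[gm_complete$samples$label == "hybrid"]
  if (length(so_ids) && length(bo_ids)) {
    panel <- fixed_differences(gmk, so_ids, bo_ids)
    res$panel_size <- panel$n_sites
    if (panel$n_sites >= 100 && length(hyb_ids)) {
      prof_rows <- lapply(hyb_ids, function(h) {
        pr <- ancestry_profile(gm_complete, h, panel_on(gm_complete, gmk, panel))
        data.frame(sample_id = h, frac_A = pr$frac_A, frac_het = pr$frac_het,
                   n_hom_A = pr$n_hom_A, n_sites_used = pr$n_sites_used,
                   class = classify_hybrid(pr))
      })
      res$hybrid_profiles <- do.call(rbind, prof_rows)
      write_tsv_prov(res$hybrid_profiles,
                     file.path(cfg$out_dir, "hybrid_profiles.tsv"),
                     cfg_hash, cfg$seed)
    }
  }

  stage("split_time")
  focal_ids <- gmk$samples$sample_id[lab %in% cfg$groups$focal]
  ref_ids <- gmk$samples$sample_id[lab %in% cfg$groups$reference]
  if (length(focal_ids) >= 1 && length(ref_ids) >= 2) {
    des <- group_design(focal_ids, ref_ids)
    pat <- private_allele_counts(gmk, des)
    res$private_alleles <- pat
    write_tsv_prov(pat, file.path(cfg$out_dir, "private_alleles.tsv"),
                   cfg_hash, cfg$seed)
    r_obs <- ratio_statistic(pat)
    perm <- permutation_test(gmk, des, n_perm = cfg$n_perm, seed = cfg$seed)
    curve <- stage_cached(cache_dir, "ratio_curve",
                          substr(rlang::hash(list(cfg$model, cfg$T_grid,
                                                  cfg$n_replicates,
                                                  cfg$curve_segments,
                                                  cfg$seed, length(ref_ids))),
                                 1, 12),
                          function() expected_ratio_curve(
                            cfg$model, cfg$T_grid, cfg$n_replicates,
                            seed = cfg$seed, n_ref = length(ref_ids),
                            n_segments = cfg$curve_segments))
    write_tsv_prov(as.data.frame(curve),
                   file.path(cfg$out_dir, "ratio_curve.tsv"),
                   cfg_hash, cfg$seed)
    est <- tryCatch({
      T_hat <- estimate_split_time(r_obs, curve)
      yrs <- split_time_to_years(T_hat, cfg$model$Ne, cfg$model$gen_time)
      iv <- uncertainty_interval(yrs$years, 5)
      data.frame(r_obs = r_obs, p_value = perm$p_value, T_hat = T_hat,
                 years = yrs$years, years_rounded = yrs$years_rounded,
                 interval_low = iv["low"], interval_high = iv["high"],
                 Ne = cfg$model$Ne, gen_time = cfg$model$gen_time)
    }, error = function(e) data.frame(r_obs = r_obs, p_value = perm$p_value,
                                      T_hat = NA_real_, years = NA_real_,
                                      years_rounded = NA_real_,
                                      interval_low = NA_real_,
                                      interval_high = NA_real_,
                                      Ne = cfg$model$Ne,
                                      gen_time = cfg$model$gen_time))
    res$split_time <- est
    write_tsv_prov(est, file.path(cfg$out_dir, "split_time.tsv"),
                   cfg_hash, cfg$seed)
  }
  invisible(res)
}

# A panel built on the relative-filtered matrix refers to site indices in
# that matrix; re-anchor it onto another matrix sharing site identities.
panel_on <- function(gm_target, gm_source, panel) {
  key_t <- paste(gm_target$sites$scaffold, gm_target$sites$position)
  key_s <- paste(gm_source$sites$scaffold, gm_source$sites$position)
  idx <- match(key_s[panel$site_idx], key_t)
  ok <- !is.na(idx)
  panel$site_idx <- idx[ok]
  panel$a_is_alt <- panel$a_is_alt[ok]
  panel$n_sites <- sum(ok)
  panel
}

#' Generate the small synthetic fixture cohort
#'
#' Writes a deterministic, desk-scale cohort (VCF, metadata TSV, depth
#' TSV, mtDNA FASTA) to a directory: a four-population two-species cohort
#' with constructed F1 and backcross hybrids, per-scaffold depth with ZW
#' dosage, and a two-cluster mtDNA alignment.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @param n_segments segments to simulate (default 300).
#' @return (invisibly) a list of the written paths and the cohort object.
#' @export
make_fixtures <- function(dir = tempfile("fixtures"), seed = 1L,
                          n_segments = 300) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- cohort_spec(n_nso = 4, n_cso = 3, n_ebo = 6, n_wbo = 6,
                      n_f1 = 1, n_backcross = 1, seed = seed)
  gm <- simulate_two_species_cohort(spec, n_segments = n_segments)
  set.seed(seed + 1L)
  n <- nrow(gm$genotypes)
  gm$samples$sex <- rep(c("male", "female"), length.out = n)
  gm$gq <- matrix(pmin(99L, pmax(0L, as.integer(rnorm(length(gm$genotypes),
                                                      70, 15)))),
                  n, ncol(gm$genotypes))
  vcf <- file.path(dir, "cohort.vcf")
  meta <- file.path(dir, "metadata.tsv")
  write_vcf(gm, vcf)
  write_sample_metadata(gm, meta)
  scaffolds <- data.frame(
    name = c(sprintf("auto%d", 1:4), "scafZ", "scafW", "scafW_short"),
    length = c(rep(2e6, 4), 1.5e6, 1.2e6, 9e4),
    class = c(rep("autosome", 4), "Z", "W", "W"),
    stringsAsFactors = FALSE)
  dt <- simulate_depth_table(gm$samples, scaffolds, base_depth = 30,
                             noise_cv = 0.08, seed = seed + 2L)
  depth <- file.path(dir, "depth.tsv")
  write_depth_table(dt, depth)
  mt <- simulate_mtdna(n_so = 4, n_bo = 6, divergence = 0.05, length = 800,
                       seed = seed + 3L)
  fasta <- file.path(dir, "mtdna.fasta")
  write_fasta_alignment(mt$alignment, fasta)
  invisible(list(dir = dir, vcf = vcf, metadata = meta, depth = depth,
                 mtdna = fasta, cohort = gm, depth_table = dt, mtdna_sim = mt))
}
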