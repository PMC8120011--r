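#' Demographic model for the split-time simulations
#'
#' Parameter bundle for the two-population isolation model used by the
#' private-allele split-time estimator, and for the nested two-species
#' cohort generator. Defaults are the analysis conditions: diploid
#' effective size 120,000 (from barred-owl nucleotide diversity),
#' mutation rate 4.6e-9 /site/generation, recombination rate equal to the
#' mutation rate, 10-kb segments mimicking a ~1-Gb genome in 100,000
#' independent pieces, and a 5-year generation time.
#'
#' @param Ne diploid effective population size.
#' @param mu mutation rate per site per generation.
#' @param rec recombination rate per site per generation (used by the
#'   gamete-level hybrid constructors; the coalescent segments themselves
#'   are internally non-recombining).
#' @param T_split split time in units of `4 * Ne` generations.
#' @param segment_length segment length in bases.
#' @param n_segments number of independent segments per genome.
#' @param gen_time years per generation.
#' @param species_divergence_target expected between-species per-site
#'   divergence for the two-species generator.
#' @return a `demographic_model` list.
#' @export
demographic_model <- function(Ne = 120000, mu = 4.6e-9, rec = mu,
                              T_split = 0.0029, segment_length = 1e4,
                              n_segments = 1e5, gen_time = 5,
                              species_divergence_target = 0.007) {
  stopifnot(Ne > 0, mu >= 0, rec >= 0, T_split >= 0, n_segments >= 1,
            segment_length > 0, gen_time > 0)
  structure(list(Ne = Ne, mu = mu, rec = rec, T_split = T_split,
                 segment_length = segment_length,
                 n_segments = as.integer(n_segments), gen_time = gen_time,
                 species_divergence_target = species_divergence_target),
            class = "demographic_model")
}

# Run the C++ segment simulator and package the result.
# pops: data.frame(name, n_dip, size); events: data.frame(time, type, a, b)
# with type 0 = merge pop a into pop b, type 1 = resize pop a to size b,
# times in generations ago, sorted ascending.
run_coalescent <- function(pops, events, mu, segment_length, n_segments,
                           labels, haplotypes = FALSE) {
  events <- events[order(events$time), , drop = FALSE]
  sim <- sim_segments_cpp(as.integer(pops$n_dip), as.numeric(pops$size),
                          as.numeric(events$time), as.integer(events$type),
                          as.integer(events$a), as.numeric(events$b),
                          mu, segment_length, as.integer(n_segments),
                          haplotypes)
  S <- length(sim$seg)
  ord <- order(sim$seg, sim$pos)
  ids <- unlist(lapply(seq_len(nrow(pops)), function(j)
    sprintf("%s%02d", pops$name[j], seq_len(pops$n_dip[j]))))
  samples <- data.frame(sample_id = ids, label = rep(labels, pops$n_dip),
                        sex = "unknown", location = "simulated",
                        stringsAsFactors = FALSE)
  sites <- data.frame(scaffold = sprintf("seg%06d", sim$seg[ord]),
                      position = sim$pos[ord],
                      ref = rep("A", S), alt = rep("T", S),
                      stringsAsFactors = FALSE)
  geno <- sim$geno[, ord, drop = FALSE]
  hap <- if (haplotypes) sim$hap[, ord, drop = FALSE] else NULL
  genotype_matrix(geno, samples = samples, sites = sites,
                  total_length = n_segments * segment_length,
                  haplotypes = hap)
}

#' Simulate a two-population split cohort
#'
#' Coalescent simulation of `n_w` focal and `n_e` reference diploids under
#' a clean isolation model: both populations and their ancestor at size
#' `Ne`, splitting `T_split * 4 * Ne` generations ago. Each of
#' `n_segments` segments is an independent, internally non-recombining
#' genealogy; mutations follow the infinite-sites model with rate
#' `mu * segment_length` per generation of branch length.
#'
#' An optional bottleneck in the focal population after the split can be
#' requested to probe the estimator's insensitivity to post-split focal
#' demography.
#'
#' @param model a [demographic_model()]; `n_segments` may be overridden.
#' @param n_w,n_e diploid sample sizes (focal / reference).
#' @param seed integer RNG seed.
#' @param n_segments override of `model$n_segments`.
#' @param focal_bottleneck optional `list(start, end, factor)`: between
#'   `start` and `end` generations ago the focal population size is
#'   `Ne * factor` (must lie within the isolation period).
#' @param haplotypes keep the 0/1 haplotype matrix (needed for gamete-level
#'   constructions; off by default to save memory).
#' @return a [genotype_matrix()] with labels `WBO` (focal) and `EBO`
#'   (reference).
#' @export
simulate_split_cohort <- function(model = demographic_model(), n_w = 1,
                                  n_e = 12, seed = NULL,
                                  n_segments = model$n_segments,
                                  focal_bottleneck = NULL,
                                  haplotypes = FALSE) {
  if (n_w < 1 || n_e < 1) stop("sample sizes must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  T_gen <- model$T_split * 4 * model$Ne
  pops <- data.frame(name = c("W", "E"), n_dip = c(n_w, n_e),
                     size = c(model$Ne, model$Ne), stringsAsFactors = FALSE)
  events <- data.frame(time = T_gen, type = 0L, a = 0L, b = 1L)
  if (!is.null(focal_bottleneck)) {
    fb <- focal_bottleneck
    stopifnot(fb$start < fb$end, fb$end <= T_gen || T_gen == 0)
    events <- rbind(
      data.frame(time = fb$start, type = 1L, a = 0L, b = model$Ne * fb$factor),
      data.frame(time = fb$end, type = 1L, a = 0L, b = model$Ne),
      events)
  }
  run_coalescent(pops, events, model$mu, model$segment_length, n_segments,
                 labels = c("WBO", "EBO"), haplotypes = haplotypes)
}

#' Cohort specification for the two-species generator
#'
#' Default sample sizes mirror the study cohort: 8 NSO, 3 CSO, 12 EBO,
#' 13 WBO, with optional constructed hybrids appended.
#'
#' @param n_nso,n_cso,n_ebo,n_wbo diploids per population.
#' @param n_f1 number of F1 hybrids to construct (SO mother x BO father by
#'   default, alternating NSO/CSO mothers).
#' @param n_backcross number of F1 x WBO backcrosses to construct.
#' @param seed integer RNG seed, recorded in the output metadata.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_nso = 8, n_cso = 3, n_ebo = 12, n_wbo = 13,
                        n_f1 = 0, n_backcross = 0, seed = 1L) {
  stopifnot(n_nso >= 0, n_cso >= 0, n_ebo >= 0, n_wbo >= 0,
            n_f1 >= 0, n_backcross >= 0)
  structure(list(n_nso = n_nso, n_cso = n_cso, n_ebo = n_ebo, n_wbo = n_wbo,
                 n_f1 = n_f1, n_backcross = n_backcross,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a two-species, four-population cohort
#'
#' Nested isolation model emulating the study system: a deep split between
#' spotted owls (NSO + CSO) and barred owls (EBO + WBO) and shallow splits
#' within each species. Population sizes and split times are solved from
#' diversity targets under the standard identities `pi = 4 * Ne * mu`
#' (within) and `divergence = 2 * mu * t + pi_ancestral` (between), so the
#' realized expectations match: between-species divergence ~ 0.7%,
#' spotted-owl diversity ~ 1.4e-4, barred-owl diversity ~ 2.3e-3. The
#' EBO-WBO split time comes from `model$T_split` (in `4 * Ne_bo` units).
#'
#' @param spec a [cohort_spec()].
#' @param model a [demographic_model()]; `n_segments` may be overridden.
#' @param n_segments number of independent 10-kb segments.
#' @param pi_so,pi_bo within-species diversity targets.
#' @param pi_so_between between-subspecies (NSO vs CSO) diversity target,
#'   setting the NSO-CSO split time.
#' @param haplotypes keep haplotypes (default `TRUE`; needed to construct
#'   hybrids).
#' @return a [genotype_matrix()]; `samples$label` holds the true population
#'   of origin and constructed hybrids carry `truth_class` and
#'   `maternal_species` columns.
#' @export
simulate_two_species_cohort <- function(spec = cohort_spec(),
                                        model = demographic_model(),
                                        n_segments = model$n_segments,
                                        pi_so = 1.4e-4, pi_bo = 2.3e-3,
                                        pi_so_between = 1.69e-4,
                                        haplotypes = TRUE) {
  mu <- model$mu
  div <- model$species_divergence_target
  if (pi_so >= div || pi_bo >= div)
    stop("within-species diversity targets must be below the between-species divergence target")
  Ne_so <- pi_so / (4 * mu)
  Ne_bo <- pi_bo / (4 * mu)
  t_so <- max(0, (pi_so_between - pi_so) / (2 * mu))
  t_bo <- model$T_split * 4 * Ne_bo
  t_sp <- (div - pi_bo) / (2 * mu)   # ancestral size = Ne_bo
  if (t_sp <= max(t_so, t_bo))
    stop("species split time collides with within-species splits; targets inconsistent")
  set.seed(spec$seed)
  pops <- data.frame(name = c("NSO", "CSO", "EBO", "WBO"),
                     n_dip = c(spec$n_nso, spec$n_cso, spec$n_ebo, spec$n_wbo),
                     size = c(Ne_so, Ne_so, Ne_bo, Ne_bo),
                     stringsAsFactors = FALSE)
  events <- data.frame(
    time = c(t_bo, t_so, t_sp, t_sp + 1e-9),
    type = c(0L, 0L, 0L, 1L),
    a    = c(3L, 1L, 2L, 0L),
    b    = c(2, 0, 0, Ne_bo))
  gm <- run_coalescent(pops, events, mu, model$segment_length, n_segments,
                       labels = pops$name, haplotypes = haplotypes)
  gm$samples$truth_class <- "pure"
  gm$samples$maternal_species <- ifelse(gm$samples$label %in% c("NSO", "CSO"),
                                        "SO", "BO")
  if (spec$n_f1 > 0 || spec$n_backcross > 0)
    gm <- append_constructed_hybrids(gm, spec, model)
  gm
}

# Build and append the requested F1 and backcross individuals.
append_constructed_hybrids <- function(gm, spec, model) {
  so_ids <- gm$samples$sample_id[gm$samples$label %in% c("NSO", "CSO")]
  bo_ids <- gm$samples$sample_id[gm$samples$label %in% c("EBO", "WBO")]
  wbo_ids <- gm$samples$sample_id[gm$samples$label == "WBO"]
  if (!length(so_ids) || !length(bo_ids))
    stop("hybrid construction requires samples from both species")
  n_tot <- spec$n_f1 + spec$n_backcross
  for (k in seq_len(n_tot)) {
    mother <- so_ids[(k - 1) %% length(so_ids) + 1]
    father <- bo_ids[(k - 1) %% length(bo_ids) + 1]
    f1 <- make_f1(gm, mother, father, model = model)
    if (k <= spec$n_f1) {
      gm <- gm_append_sample(gm, f1, sprintf("HYB%02d", k),
                             truth_class = "F1", maternal_species = "SO")
    } else {
      bparent <- wbo_ids[(k - 1) %% max(1, length(wbo_ids)) + 1]
      bc <- make_backcross(gm, f1, bparent, model = model)
      gm <- gm_append_sample(gm, bc, sprintf("HYB%02d", k),
                             truth_class = "backcross_B",
                             maternal_species = "SO")
    }
  }
  gm
}

# Segment index per site (factor over scaffolds in order of appearance).
site_segments <- function(gm) {
  match(gm$sites$scaffold, unique(gm$sites$scaffold))
}

# Sample one gamete from a pair of haplotype rows. Crossovers per segment
# per meiosis are Poisson(rec * segment_length) at uniform positions; the
# starting haplotype is fair per segment.
sample_gamete <- function(hap_pair, seg, pos, rec, segment_length) {
  S <- ncol(hap_pair)
  pick <- integer(S)                       # 1 or 2: which haplotype at site
  for (s in unique(seg)) {
    idx <- which(seg == s)
    start <- sample(c(1L, 2L), 1)
    k <- rpois(1, rec * segment_length)
    if (k == 0) {
      pick[idx] <- start
    } else {
      bk <- sort(runif(k, 0, segment_length))
      n_before <- findInterval(pos[idx], bk)
      pick[idx] <- 1L + (start - 1L + n_before) %% 2L
    }
  }
  out <- ifelse(pick == 1L, hap_pair[1, ], hap_pair[2, ])
  as.integer(out)
}

# Haplotype rows for one sample; falls back to phasing homozygotes exactly
# and heterozygotes at random when the matrix carries no haplotypes.
sample_haplotypes <- function(gm, sample) {
  i <- resolve_samples(gm, sample)
  stopifnot(length(i) == 1)
  if (!is.null(gm$haplotypes) && nrow(gm$haplotypes) >= 2 * i) {
    gm$haplotypes[c(2L * i - 1L, 2L * i), , drop = FALSE]
  } else {
    g <- gm$genotypes[i, ]
    h1 <- ifelse(is.na(g), NA_integer_, as.integer(g >= 1L))
    h2 <- ifelse(is.na(g), NA_integer_, as.integer(g == 2L))
    flip <- !is.na(g) & g == 1L & runif(length(g)) < 0.5
    tmp <- h1[flip]; h1[flip] <- h2[flip]; h2[flip] <- tmp
    rbind(h1, h2)
  }
}

#' Construct an F1 offspring by gamete sampling
#'
#' One gamete is sampled from each parent per segment, with intra-segment
#' recombination (crossovers Poisson with mean `rec * segment_length` per
#' meiosis, uniform positions). The child's genotype is the gamete sum; a
#' site missing in a parent is missing in the child.
#'
#' @param gm a [genotype_matrix()] (haplotypes used when present).
#' @param parent_a,parent_b parent sample ids or indices; `parent_a` is the
#'   mother (used for mitochondrial bookkeeping).
#' @param seed optional RNG seed.
#' @param model a [demographic_model()] supplying `rec` and
#'   `segment_length`.
#' @return a `constructed_sample` list: `genotype`, `haplotypes` (2 x S),
#'   `mother`, `father`.
#' @export
make_f1 <- function(gm, parent_a, parent_b, seed = NULL,
                    model = demographic_model()) {
  if (!is.null(seed)) set.seed(seed)
  seg <- site_segments(gm)
  pos <- gm$sites$position
  ga <- sample_gamete(sample_haplotypes(gm, parent_a), seg, pos,
                      model$rec, model$segment_length)
  gb <- sample_gamete(sample_haplotypes(gm, parent_b), seg, pos,
                      model$rec, model$segment_length)
  structure(list(genotype = ga + gb, haplotypes = rbind(ga, gb),
                 mother = parent_a, father = parent_b),
            class = "constructed_sample")
}

#' Construct a first-generation backcross
#'
#' Gamete from a constructed F1 (recombining its two species haplotypes)
#' plus a gamete from a parental-population individual. At species
#' fixed-difference sites the expected minor-parent allele fraction is 25%
#' and no minor-parent homozygote can arise.
#'
#' @param gm a [genotype_matrix()].
#' @param f1 a `constructed_sample` from [make_f1()].
#' @param parent parental-population sample id or index (the mother of the
#'   backcross is taken to be the F1).
#' @param seed optional RNG seed.
#' @param model a [demographic_model()].
#' @return a `constructed_sample`.
#' @export
make_backcross <- function(gm, f1, parent, seed = NULL,
                           model = demographic_model()) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(f1, "constructed_sample"))
  seg <- site_segments(gm)
  pos <- gm$sites$position
  gf <- sample_gamete(f1$haplotypes, seg, pos, model$rec, model$segment_length)
  gp <- sample_gamete(sample_haplotypes(gm, parent), seg, pos,
                      model$rec, model$segment_length)
  structure(list(genotype = gf + gp, haplotypes = rbind(gf, gp),
                 mother = "F1", father = parent),
            class = "constructed_sample")
}

#' Append a constructed sample to a cohort
#'
#' @param gm a [genotype_matrix()].
#' @param child a `constructed_sample`.
#' @param sample_id id for the new sample.
#' @param label population label (default `"hybrid"`).
#' @param truth_class,maternal_species truth bookkeeping columns.
#' @return the extended `genotype_matrix`.
#' @export
gm_append_sample <- function(gm, child, sample_id, label = "hybrid",
                             truth_class = NA_character_,
                             maternal_species = NA_character_) {
  stopifnot(inherits(child, "constructed_sample"))
  geno <- rbind(gm$genotypes, child$genotype)
  rownames(geno) <- c(gm$samples$sample_id, sample_id)
  samp <- gm$samples
  newrow <- samp[1, , drop = FALSE]
  newrow[1, ] <- NA
  newrow$sample_id <- sample_id
  newrow$label <- label
  newrow$sex <- "unknown"
  newrow$location <- "constructed"
  if ("truth_class" %in% names(samp)) newrow$truth_class <- truth_class
  if ("maternal_species" %in% names(samp)) newrow$maternal_species <- maternal_species
  samp <- rbind(samp, newrow)
  gq <- gm$gq
  if (!is.null(gq)) gq <- rbind(gq, rep(99L, ncol(gq)))
  hap <- gm$haplotypes
  if (!is.null(hap)) hap <- rbind(hap, child$haplotypes)
  genotype_matrix(geno, samples = samp, sites = gm$sites, gq = gq,
                  total_length = gm$total_length, haplotypes = hap)
}

#' Simulate per-scaffold read-depth and missingness tables
#'
#' Emulates mean mapped read depth per scaffold per sample under avian ZW
#' dosage: autosomes at `base_depth` in both sexes; Z at `base_depth` in
#' males (ZZ) and half that in females (ZW); W at half depth in females and
#' ~0 in males, with male missingness ~1 on W. Noise is multiplicative
#' lognormal with coefficient of variation `noise_cv`.
#'
#' @param samples data frame with `sample_id` and `sex`
#'   (`"male"`/`"female"`).
#' @param scaffolds data frame with `name`, `length`, `class` in
#'   `{"autosome", "Z", "W"}`.
#' @param base_depth expected autosomal depth.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed optional RNG seed.
#' @return a `depth_table`: scaffold metadata plus depth and missingness
#'   matrices (scaffold x sample).
#' @export
simulate_depth_table <- function(samples, scaffolds, base_depth = 30,
                                 noise_cv = 0.1, seed = NULL) {
  stopifnot(base_depth > 0, noise_cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  ns <- nrow(scaffolds)
  n <- nrow(samples)
  female <- samples$sex == "female"
  expect <- matrix(base_depth, ns, n)
  zrow <- scaffolds$class == "Z"
  wrow <- scaffolds$class == "W"
  expect[zrow, female] <- base_depth / 2
  expect[wrow, female] <- base_depth / 2
  expect[wrow, !female] <- 0
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- matrix(exp(rnorm(ns * n, -sdlog^2 / 2, sdlog)), ns, n)
    expect <- expect * noise
  }
  missing <- matrix(0, ns, n)
  missing[wrow, !female] <- 1
  if (noise_cv > 0 && any(!wrow))
    missing[!wrow, ] <- matrix(runif(sum(!wrow) * n, 0, 0.02), sum(!wrow), n)
  dimnames(expect) <- dimnames(missing) <- list(scaffolds$name,
                                                samples$sample_id)
  depth_table(scaffolds, expect, missing)
}

#' Simulate a mitochondrial control-region alignment
#'
#' Two haplotype clusters (maternal lineages of the two species) separated
#' by approximately `divergence` per site, with small within-cluster
#' variation (one tenth of the between-cluster rate).
#'
#' @param n_so,n_bo haplotypes per cluster.
#' @param divergence between-cluster per-site divergence, in (0, 1).
#' @param length alignment length in bases.
#' @param seed optional RNG seed.
#' @param ids optional sequence names (`SO_mt1`, ... by default).
#' @return list with `alignment` (character matrix, sequences in rows) and
#'   `labels` (`"SO"`/`"BO"` per sequence).
#' @export
simulate_mtdna <- function(n_so, n_bo, divergence = 0.05, length = 1000,
                           seed = NULL, ids = NULL) {
  stopifnot(divergence > 0, divergence < 1, length > 0,
            n_so >= 0, n_bo >= 0)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("a", "c", "g", "t")
  mutate <- function(seq, rate) {
    hit <- runif(length(seq)) < rate
    if (any(hit))
      seq[hit] <- vapply(seq[hit], function(b)
        sample(setdiff(bases, b), 1), character(1))
    seq
  }
  root <- sample(bases, length, replace = TRUE)
  so_anc <- mutate(root, divergence)
  bo_anc <- root
  n <- n_so + n_bo
  aln <- matrix("", n, length)
  labels <- c(rep("SO", n_so), rep("BO", n_bo))
  for (i in seq_len(n)) {
    anc <- if (labels[i] == "SO") so_anc else bo_anc
    aln[i, ] <- mutate(anc, divergence / 10)
  }
  if (is.null(ids))
    ids <- c(sprintf("SO_mt%d", seq_len(n_so)), sprintf("BO_mt%d", seq_len(n_bo)))
  rownames(aln) <- ids
  list(alignment = aln, labels = setNames(labels, ids))
}

#' Write an alignment as FASTA
#' @param alignment character matrix, sequences in rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(alignment, path) {
  ape::write.FASTA(ape::as.DNAbin(alignment), path)
  invisible(path)
}

#' Read a FASTA alignment into a character matrix
#' @param path FASTA file of equal-length aligned sequences.
#' @return character matrix, sequences in rows.
#' @export
read_fasta_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1)
    stop("sequences are not aligned (unequal lengths)")
  as.character(as.matrix(dna))
}
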