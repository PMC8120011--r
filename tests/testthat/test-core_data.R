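# Hand-written 3-sample, 4-site VCF used for parser checks.
write_tiny_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"q\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"q\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsampA\tsampB\tsampC",
    "scaf1\t101\t.\tA\tT\t50\tPASS\tDP=90;QD=25.0\tGT:GQ\t0/0:99\t0/1:80\t1/1:70",
    "scaf1\t205\t.\tG\tC\t50\tPASS\tDP=85;QD=1.5\tGT:GQ\t0/1:35\t0/0:99\t./.:.",
    "scaf2\t42\t.\tT\tA\t50\tPASS\tDP=88;QD=30.0\tGT:GQ\t1/1:99\t1/1:99\t0/1:99",
    "scaf2\t99\t.\tC\tG,A\t50\tPASS\tDP=80;QD=12.0\tGT:GQ\t0/0:99\t0/1:99\t0/0:99"),
    path)
  path
}

test_that("read_vcf matches a hand-read transcription of the fixture", {
  path <- write_tiny_vcf(tempfile(fileext = ".vcf"))
  gm <- read_vcf(path)
  expect_equal(dim(gm), c(3L, 4L))
  expect_equal(gm$samples$sample_id, c("sampA", "sampB", "sampC"))
  expect_equal(unname(gm$genotypes[, 1]), c(0L, 1L, 2L))
  expect_equal(unname(gm$genotypes[, 2]), c(1L, 0L, NA_integer_))
  expect_equal(unname(gm$genotypes[, 3]), c(2L, 2L, 1L))
  expect_equal(gm$sites$position, c(101L, 205L, 42L, 99L))
  expect_equal(gm$sites$QD, c(25, 1.5, 30, 12))
  expect_equal(gm$sites$total_depth, c(90, 85, 88, 80))
  expect_equal(gm$sites$is_biallelic_snp, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(unname(gm$gq[, 2]), c(35L, 99L, NA_integer_))
})

test_that("metadata mismatches and malformed input are reported", {
  path <- write_tiny_vcf(tempfile(fileext = ".vcf"))
  md <- data.frame(sample_id = c("sampA", "sampB"), label = "NSO",
                   sex = "unknown", location = "")
  expect_error(read_vcf(path, metadata = md), "sampC")
  expect_error(read_vcf(tempfile(fileext = ".vcf")), "not found")
})

test_that("write_vcf / read_vcf round-trips genotypes, GQ and coordinates", {
  b <- fixture_bundle()
  gm <- b$cohort
  gm$gq <- matrix(99L, nrow(gm$genotypes), ncol(gm$genotypes))
  gm$gq[2, 5] <- 10L
  gm$genotypes[1, 3] <- NA_integer_
  out <- tempfile(fileext = ".vcf")
  write_vcf(gm, out)
  back <- read_vcf(out)
  expect_equal(unname(back$genotypes), unname(gm$genotypes))
  expect_equal(unname(back$gq), unname(gm$gq))
  expect_equal(back$sites$scaffold, gm$sites$scaffold)
  expect_equal(back$sites$position, gm$sites$position)
  # missing-data convention: the masked call is written ./.
  lines <- readLines(out)
  rec <- lines[grepl("^#", lines) == FALSE][3]
  expect_match(rec, "\\./\\.")
})

test_that("empty matrices round-trip as header-only VCFs", {
  gm <- genotype_matrix(matrix(integer(0), 2, 0),
                        samples = data.frame(sample_id = c("a", "b"),
                                             label = "x", sex = "unknown",
                                             location = ""))
  out <- tempfile(fileext = ".vcf")
  write_vcf(gm, out)
  expect_true(all(grepl("^#", readLines(out))))
  back <- read_vcf(out)
  expect_equal(ncol(back$genotypes), 0L)
})

test_that("HWE exact test matches enumeration oracles", {
  # monomorphic: no heterozygote can exceed the observed zero
  expect_equal(hwe_exact_test(5, 0, 0), 1)
  # all-heterozygote case against the full enumeration oracle
  expect_equal(hwe_exact_test(0, 26, 0), oracle_hwe_excess(0, 26, 0),
               tolerance = 1e-10)
  # random small configurations
  set.seed(4)
  for (i in 1:40) {
    cnt <- as.integer(rmultinom(1, sample(2:30, 1), c(0.4, 0.3, 0.3)))
    p <- hwe_exact_test(cnt[1], cnt[2], cnt[3])
    expect_equal(p, oracle_hwe_excess(cnt[1], cnt[2], cnt[3]),
                 tolerance = 1e-9)
  }
  # literal allele-slot enumeration for tiny cohorts
  for (cnt in list(c(1, 2, 1), c(0, 3, 1), c(2, 0, 2), c(1, 1, 3))) {
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 oracle_hwe_tiny(cnt[1], cnt[2], cnt[3]), tolerance = 1e-9)
  }
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
})

test_that("phred conversion is exact and rejects bad input", {
  expect_equal(phred_from_p(1), 0)
  expect_equal(phred_from_p(0.1), 10)
  expect_error(phred_from_p(0), "in \\(0, 1\\]")
  expect_error(phred_from_p(-1), "in \\(0, 1\\]")
})

# 10-site fixture with engineered filter violations.
filter_fixture <- function() {
  set.seed(9)
  geno <- matrix(sample(0:2, 60, replace = TRUE), 6, 10)
  sites <- data.frame(scaffold = "s1", position = 1:10 * 100,
                      ref = "A", alt = "G",
                      total_depth = c(100, 100, 100, 100, 100, 100, 100,
                                      100, 100, 100),
                      is_biallelic_snp = rep(TRUE, 10),
                      QD = c(1.0, 1.9, 0.5, rep(25, 7)),   # 3 fail QD < 2
                      FS = rep(10, 10))
  genotype_matrix(geno, sites = sites)
}

test_that("hard annotation filters remove exactly the violating sites", {
  gm <- filter_fixture()
  out <- apply_site_filters(gm, filter_config(hwe_p_threshold = 0))
  rep <- filter_report(out)
  expect_equal(rep$n_removed[rep$rule == "hard_annotations"], 3L)
  expect_equal(ncol(out$genotypes), 7L)
})

test_that("depth cap removes outliers relative to the retained sites", {
  set.seed(21)
  S <- 61L
  geno <- matrix(sample(0:2, 4 * S, replace = TRUE), 4, S)
  dp <- c(round(rnorm(S - 1, 100, 10)), 300)
  gm <- genotype_matrix(geno,
                        sites = data.frame(scaffold = "s1",
                                           position = seq_len(S),
                                           ref = "A", alt = "G",
                                           total_depth = dp,
                                           is_biallelic_snp = TRUE))
  # the outlier exceeds the cap computed on the fixture itself
  expect_gt(dp[S], mean(dp) + 5 * sd(dp))
  out <- apply_site_filters(gm, filter_config(hwe_p_threshold = 0))
  rep <- filter_report(out)
  expect_equal(rep$n_removed[rep$rule == "depth_cap"], 1L)
  expect_false(300 %in% out$sites$total_depth)
})

test_that("all-pass input is returned unchanged with an all-zero report", {
  gm <- filter_fixture()
  gm$sites$QD <- rep(25, 10)
  out <- apply_site_filters(gm, filter_config(hwe_p_threshold = 0))
  expect_equal(out$genotypes, gm$genotypes)
  expect_true(all(filter_report(out)$n_removed == 0L))
})

test_that("HWE filter drops excess-het sites at the phred-equivalent cutoff", {
  geno <- matrix(1L, 26, 2)                   # site 1: all 26 diploids het
  geno[, 2] <- rep(c(0L, 2L), 13)             # no heterozygotes at site 2
  gm <- genotype_matrix(geno)
  out <- apply_site_filters(gm, filter_config())
  rep <- filter_report(out)
  expect_equal(rep$n_removed[rep$rule == "hwe_excess_het"], 1L)
  expect_equal(ncol(out$genotypes), 1L)
})

test_that("filter report sums to the attrition and refiltering is stable", {
  b <- fixture_bundle()
  gm <- b$cohort
  set.seed(31)
  gm$sites$QD <- runif(ncol(gm$genotypes), 1, 30)
  gm$sites$total_depth <- rpois(ncol(gm$genotypes), 100)
  out <- apply_site_filters(gm, filter_config())
  rep <- filter_report(out)
  expect_equal(sum(rep$n_removed), ncol(gm$genotypes) - ncol(out$genotypes))
  # idempotence up to the depth cap (mean/SD recomputed on the survivors)
  out2 <- apply_site_filters(out, filter_config())
  rep2 <- filter_report(out2)
  expect_true(all(rep2$n_removed[rep2$rule != "depth_cap"] == 0L))
})

test_that("GQ masking blanks exactly the low-quality calls", {
  geno <- matrix(1L, 4, 5)
  gq <- matrix(99L, 4, 5)
  low <- rbind(c(1, 1), c(2, 3), c(3, 5), c(4, 2), c(1, 4), c(2, 5), c(3, 1))
  gq[low] <- 39L
  gm <- genotype_matrix(geno, gq = gq)
  out <- mask_low_gq(gm, 40L)
  expect_equal(sum(is.na(out$genotypes)), 7L)
  expect_equal(unname(is.na(out$genotypes)), gq < 40)
  expect_equal(mask_low_gq(gm, 0L)$genotypes, gm$genotypes)
  gm99 <- genotype_matrix(geno, gq = matrix(99L, 4, 5))
  expect_equal(mask_low_gq(gm99, 40L)$genotypes, gm99$genotypes)
})

test_that("drop_incomplete_sites keeps exactly the complete sites", {
  geno <- matrix(1L, 3, 5)
  geno[2, 2] <- NA_integer_
  geno[c(1, 3), 4] <- NA_integer_
  gm <- genotype_matrix(geno)
  out <- drop_incomplete_sites(gm)
  expect_equal(ncol(out$genotypes), 3L)
  expect_equal(out$sites$position, c(1L, 3L, 5L))
  complete <- genotype_matrix(matrix(1L, 3, 5))
  expect_equal(drop_incomplete_sites(complete)$genotypes, complete$genotypes)
})

test_that("BED exclusion uses 0-based half-open coordinates", {
  gm <- genotype_matrix(matrix(0L, 2, 4),
                        sites = data.frame(scaffold = "s1",
                                           position = c(100L, 101L, 150L, 151L),
                                           ref = "A", alt = "G"))
  bed <- data.frame(chrom = "s1", start = 100L, end = 150L)
  out <- exclude_bed_regions(gm, bed)
  # BED [100, 150) covers 1-based positions 101..150
  expect_equal(out$sites$position, c(100L, 151L))
})
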