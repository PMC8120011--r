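#' Read a VCF into a genotype matrix
#'
#' Parses a VCF v4.2 file (via \pkg{vcfR}) into a [genotype_matrix()].
#' Genotypes become alt-allele dosages; multiallelic and non-SNP records are
#' retained but flagged (`sites$is_biallelic_snp = FALSE`) for
#' [apply_site_filters()] to remove. Per-site total depth is taken from the
#' INFO `DP` field when present, otherwise summed over per-sample `DP`.
#'
#' @param path path to a VCF (optionally bgzipped).
#' @param metadata optional sample metadata: a data frame or path to a
#'   tab-separated file with header columns `sample_id`, `label`, `sex`,
#'   `location`. Every VCF sample must appear in it.
#' @param info_fields INFO annotations to carry into `sites` (numeric).
#' @return a `genotype_matrix`; sample order follows the VCF header.
#' @export
read_vcf <- function(path, metadata = NULL,
                     info_fields = c("QD", "FS", "MQ", "MQRankSum",
                                     "ReadPosRankSum", "SOR")) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF '", path, "': ",
                                           conditionMessage(e)))
  fix <- vcf@fix
  S <- nrow(fix)
  sample_ids <- colnames(vcf@gt)[-1]
  n <- length(sample_ids)

  if (S > 0L) {
    gt <- t(vcfR::extract.gt(vcf, element = "GT"))
    geno <- matrix(NA_integer_, n, S)
    clean <- gsub("\\|", "/", gt)
    geno[clean == "0/0"] <- 0L
    geno[clean %in% c("0/1", "1/0")] <- 1L
    geno[clean == "1/1"] <- 2L
    gq <- suppressWarnings(t(vcfR::extract.gt(vcf, element = "GQ",
                                              as.numeric = TRUE)))
    if (all(is.na(gq))) gq <- NULL
    alt <- fix[, "ALT"]
    ref <- fix[, "REF"]
    is_snp <- !is.na(alt) & !grepl(",", alt) &
      nchar(ref) == 1L & nchar(alt) == 1L &
      ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
    info_dp <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "DP")))
    if (all(is.na(info_dp))) {
      dp <- suppressWarnings(t(vcfR::extract.gt(vcf, element = "DP",
                                                as.numeric = TRUE)))
      info_dp <- if (all(is.na(dp))) rep(NA_real_, S) else
        colSums(dp, na.rm = TRUE)
    }
    sites <- data.frame(scaffold = fix[, "CHROM"],
                        position = as.integer(fix[, "POS"]),
                        ref = ref, alt = alt,
                        total_depth = info_dp,
                        is_biallelic_snp = is_snp,
                        stringsAsFactors = FALSE)
    for (f in info_fields) {
      v <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, f)))
      if (!all(is.na(v))) sites[[f]] <- v
    }
  } else {
    geno <- matrix(integer(0), n, 0)
    gq <- NULL
    sites <- data.frame(scaffold = character(0), position = integer(0),
                        ref = character(0), alt = character(0),
                        total_depth = numeric(0),
                        is_biallelic_snp = logical(0),
                        stringsAsFactors = FALSE)
  }

  samples <- NULL
  if (!is.null(metadata)) {
    md <- if (is.character(metadata)) read_sample_metadata(metadata) else metadata
    idx <- match(sample_ids, md$sample_id)
    if (anyNA(idx))
      stop("samples in VCF but not in metadata: ",
           paste(sample_ids[is.na(idx)], collapse = ", "))
    samples <- md[idx, , drop = FALSE]
    rownames(samples) <- NULL
  } else {
    samples <- data.frame(sample_id = sample_ids, label = "unknown",
                          sex = "unknown", location = "",
                          stringsAsFactors = FALSE)
  }
  rownames(geno) <- sample_ids
  genotype_matrix(geno, samples = samples, sites = sites, gq = gq)
}

#' Read a sample metadata table
#'
#' Tab-separated with header `sample_id`, `label`, `sex`, `location`.
#' @param path file path.
#' @return data frame.
#' @export
read_sample_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "label", "sex", "location")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  md
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits a plain-text VCF readable by [read_vcf()]. Missing genotypes are
#' written `./.`; GQ and per-site INFO annotations present in the object are
#' round-tripped.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write VCF: ", path))
  on.exit(close(con))
  sites <- gm$sites
  info_cols <- setdiff(names(sites),
                       c("scaffold", "position", "ref", "alt",
                         "total_depth", "is_biallelic_snp"))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=strixpop",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            info_cols, info_cols),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples$sample_id), collapse = "\t")), con)
  S <- ncol(gm$genotypes)
  if (S == 0L) return(invisible(path))

  gt_str <- matrix(".", nrow(gm$genotypes), S)
  gt_str[gm$genotypes == 0L] <- "0/0"
  gt_str[gm$genotypes == 1L] <- "0/1"
  gt_str[gm$genotypes == 2L] <- "1/1"
  gt_str[is.na(gm$genotypes)] <- "./."
  fmt <- "GT"
  if (!is.null(gm$gq)) {
    gqs <- ifelse(is.na(gm$gq), ".", as.character(gm$gq))
    gt_str <- matrix(paste(gt_str, gqs, sep = ":"), nrow(gm$genotypes), S)
    fmt <- "GT:GQ"
  }
  info <- rep("", S)
  if (!is.null(sites$total_depth)) {
    v <- sites$total_depth
    info <- ifelse(is.na(v), info, paste0("DP=", format(v, trim = TRUE,
                                                        scientific = FALSE)))
  }
  for (f in info_cols) {
    v <- sites[[f]]
    piece <- ifelse(is.na(v), NA,
                    paste0(f, "=", format(v, trim = TRUE, digits = 10)))
    info <- ifelse(is.na(piece), info,
                   ifelse(nzchar(info), paste(info, piece, sep = ";"), piece))
  }
  info[!nzchar(info)] <- "."
  recs <- paste(sites$scaffold, sites$position, ".", sites$ref, sites$alt,
                ".", "PASS", info, fmt, sep = "\t")
  body <- apply(gt_str, 2, paste, collapse = "\t")
  writeLines(paste(recs, body, sep = "\t"), con)
  invisible(path)
}

#' Write the sample metadata of a cohort as TSV
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(gm, path) {
  write.table(gm$samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
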