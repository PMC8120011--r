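#' Per-scaffold depth table
#'
#' Container for mean mapped read depth and missingness per scaffold per
#' sample, the inputs to sex-chromosome identification in a ZW system.
#'
#' @param scaffolds data frame with `name` and `length` (bases); an
#'   optional `class` column is preserved (simulation truth).
#' @param mean_depth numeric matrix, scaffold x sample, >= 0.
#' @param missingness numeric matrix in `[0, 1]`, scaffold x sample.
#' @return a `depth_table` list.
#' @export
depth_table <- function(scaffolds, mean_depth, missingness = NULL) {
  stopifnot(all(scaffolds$length > 0),
            nrow(mean_depth) == nrow(scaffolds))
  if (is.null(missingness))
    missingness <- matrix(0, nrow(mean_depth), ncol(mean_depth),
                          dimnames = dimnames(mean_depth))
  stopifnot(all(missingness >= 0 & missingness <= 1),
            all(dim(missingness) == dim(mean_depth)))
  structure(list(scaffolds = scaffolds, mean_depth = mean_depth,
                 missingness = missingness),
            class = "depth_table")
}

#' Write / read a depth table as TSV
#'
#' Long format: scaffold, length, class (if known), sample, mean_depth,
#' missingness.
#' @param dt a [depth_table()].
#' @param path file path.
#' @return `path` (write) or a `depth_table` (read).
#' @export
write_depth_table <- function(dt, path) {
  long <- expand.grid(scaffold = dt$scaffolds$name,
                      sample = colnames(dt$mean_depth),
                      stringsAsFactors = FALSE)
  long$length <- dt$scaffolds$length[match(long$scaffold, dt$scaffolds$name)]
  if (!is.null(dt$scaffolds$class))
    long$class <- dt$scaffolds$class[match(long$scaffold, dt$scaffolds$name)]
  long$mean_depth <- dt$mean_depth[cbind(match(long$scaffold, dt$scaffolds$name),
                                         match(long$sample, colnames(dt$mean_depth)))]
  long$missingness <- dt$missingness[cbind(match(long$scaffold, dt$scaffolds$name),
                                           match(long$sample, colnames(dt$mean_depth)))]
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_table
#' @export
read_depth_table <- function(path) {
  long <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  scaffolds <- unique(long[, intersect(c("scaffold", "length", "class"),
                                       names(long))])
  names(scaffolds)[1] <- "name"
  samples <- unique(long$sample)
  md <- matrix(NA_real_, nrow(scaffolds), length(samples),
               dimnames = list(scaffolds$name, samples))
  ms <- md
  ridx <- match(long$scaffold, scaffolds$name)
  cidx <- match(long$sample, samples)
  md[cbind(ridx, cidx)] <- long$mean_depth
  ms[cbind(ridx, cidx)] <- long$missingness
  depth_table(scaffolds, md, ms)
}

# Per-sample normalization: each sample's depths divided by its median
# depth over the given scaffold rows (all scaffolds on the first pass;
# the genome is dominated by autosomes, so that median is a reasonable
# autosomal baseline, refined on a second pass).
normalized_depth <- function(dt, rows = seq_len(nrow(dt$mean_depth))) {
  med <- apply(dt$mean_depth[rows, , drop = FALSE], 2, median)
  if (any(med <= 0)) stop("sample with non-positive median depth")
  sweep(dt$mean_depth, 2, med, "/")
}

#' Classify scaffolds as autosome or Z from sex-stratified depth
#'
#' Computes the female/male ratio of normalized mean depth per scaffold
#' (each sample normalized by its own median depth, removing library-size
#' effects). Z-linked scaffolds show half depth in ZW females: ratio in
#' `[0.35, 0.65]` is called `Z`, `[0.8, 1.2]` `autosome`, anything else
#' `unclassified` (an explicit gap rather than a forced call).
#'
#' @param dt a [depth_table()].
#' @param sexes character vector (`"male"`/`"female"`) per sample, in
#'   depth-table column order or named by sample id.
#' @param z_band,auto_band ratio bands for the two classes.
#' @return data frame: `scaffold`, `length`, `fm_ratio`, `class`.
#' @export
classify_autosome_z <- function(dt, sexes,
                                z_band = c(0.35, 0.65),
                                auto_band = c(0.8, 1.2)) {
  sexes <- align_sexes(dt, sexes)
  if (!any(sexes == "male") || !any(sexes == "female"))
    stop("need at least one male and one female")
  classify_pass <- function(rows) {
    nd <- normalized_depth(dt, rows)
    f <- rowMeans(nd[, sexes == "female", drop = FALSE])
    m <- rowMeans(nd[, sexes == "male", drop = FALSE])
    ratio <- ifelse(m > 0, f / m, NA_real_)
    cls <- rep("unclassified", length(ratio))
    cls[!is.na(ratio) & ratio >= z_band[1] & ratio <= z_band[2]] <- "Z"
    cls[!is.na(ratio) & ratio >= auto_band[1] & ratio <= auto_band[2]] <-
      "autosome"
    list(ratio = ratio, cls = cls)
  }
  # first pass normalizes on all scaffolds; the second renormalizes on
  # the provisional autosomes, removing the pull of sex-linked scaffolds
  p1 <- classify_pass(seq_len(nrow(dt$mean_depth)))
  p <- if (any(p1$cls == "autosome"))
    classify_pass(which(p1$cls == "autosome")) else p1
  data.frame(scaffold = dt$scaffolds$name, length = dt$scaffolds$length,
             fm_ratio = p$ratio, class = p$cls, stringsAsFactors = FALSE)
}

#' Identify W-linked scaffolds from male missingness
#'
#' W-linked sequence is absent in ZZ males, so W scaffolds are those of at
#' least `min_length` bases with missingness above `missing_min` in every
#' male sample.
#'
#' @param dt a [depth_table()].
#' @param sexes per-sample sexes (see [classify_autosome_z()]).
#' @param min_length minimum scaffold length (default 100 kb).
#' @param missing_min male missingness threshold (default 0.99).
#' @return character vector of W scaffold names.
#' @export
identify_w <- function(dt, sexes, min_length = 1e5, missing_min = 0.99) {
  sexes <- align_sexes(dt, sexes)
  if (!any(sexes == "male") || !any(sexes == "female"))
    stop("need at least one male and one female")
  mm <- dt$missingness[, sexes == "male", drop = FALSE]
  all_missing <- apply(mm, 1, function(x) all(x > missing_min))
  dt$scaffolds$name[all_missing & dt$scaffolds$length >= min_length]
}

#' Infer sample sex from marker-scaffold depth
#'
#' A sample is called `female` when the W marker shows real coverage
#' (> 0.1x its autosome-median depth) and the Z marker shows reduced
#' dosage (< 0.75x); `male` when the W marker is empty and Z is at full
#' dosage (>= 0.75x); contradictory profiles return `unknown`.
#'
#' @param dt a [depth_table()].
#' @param z_marker,w_marker names of a Z-linked and a W-linked scaffold.
#' @return data frame: `sample_id`, `z_rel`, `w_rel`, `sex`.
#' @export
infer_sex <- function(dt, z_marker, w_marker) {
  rn <- dt$scaffolds$name
  if (!(z_marker %in% rn) || !(w_marker %in% rn))
    stop("marker scaffold absent from depth table")
  auto <- setdiff(rn, c(z_marker, w_marker))
  med <- apply(dt$mean_depth[auto, , drop = FALSE], 2, median)
  if (any(med <= 0)) stop("sample with non-positive autosome-median depth")
  z_rel <- dt$mean_depth[z_marker, ] / med
  w_rel <- dt$mean_depth[w_marker, ] / med
  sex <- ifelse(w_rel > 0.1 & z_rel < 0.75, "female",
                ifelse(w_rel <= 0.1 & z_rel >= 0.75, "male", "unknown"))
  data.frame(sample_id = colnames(dt$mean_depth), z_rel = as.numeric(z_rel),
             w_rel = as.numeric(w_rel), sex = as.character(sex),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Accept sexes as a plain vector (column order) or named by sample id.
align_sexes <- function(dt, sexes) {
  ids <- colnames(dt$mean_depth)
  if (!is.null(names(sexes))) {
    idx <- match(ids, names(sexes))
    if (anyNA(idx)) stop("sexes missing for: ",
                         paste(ids[is.na(idx)], collapse = ", "))
    sexes <- sexes[idx]
  }
  if (length(sexes) != length(ids))
    stop("sexes must match the depth-table samples")
  unname(sexes)
}
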