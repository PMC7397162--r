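#' Read a biallelic SNP genotype matrix
#'
#' Reads a delimited text file with lines in rows and markers in columns;
#' the first column holds line ids. Calls must be coded 0/1/2 (0 =
#' homozygous minor allele, 1 = heterozygous, 2 = homozygous major allele)
#' with `NA` or empty for missing. Markers that are entirely missing are an
#' error.
#'
#' @param path Path to a CSV/TSV file.
#' @return A genotype tibble: column `line` plus one numeric column per
#'   marker.
#' @export
read_genotypes <- function(path) {
  df <- read_delim_auto(path)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    abort(sprintf("'%s': empty or malformed genotype file", path))
  }
  names(df)[1] <- "line"
  df$line <- as.character(df$line)
  if (anyDuplicated(df$line)) abort("duplicate line ids in genotype file")
  for (j in setdiff(names(df), "line")) df[[j]] <- as.numeric(df[[j]])
  validate_genotypes(tibble::as_tibble(df))
}

#' Validate a genotype table
#'
#' @param geno Genotype tibble (`line` column plus marker columns).
#' @param allow_dosage Allow real-valued calls in `[0, 2]` (e.g. after mean
#'   imputation) instead of strict 0/1/2.
#' @return `geno`, invisibly validated (returned visibly for piping).
#' @export
validate_genotypes <- function(geno, allow_dosage = FALSE) {
  m <- geno_matrix(geno)
  obs <- m[!is.na(m)]
  if (allow_dosage) {
    if (any(obs < 0 | obs > 2)) abort("genotype dosages must lie in [0, 2]")
  } else if (!all(obs %in% c(0, 1, 2))) {
    bad <- obs[!obs %in% c(0, 1, 2)][1]
    abort(sprintf("genotype call outside {0, 1, 2}: %s", format(bad)))
  }
  all_miss <- colSums(!is.na(m)) == 0L
  if (any(all_miss)) {
    abort(sprintf(
      "marker(s) with all calls missing: %s",
      paste(colnames(m)[all_miss], collapse = ", ")
    ))
  }
  geno
}

# Internal: genotype tibble -> numeric matrix with line rownames.
geno_matrix <- function(geno, id_col = "line") {
  pheno_matrix(geno, id_col = id_col)
}

#' Per-marker allele frequency and missingness
#'
#' The allele frequency is `p = mean(calls) / 2` over observed calls
#' (heterozygotes count as one minor allele) and the minor allele frequency
#' is `min(p, 1 - p)`, so MAF is invariant to swapping the 0/2 coding.
#'
#' @param geno Genotype tibble.
#' @return A tibble with columns `marker`, `maf`, `missing_rate`, `n_obs`.
#' @export
#' @examples
#' g <- tibble::tibble(line = as.character(1:5), m1 = c(0, 0, 1, 2, 2))
#' marker_stats(g)
marker_stats <- function(geno) {
  m <- geno_matrix(geno)
  n <- nrow(m)
  n_obs <- colSums(!is.na(m))
  p <- colMeans(m, na.rm = TRUE) / 2
  tibble::tibble(
    marker = colnames(m),
    maf = unname(pmin(p, 1 - p)),
    missing_rate = unname(1 - n_obs / n),
    n_obs = as.integer(unname(n_obs))
  )
}

#' Marker quality control
#'
#' Removes markers with minor allele frequency at or below `maf_threshold`
#' or with missingness above `miss_threshold` (defaults mirror the usual
#' MAF > 0.05, missing <= 20% filter), then optionally replaces remaining
#' missing calls by the marker's observed mean (a real-valued dosage).
#'
#' @param geno Genotype tibble.
#' @param maf_threshold Markers kept only if `maf > maf_threshold`.
#' @param miss_threshold Markers kept only if `missing_rate <= miss_threshold`.
#' @param impute `"mean"` (default) or `"none"`.
#' @return The filtered (and possibly imputed) genotype tibble.
#' @export
marker_qc <- function(geno, maf_threshold = 0.05, miss_threshold = 0.20,
                      impute = c("mean", "none")) {
  impute <- match.arg(impute)
  stats <- marker_stats(geno)
  keep <- stats$maf > maf_threshold & stats$missing_rate <= miss_threshold
  if (!any(keep)) abort("all markers removed by QC thresholds")
  m <- geno_matrix(geno)[, stats$marker[keep], drop = FALSE]
  if (impute == "mean" && anyNA(m)) {
    mu <- colMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mu[idx[, 2]]
  }
  out <- matrix_to_pheno(m)
  out
}
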