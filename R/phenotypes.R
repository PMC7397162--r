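#' Build a trait-environment item key
#'
#' Items (the "columns" of an IBCF phenotype table) are trait-environment
#' combinations rendered as a single string key
#' `trait_location_year[_stage]`, e.g. `"GY_LND_2015"` or
#' `"NDVI_PUL_2016_heading"`. Bare labels such as `"A"` are also valid keys
#' (a trait with no environment qualifier).
#'
#' @param trait Trait label (e.g. `"GY"`, `"HD"`, `"NDVI"`).
#' @param location Optional location label (e.g. `"LND"`).
#' @param year Optional integer season label.
#' @param stage Optional developmental-stage label for spectral traits.
#' @return Character vector of item keys.
#' @export
#' @examples
#' make_item_key("GY", "LND", 2015)
make_item_key <- function(trait, location = NULL, year = NULL, stage = NULL) {
  parts <- list(trait, location, year, stage)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  do.call(paste, c(parts, sep = "_"))
}

#' Parse trait-environment item keys
#'
#' Splits keys of the form `trait_location_year[_stage]` back into their
#' components. Keys with fewer than three `_`-separated parts keep only the
#' leading components (a bare key is all trait).
#'
#' @param items Character vector of item keys.
#' @return A tibble with columns `item`, `trait`, `location`, `year`
#'   (integer) and `stage`; absent components are `NA`.
#' @export
#' @examples
#' parse_item_key(c("GY_LND_2015", "NDVI_PUL_2016_heading", "A"))
parse_item_key <- function(items) {
  parts <- strsplit(items, "_", fixed = TRUE)
  take <- function(p, i) if (length(p) >= i) p[[i]] else NA_character_
  tibble::tibble(
    item = items,
    trait = vapply(parts, take, character(1), 1L),
    location = vapply(parts, take, character(1), 2L),
    year = suppressWarnings(as.integer(vapply(parts, take, character(1), 3L))),
    stage = vapply(parts, take, character(1), 4L)
  )
}

# Internal: wide phenotype tibble -> numeric matrix with line rownames.
pheno_matrix <- function(pheno, id_col = "line") {
  stopifnot(is.data.frame(pheno))
  if (!id_col %in% names(pheno)) {
    abort(sprintf("phenotype table must have a '%s' column", id_col))
  }
  ids <- as.character(pheno[[id_col]])
  if (anyDuplicated(ids)) abort("duplicate line ids in phenotype table")
  items <- setdiff(names(pheno), id_col)
  if (length(items) == 0L) abort("phenotype table has no item columns")
  m <- as.matrix(as.data.frame(lapply(pheno[items], as.numeric)))
  dimnames(m) <- list(ids, items)
  m
}

# Internal: numeric matrix -> wide phenotype tibble.
matrix_to_pheno <- function(m, id_col = "line") {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(!!id_col := rownames(m)), out)
}

#' Validate a wide phenotype table
#'
#' A phenotype table is a tibble whose first column `line` holds unique line
#' ids and whose remaining columns are numeric trait-environment items;
#' missing cells are `NA`. Every item must have at least one observed value.
#'
#' @param pheno A wide phenotype tibble.
#' @return `pheno`, invisibly, after validation.
#' @export
validate_phenotypes <- function(pheno) {
  m <- pheno_matrix(pheno)
  if (!all(is.finite(m) | is.na(m))) {
    abort("phenotype values must be finite where observed")
  }
  empty <- colSums(!is.na(m)) == 0L
  if (any(empty)) {
    abort(sprintf(
      "item(s) with no observed values: %s",
      paste(colnames(m)[empty], collapse = ", ")
    ))
  }
  invisible(pheno)
}

#' Read a phenotype table
#'
#' Reads a delimited text file (comma- or tab-separated, autodetected from
#' the extension) into a wide phenotype tibble. The wide dialect expects the
#' first column to hold line ids and the remaining columns one item each.
#' The long dialect expects columns `line`, `trait`, `location`, `year`,
#' optionally `stage`, and `value`, and is pivoted to wide using
#' [make_item_key()]. Missing cells are empty fields or `NA`.
#'
#' @param path Path to a CSV/TSV file.
#' @param dialect `"wide"` (default) or `"long"`.
#' @return A wide phenotype tibble (column `line` plus one numeric column
#'   per item).
#' @export
read_phenotypes <- function(path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  df <- read_delim_auto(path)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    abort(sprintf("'%s': empty or malformed phenotype file", path))
  }
  if (dialect == "wide") {
    names(df)[1] <- "line"
    df$line <- as.character(df$line)
    if (anyDuplicated(df$line)) abort("duplicate line ids in phenotype file")
    for (j in setdiff(names(df), "line")) {
      v <- df[[j]]
      if (is.character(v)) {
        num <- suppressWarnings(as.numeric(v))
        bad <- !is.na(v) & v != "" & v != "NA" & is.na(num)
        if (any(bad)) {
          abort(sprintf("non-numeric value in item '%s': %s", j, v[bad][1]))
        }
        v <- num
      }
      df[[j]] <- as.numeric(v)
    }
    validate_phenotypes(df)
    return(tibble::as_tibble(df))
  }
  needed <- c("line", "trait", "value")
  if (!all(needed %in% names(df))) {
    abort("long dialect requires columns line, trait, value (plus optional location, year, stage)")
  }
  df$line <- as.character(df$line)
  if (is.character(df$value)) {
    num <- suppressWarnings(as.numeric(df$value))
    bad <- !is.na(df$value) & df$value != "" & df$value != "NA" & is.na(num)
    if (any(bad)) abort(sprintf("non-numeric value: %s", df$value[bad][1]))
    df$value <- num
  }
  long <- dplyr::mutate(df, item = make_item_key(
    .data$trait,
    if ("location" %in% names(df)) df$location else NULL,
    if ("year" %in% names(df)) df$year else NULL,
    if ("stage" %in% names(df)) df$stage else NULL
  ))
  dup <- dplyr::count(long, .data$line, .data$item)
  dup <- dplyr::filter(dup, .data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf(
      "duplicate cell for line '%s', item '%s'", dup$line[1], dup$item[1]
    ))
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(long, "line", "item", "value"),
    names_from = "item", values_from = "value"
  )
  validate_phenotypes(wide)
  wide
}

#' Write a phenotype table
#'
#' @param pheno A wide phenotype tibble.
#' @param path Output CSV/TSV path (delimiter from extension).
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  validate_phenotypes(pheno)
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(pheno, path, na = "NA")
  } else {
    readr::write_csv(pheno, path, na = "NA")
  }
  invisible(path)
}

# Delimiter autodetection by extension; defaults to comma.
read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0L) abort(sprintf("'%s': empty file", path))
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    na = c("", "NA"))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    na = c("", "NA"))
  }
}

#' Intersect phenotype and genotype tables on shared lines
#'
#' Lines present in one table but not the other are dropped with a warning;
#' both tables are returned in the same (phenotype) line order.
#'
#' @param pheno Wide phenotype tibble.
#' @param geno Genotype tibble (see [read_genotypes()]).
#' @return A list with elements `pheno` and `geno`.
#' @export
align_lines <- function(pheno, geno) {
  shared <- intersect(pheno$line, geno$line)
  if (length(shared) == 0L) abort("no lines shared between phenotypes and genotypes")
  dropped <- length(unique(c(pheno$line, geno$line))) - length(shared)
  if (dropped > 0L) {
    warn(sprintf("dropping %d line(s) not present in both tables", dropped))
  }
  list(
    pheno = pheno[match(shared, pheno$line), , drop = FALSE],
    geno = geno[match(shared, geno$line), , drop = FALSE]
  )
}
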