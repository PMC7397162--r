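#' Standardize a phenotype table per item
#'
#' Each trait-environment item j is centred and scaled with the mean and the
#' population (n-divisor) standard deviation of its observed cells:
#' `Z_ij = (y_ij - mu_j) / sigma_j`. The population convention is what
#' reproduces the reference worked example; the sample (n-1) convention does
#' not.
#'
#' @param pheno Wide phenotype tibble.
#' @param params Optional precomputed parameter tibble (columns `item`,
#'   `mu`, `sigma`) to apply instead of estimating from `pheno`; used by the
#'   next-season scenario where masked columns have no observed cells.
#' @return A list with elements `z` (wide tibble of standardized values,
#'   same shape and missingness as `pheno`) and `params` (tibble with
#'   columns `item`, `mu`, `sigma`, `n_obs`).
#' @export
#' @examples
#' tab1 <- read_phenotypes(system.file("extdata", "table1_phenotypes.csv",
#'   package = "ibcfgs"))
#' standardize_phenotypes(tab1)$params
standardize_phenotypes <- function(pheno, params = NULL) {
  # With precomputed params a column may be entirely missing (a masked
  # target item), so full validation only applies when estimating.
  m <- pheno_matrix(if (is.null(params)) validate_phenotypes(pheno) else pheno)
  if (is.null(params)) {
    n_obs <- colSums(!is.na(m))
    if (any(n_obs < 2L)) {
      abort(sprintf(
        "item(s) with fewer than 2 observed values: %s",
        paste(colnames(m)[n_obs < 2L], collapse = ", ")
      ))
    }
    mu <- colMeans(m, na.rm = TRUE)
    sigma <- apply(m, 2, pop_sd)
    if (any(sigma == 0)) {
      abort(sprintf(
        "constant item(s) cannot be standardized: %s",
        paste(colnames(m)[sigma == 0], collapse = ", ")
      ))
    }
    params <- tibble::tibble(
      item = colnames(m), mu = unname(mu), sigma = unname(sigma),
      n_obs = as.integer(n_obs)
    )
  } else {
    if (!all(colnames(m) %in% params$item)) {
      abort("params must cover every item in the table")
    }
    params <- params[match(colnames(m), params$item), , drop = FALSE]
    if (any(params$sigma <= 0)) abort("params sigma must be positive")
  }
  z <- sweep(sweep(m, 2, params$mu, "-"), 2, params$sigma, "/")
  list(z = matrix_to_pheno(z), params = params)
}

# Population (n-divisor) standard deviation over observed values.
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}
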