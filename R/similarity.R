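#' Item-item similarity matrix
#'
#' Pairwise-complete Pearson correlation between item columns: the weight
#' between items j and j' is computed over the lines where both are
#' observed. Pairs with fewer than two complete observations, or with zero
#' variance over the complete pairs, are undefined: they are stored as 0 and
#' flagged, and the predictor treats them as weight 0.
#'
#' Pearson correlation is scale-invariant, so the same matrix results from
#' raw or standardized columns (over identical complete pairs).
#'
#' @param z Wide tibble of (standardized) phenotype values.
#' @return A `similarity_matrix` object: list with `w` (items x items
#'   weight matrix, diagonal 1), `n_pairs` (complete-pair counts) and
#'   `defined` (logical matrix).
#' @export
similarity_matrix <- function(z) {
  m <- pheno_matrix(z)
  obs <- !is.na(m)
  n_pairs <- crossprod(obs * 1)
  w <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  defined <- n_pairs >= 2L & !is.na(w)
  w[!defined] <- 0
  diag(w) <- 1
  diag(defined) <- TRUE
  storage.mode(n_pairs) <- "integer"
  new_similarity(w, n_pairs = n_pairs, defined = defined)
}

new_similarity <- function(w, n_pairs = NULL, defined = NULL) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  if (is.null(defined)) defined <- matrix(TRUE, nrow(w), ncol(w), dimnames = dimnames(w))
  structure(
    list(w = w, n_pairs = n_pairs, defined = defined, items = colnames(w)),
    class = "similarity_matrix"
  )
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix: %d items>\n", length(x$items)))
  print(round(x$w, 3))
  und <- sum(!x$defined[upper.tri(x$defined)])
  if (und > 0) cat(sprintf("%d undefined pair(s) stored as weight 0\n", und))
  invisible(x)
}

#' @rdname similarity_matrix
#' @param x A `similarity_matrix`.
#' @param ... Unused.
#' @return `tidy()` returns a long tibble with one row per ordered item
#'   pair: `item1`, `item2`, `weight`, `n_pairs`, `defined`.
#' @method tidy similarity_matrix
#' @export
tidy.similarity_matrix <- function(x, ...) {
  tibble::tibble(
    item1 = rep(x$items, times = length(x$items)),
    item2 = rep(x$items, each = length(x$items)),
    weight = as.vector(x$w),
    n_pairs = if (is.null(x$n_pairs)) NA_integer_ else as.vector(x$n_pairs),
    defined = as.vector(x$defined)
  )
}

#' Read / write a similarity matrix as square CSV
#'
#' The file format is a square table whose first column and header both hold
#' the item keys, so an externally supplied weight matrix can be used
#' verbatim. Supplied matrices may be (mildly) asymmetric; prediction for
#' target item J uses row J.
#'
#' @param path CSV path.
#' @return `read_similarity()` returns a `similarity_matrix`;
#'   `write_similarity()` returns `path` invisibly.
#' @export
read_similarity <- function(path) {
  df <- read_delim_auto(path)
  items <- as.character(df[[1]])
  w <- as.matrix(as.data.frame(lapply(df[-1], as.numeric)))
  if (nrow(w) != ncol(w) || !identical(items, colnames(df)[-1])) {
    abort("similarity file must be square with matching row and column items")
  }
  dimnames(w) <- list(items, items)
  if (any(abs(w) > 1 + 1e-8)) abort("similarity weights must lie in [-1, 1]")
  if (any(abs(diag(w) - 1) > 1e-8)) abort("similarity diagonal must be 1")
  new_similarity(w)
}

#' @rdname read_similarity
#' @param sim A `similarity_matrix`.
#' @export
write_similarity <- function(sim, path) {
  stopifnot(inherits(sim, "similarity_matrix"))
  df <- dplyr::bind_cols(
    tibble::tibble(item = sim$items),
    tibble::as_tibble(sim$w, .name_repair = "minimal")
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' Heatmap of an item-item similarity matrix
#'
#' @param object A `similarity_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot similarity_matrix
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$item2, levels = object$items),
    y = factor(.data$item1, levels = rev(object$items)),
    fill = .data$weight
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "w") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
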