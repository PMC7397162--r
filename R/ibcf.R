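#' Impute missing phenotypes by item-based collaborative filtering
#'
#' For each unobserved cell (line i, target item J), the standardized
#' prediction is the absolute-weight-normalized weighted average of the
#' line's observed standardized values,
#' \deqn{\hat z_{iJ} = \sum_{j' \in N_i(J)} z_{ij'} w_{Jj'} \big/
#'       \sum_{j' \in N_i(J)} |w_{Jj'}|,}
#' where the neighborhood N_i(J) is every item observed for line i (possibly
#' restricted by `top_k` / `min_abs_weight`), and the phenotype-scale
#' prediction back-transforms with the target item's mean and population SD:
#' `y_hat = mu_J + sigma_J * z_hat`. Observed cells pass through unchanged.
#' Cells with an empty neighborhood or a zero weight denominator fall back
#' to `mu_J` and are flagged.
#'
#' @param pheno Wide phenotype tibble with `NA` for the cells to predict.
#' @param similarity Optional `similarity_matrix` (e.g. read from file);
#'   by default the pairwise-complete Pearson matrix of the standardized
#'   observed cells. Rows index the target item (relevant if the supplied
#'   matrix is asymmetric).
#' @param top_k Optional: use only the `top_k` neighbors with largest
#'   absolute weight (default: all observed items).
#' @param min_abs_weight Ignore neighbors with `|w| <= min_abs_weight`
#'   (default 0; undefined similarities are stored as 0 and hence ignored).
#' @param params Optional precomputed standardization parameters (see
#'   [standardize_phenotypes()]).
#' @return An `ibcf_imputation` object: list with `predictions` (the
#'   completed wide tibble), `cells` (tibble of imputed cells: `line`,
#'   `item`, `z_hat`, `y_hat`, `flagged`), `params`, `similarity` and
#'   `policy`.
#' @export
#' @examples
#' tab1 <- read_phenotypes(system.file("extdata", "table1_phenotypes.csv",
#'   package = "ibcfgs"))
#' w <- read_similarity(system.file("extdata", "table3_similarity.csv",
#'   package = "ibcfgs"))
#' fit <- ibcf_impute(tab1, similarity = w)
#' tidy(fit)
ibcf_impute <- function(pheno, similarity = NULL, top_k = NULL,
                        min_abs_weight = 0, params = NULL) {
  if (!is.null(top_k) && (length(top_k) != 1L || top_k < 1)) {
    abort("top_k must be a single integer >= 1")
  }
  m <- pheno_matrix(if (is.null(params)) validate_phenotypes(pheno) else pheno)
  items <- colnames(m)
  std <- standardize_phenotypes(pheno, params = params)
  z <- pheno_matrix(std$z)
  if (is.null(similarity)) {
    similarity <- similarity_matrix(std$z)
  } else {
    stopifnot(inherits(similarity, "similarity_matrix"))
    if (!all(items %in% similarity$items)) {
      abort("similarity matrix does not cover every item in the table")
    }
    idx <- match(items, similarity$items)
    similarity <- new_similarity(
      similarity$w[idx, idx, drop = FALSE],
      n_pairs = if (!is.null(similarity$n_pairs)) similarity$n_pairs[idx, idx, drop = FALSE],
      defined = similarity$defined[idx, idx, drop = FALSE]
    )
  }
  w <- similarity$w
  mu <- setNames(std$params$mu, std$params$item)[items]
  sigma <- setNames(std$params$sigma, std$params$item)[items]

  completed <- m
  cells <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    miss <- which(is.na(m[i, ]))
    if (length(miss) == 0L) next
    obs <- which(!is.na(m[i, ]))
    rows <- lapply(miss, function(J) {
      nb <- setdiff(obs, J)
      wj <- w[J, nb]
      keep <- abs(wj) > min_abs_weight & similarity$defined[J, nb]
      nb <- nb[keep]
      wj <- wj[keep]
      if (!is.null(top_k) && length(nb) > top_k) {
        ord <- order(abs(wj), decreasing = TRUE)[seq_len(top_k)]
        nb <- nb[ord]
        wj <- wj[ord]
      }
      denom <- sum(abs(wj))
      if (length(nb) == 0L || denom == 0) {
        tibble::tibble(
          line = rownames(m)[i], item = items[J],
          z_hat = NA_real_, y_hat = unname(mu[J]), flagged = TRUE
        )
      } else {
        zh <- sum(z[i, nb] * wj) / denom
        tibble::tibble(
          line = rownames(m)[i], item = items[J],
          z_hat = zh, y_hat = unname(mu[J] + sigma[J] * zh), flagged = FALSE
        )
      }
    })
    cells[[i]] <- dplyr::bind_rows(rows)
    completed[i, miss] <- vapply(rows, function(r) r$y_hat, numeric(1))
  }
  cells <- dplyr::bind_rows(cells)
  if (nrow(cells) == 0L) {
    cells <- tibble::tibble(
      line = character(), item = character(),
      z_hat = numeric(), y_hat = numeric(), flagged = logical()
    )
  }
  structure(
    list(
      predictions = matrix_to_pheno(completed),
      cells = cells,
      params = std$params,
      similarity = similarity,
      policy = list(top_k = top_k, min_abs_weight = min_abs_weight)
    ),
    class = "ibcf_imputation"
  )
}

#' @export
print.ibcf_imputation <- function(x, ...) {
  cat(sprintf(
    "<ibcf_imputation: %d line(s) x %d item(s), %d cell(s) imputed, %d flagged>\n",
    nrow(x$predictions), length(x$similarity$items), nrow(x$cells),
    sum(x$cells$flagged)
  ))
  invisible(x)
}

#' @rdname ibcf_impute
#' @param x,object An `ibcf_imputation`.
#' @param ... Unused.
#' @return `tidy()` returns the imputed-cell tibble.
#' @method tidy ibcf_imputation
#' @export
tidy.ibcf_imputation <- function(x, ...) x$cells

#' @rdname ibcf_impute
#' @method glance ibcf_imputation
#' @export
glance.ibcf_imputation <- function(x, ...) {
  tibble::tibble(
    n_lines = nrow(x$predictions),
    n_items = length(x$similarity$items),
    n_imputed = nrow(x$cells),
    n_flagged = sum(x$cells$flagged)
  )
}

#' Tile plot of a completed phenotype table
#'
#' Shows standardized values with imputed cells outlined.
#'
#' @param object An `ibcf_imputation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ibcf_imputation
#' @export
autoplot.ibcf_imputation <- function(object, ...) {
  comp <- tidyr::pivot_longer(object$predictions, -"line",
                              names_to = "item", values_to = "value")
  comp <- dplyr::left_join(comp, object$params[c("item", "mu", "sigma")],
                           by = "item")
  comp$z <- (comp$value - comp$mu) / comp$sigma
  comp$imputed <- paste(comp$line, comp$item) %in%
    paste(object$cells$line, object$cells$item)
  ggplot2::ggplot(comp, ggplot2::aes(
    x = .data$item, y = .data$line, fill = .data$z,
    colour = .data$imputed
  )) +
    ggplot2::geom_tile(linewidth = 0.8, width = 0.95, height = 0.95) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = NA, `TRUE` = "black")) +
    ggplot2::labs(x = NULL, y = NULL, colour = "imputed") +
    ggplot2::theme_minimal()
}
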