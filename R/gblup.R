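#' Genomic relationship matrix (VanRaden method 1)
#'
#' `K = W W' / (2 * sum(p_k (1 - p_k)))` where `W` is the genotype matrix
#' with each column centred by twice its allele frequency `p_k`. Under
#' Hardy-Weinberg-consistent data the mean diagonal is close to 1.
#'
#' @param geno Genotype tibble or lines x markers matrix; must be QC'd and
#'   imputed (no missing calls).
#' @return A `grm` object (symmetric lines x lines matrix with line ids as
#'   dimnames).
#' @export
compute_grm <- function(geno) {
  m <- if (is.data.frame(geno)) geno_matrix(geno) else as.matrix(geno)
  storage.mode(m) <- "double"
  if (anyNA(m)) abort("genotypes have missing calls; run marker_qc(impute = 'mean') first")
  if (ncol(m) == 0L) abort("no markers")
  p <- colMeans(m) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) abort("all markers are fixed; relationship matrix undefined")
  W <- sweep(m, 2, 2 * p, "-")
  K <- tcrossprod(W) / denom
  structure(K, class = c("grm", class(K)))
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm: %d lines, mean diagonal %.3f>\n", nrow(x), mean(diag(x))))
  invisible(x)
}

#' @method autoplot grm
#' @export
autoplot.grm <- function(object, ...) {
  d <- tibble::tibble(
    line1 = rep(rownames(object), times = ncol(object)),
    line2 = rep(colnames(object), each = nrow(object)),
    k = as.vector(unclass(object))
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$line1, .data$line2, fill = .data$k)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

# REML log-likelihood of y = 1 mu + g + e, g ~ N(0, sg2 K), on the
# eigenbasis of K (lambda = sg2 / se2; se2 profiled out).
reml_ll <- function(log_lambda, d, u1, yt) {
  lambda <- exp(log_lambda)
  n <- length(yt)
  wts <- 1 / (lambda * d + 1)
  xwx <- sum(u1^2 * wts)
  mu <- sum(u1 * wts * yt) / xwx
  r <- yt - u1 * mu
  quad <- sum(r^2 * wts)
  se2 <- quad / (n - 1)
  -0.5 * ((n - 1) * (log(2 * pi * se2) + 1) + sum(log(lambda * d + 1)) +
            log(xwx))
}

#' Fit a univariate GBLUP model
#'
#' `y = 1 mu + g + e` with `g ~ N(0, sigma2_g K)` and
#' `e ~ N(0, sigma2_e I)`. Variance components are estimated by REML using
#' a single eigendecomposition of `K` and a one-dimensional optimization
#' over `lambda = sigma2_g / sigma2_e`; breeding values are the BLUPs
#' `g_hat = sigma2_g K V^{-1} (y - 1 mu_hat)`. Lines with missing `y` are
#' predicted through their relationship to the observed lines.
#'
#' @param y Numeric response named by (or aligned with) the rows of `K`;
#'   `NA` entries are predicted, not fitted.
#' @param K A `grm` (or symmetric PSD matrix) covering the lines of `y`.
#' @param jitter Diagonal jitter added to `K` for numerical positive
#'   semi-definiteness (default 1e-6).
#' @return A `gblup_fit`: list with `mu`, `sigma2_g`, `sigma2_e`, `h2`,
#'   `lambda`, `loglik`, `gebv` (all lines) and the eigen pieces used.
#' @export
fit_gblup <- function(y, K, jitter = 1e-6) {
  K <- unclass(K)
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  if (length(y) != nrow(K)) abort("length(y) must match nrow(K)")
  ids <- rownames(K) %||% as.character(seq_len(nrow(K)))
  obs <- which(!is.na(y))
  if (length(obs) < 10L) abort("need at least 10 observed lines")
  Ko <- K[obs, obs, drop = FALSE] + diag(jitter, length(obs))
  eg <- eigen(Ko, symmetric = TRUE)
  if (min(eg$values) < -1e-8) abort("K is not positive semi-definite (even after jitter)")
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y[obs]))
  u1 <- drop(crossprod(U, rep(1, length(obs))))

  opt <- optimize(reml_ll, c(-14, 14), d = d, u1 = u1, yt = yt,
                  maximum = TRUE, tol = 1e-9)
  cand <- rbind(
    c(opt$maximum, opt$objective),
    c(-14, reml_ll(-14, d, u1, yt)),
    c(14, reml_ll(14, d, u1, yt))
  )
  best <- cand[which.max(cand[, 2]), ]
  lambda <- exp(best[1])
  loglik <- best[2]

  n_o <- length(obs)
  wts <- 1 / (lambda * d + 1)
  xwx <- sum(u1^2 * wts)
  mu <- sum(u1 * wts * yt) / xwx
  r <- yt - u1 * mu
  se2 <- sum(r^2 * wts) / (n_o - 1)
  sg2 <- lambda * se2
  # V^{-1}(y - 1 mu) in the eigenbasis of K_obs
  vinv_r <- drop(U %*% (r / (sg2 * d + se2)))
  g <- drop(sg2 * K[, obs, drop = FALSE] %*% vinv_r)
  structure(
    list(
      mu = mu, sigma2_g = sg2, sigma2_e = se2,
      h2 = sg2 / (sg2 + se2), lambda = lambda, loglik = loglik,
      gebv = setNames(g, ids), observed = setNames(ids %in% ids[obs], ids),
      reml = list(d = d, u1 = u1, yt = yt)
    ),
    class = "gblup_fit"
  )
}

#' REML log-likelihood profile of a fitted GBLUP
#'
#' Evaluates the (profiled) restricted log-likelihood of the model at an
#' arbitrary variance ratio `lambda = sigma2_g / sigma2_e`, e.g. to check
#' the optimizer against a grid.
#'
#' @param fit A `gblup_fit`.
#' @param lambda Positive variance ratio(s).
#' @return Numeric vector of log-likelihood values.
#' @export
gblup_loglik <- function(fit, lambda) {
  stopifnot(inherits(fit, "gblup_fit"))
  vapply(lambda, function(l) {
    reml_ll(log(l), fit$reml$d, fit$reml$u1, fit$reml$yt)
  }, numeric(1))
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf(
    "<gblup_fit: mu = %.4f, sigma2_g = %.4f, sigma2_e = %.4f, h2 = %.3f>\n",
    x$mu, x$sigma2_g, x$sigma2_e, x$h2
  ))
  invisible(x)
}

#' @rdname fit_gblup
#' @param x,object A `gblup_fit`.
#' @param ... Unused.
#' @return `tidy()` returns per-line breeding values; `glance()` a one-row
#'   summary of the variance components.
#' @method tidy gblup_fit
#' @export
tidy.gblup_fit <- function(x, ...) {
  tibble::tibble(line = names(x$gebv), gebv = unname(x$gebv),
                 observed = unname(x$observed))
}

#' @rdname fit_gblup
#' @method glance gblup_fit
#' @export
glance.gblup_fit <- function(x, ...) {
  tibble::tibble(
    mu = x$mu, sigma2_g = x$sigma2_g, sigma2_e = x$sigma2_e,
    h2 = x$h2, lambda = x$lambda, loglik = x$loglik
  )
}

#' GBLUP cross-validation (disjoint k-fold, repeated)
#'
#' Per iteration the lines are split into `folds` disjoint folds; each
#' fold's phenotypes are masked in turn, the model is refit on the training
#' lines, and the fold's breeding values are predicted through the
#' relationship matrix. Metrics (predictive ability, MAAPE, RMSE) are
#' computed per fold-fit and summarized over all `folds * iterations` fits.
#'
#' @param y Named numeric response aligned with `K`.
#' @param K A `grm`.
#' @param folds Folds per iteration (default 10).
#' @param iterations Repetitions (default 10).
#' @param seed Optional seed for the fold draws.
#' @param item Label used in the result tables.
#' @return A `gs_scenario`.
#' @export
gblup_cv <- function(y, K, folds = 10, iterations = 10, seed = NULL,
                     item = "trait") {
  K <- unclass(K)
  n <- nrow(K)
  stopifnot(length(y) == n)
  ids <- rownames(K) %||% as.character(seq_len(n))
  obs_all <- which(!is.na(y))
  predictions <- with_seed(seed, {
    out <- list()
    part <- 0L
    for (it in seq_len(iterations)) {
      fold <- sample(rep_len(seq_len(folds), length(obs_all)))
      for (f in seq_len(folds)) {
        part <- part + 1L
        test <- obs_all[fold == f]
        ytr <- y
        ytr[test] <- NA
        fit <- fit_gblup(ytr, K)
        pred <- fit$mu + fit$gebv[test]
        if (sd(y[test]) == 0) {
          inform(sprintf("fold %d.%d has zero variance in the truth; NA metrics", it, f))
        }
        out[[part]] <- tibble::tibble(
          partition = part, line = ids[test], item = item,
          observed = unname(y[test]), predicted = unname(pred),
          flagged = FALSE
        )
      }
    }
    dplyr::bind_rows(out)
  })
  new_scenario(
    "gblup_cv", predictions, scenario_metrics(predictions),
    list(folds = folds, iterations = iterations, seed = seed, item = item)
  )
}
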