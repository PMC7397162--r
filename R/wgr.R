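#' MCMC settings for whole-genome regression
#'
#' @param n_iter Total Gibbs iterations (default 20000).
#' @param burn_in Iterations discarded before collecting samples
#'   (default 15000); must be smaller than `n_iter`.
#' @param thin Keep every `thin`-th post-burn-in sample (default 5).
#' @param seed Optional integer seed; the sampler is deterministic given it.
#' @return An `mcmc_settings` list.
#' @export
mcmc_settings <- function(n_iter = 20000, burn_in = 15000, thin = 5,
                          seed = NULL) {
  if (n_iter < 1 || burn_in < 0 || burn_in >= n_iter) {
    abort("need 0 <= burn_in < n_iter")
  }
  if (thin < 1) abort("thin must be >= 1")
  structure(
    list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
         thin = as.integer(thin), seed = seed),
    class = "mcmc_settings"
  )
}

wgr_models <- c("BRR", "BayesA", "BayesB", "BayesC", "BL")

#' Fit a Bayesian whole-genome regression (Trait ~ Markers + Error)
#'
#' Gibbs sampler for the linear model `y = mu + M beta + e` with one of
#' five marker-effect priors:
#' * `BRR` — Gaussian with a common variance `sigma2_b` (ridge);
#' * `BayesA` — Gaussian with per-marker variances (scaled-t marginal);
#' * `BayesB` — spike-slab: point mass at zero with probability `1 - pi`
#'   plus a per-marker-variance slab;
#' * `BayesC` — spike-slab with a common slab variance;
#' * `BL` — Bayesian LASSO (double-exponential via an exponential mixture
#'   of normals).
#'
#' Hyperprior constants follow the standard scale-matching recipe: all
#' scaled-inverse-chi-square priors use 5 degrees of freedom with scales
#' set so that the prior mode of the residual variance is `(1 - R2) var(y)`
#' and the markers jointly account for `R2` of the phenotypic variance a
#' priori (`R2 = 0.5` by default). The inclusion probability of the
#' spike-slab models gets a Beta prior with mean 0.5 and weight 10; the
#' Bayesian LASSO's `lambda^2` gets a Gamma prior with shape 1.1 and prior
#' mean `2 MSx (1 - R2) / R2`, `MSx` being the summed marker variances.
#'
#' @param y Numeric response vector (no missing values).
#' @param M Marker matrix (lines x markers, 0/1/2 dosages or already
#'   centered), or a genotype tibble with a `line` column. Missing calls
#'   are not allowed; run [marker_qc()] first.
#' @param model One of `"BRR"`, `"BayesA"`, `"BayesB"`, `"BayesC"`, `"BL"`.
#' @param settings An [mcmc_settings()] object.
#' @param center Centre marker columns by their means (default `TRUE`); the
#'   centring vector is stored and reapplied by [gebv()].
#' @param scale Also scale columns to unit variance (default `FALSE`).
#' @param R2 Prior proportion of variance attributed to markers.
#' @param fixed_hyper Optional list with elements `sigma2_e` and/or
#'   `sigma2_b` to hold those variances fixed (degenerate hyperpriors);
#'   useful for validating against the closed-form ridge solution.
#' @return A `wgr_fit` object with posterior means `mu`, `beta`,
#'   `sigma2_e`, model-specific hyperparameter summaries in `hyper`,
#'   scalar-parameter traces in `draws`, and bookkeeping fields.
#' @export
fit_wgr <- function(y, M, model = wgr_models, settings = mcmc_settings(),
                    center = TRUE, scale = FALSE, R2 = 0.5,
                    fixed_hyper = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(settings, "mcmc_settings"))
  if (is.data.frame(M)) M <- geno_matrix(M)
  storage.mode(M) <- "double"
  if (!all(is.finite(y))) abort("y must be finite (subset to observed lines first)")
  if (nrow(M) != length(y)) abort("length(y) must equal nrow(M)")
  if (anyNA(M)) abort("M has missing calls; impute first (see marker_qc)")
  n <- nrow(M)
  p <- ncol(M)
  if (p == 0L) abort("M has no markers")
  if (is.null(colnames(M))) colnames(M) <- sprintf("M%05d", seq_len(p))

  ctr <- if (center) colMeans(M) else rep(0, p)
  M <- sweep(M, 2, ctr, "-")
  scl <- rep(1, p)
  if (scale) {
    scl <- apply(M, 2, sd)
    scl[scl == 0] <- 1
    M <- sweep(M, 2, scl, "/")
  }
  M <- M + 0  # force a private copy: the C++ kernel works on it in place
  xtx <- colSums(M^2)
  vy <- var(y)
  if (!is.finite(vy) || vy == 0) vy <- 1
  msx <- sum(xtx) / (n - 1)
  if (msx == 0) msx <- 1

  df0 <- 5
  S_e <- vy * (1 - R2) * (df0 + 2)
  pi0 <- 0.5
  a0 <- 10 * pi0
  b0 <- 10 * (1 - pi0)
  S_b <- switch(model,
    BRR = , BayesA = vy * R2 / msx * (df0 + 2),
    BayesB = , BayesC = vy * R2 / (msx * pi0) * (df0 + 2),
    BL = NA_real_
  )
  lambda2_0 <- 2 * msx * (1 - R2) / R2
  shape_l <- 1.1
  rate_l <- shape_l / lambda2_0

  fix_e <- !is.null(fixed_hyper$sigma2_e)
  fix_b <- !is.null(fixed_hyper$sigma2_b)

  run <- function() {
    mu <- mean(y)
    beta <- rep(0, p)
    delta <- rep(1L, p)
    resid <- y - mu
    sigma2e <- if (fix_e) fixed_hyper$sigma2_e else vy * (1 - R2)
    sigma2b <- if (fix_b) fixed_hyper$sigma2_b else vy * R2 / msx
    sigma2k <- rep(vy * R2 / msx, p)
    tau2 <- rep(2 / lambda2_0, p)
    lambda2 <- lambda2_0
    pi_in <- pi0
    spike <- model %in% c("BayesB", "BayesC")

    kept <- 0L
    mu_sum <- 0
    beta_sum <- rep(0, p)
    sigma2k_sum <- rep(0, p)
    delta_sum <- rep(0, p)
    trace <- list(sigma2_e = numeric(), sigma2_b = numeric(),
                  pi = numeric(), lambda2 = numeric())

    for (t in seq_len(settings$n_iter)) {
      e0 <- resid + mu
      mu <- rnorm(1, mean(e0), sqrt(sigma2e / n))
      resid <- e0 - mu

      s2vec <- switch(model,
        BRR = , BayesC = rep(sigma2b, p),
        BayesA = , BayesB = sigma2k,
        BL = sigma2e * tau2
      )
      wgr_update_markers(M, xtx, resid, beta, delta, sigma2e, s2vec,
                         pi_in, spike)

      if (model == "BRR" && !fix_b) {
        sigma2b <- (S_b + sum(beta^2)) / rchisq(1, df0 + p)
      } else if (model == "BayesA") {
        sigma2k <- (S_b + beta^2) / rchisq(p, df0 + 1)
      } else if (model == "BayesB") {
        sigma2k <- (S_b + beta^2) / rchisq(p, df0 + 1)
        m_in <- sum(delta)
        pi_in <- min(max(rbeta(1, a0 + m_in, b0 + p - m_in), 1e-6), 1 - 1e-6)
      } else if (model == "BayesC") {
        m_in <- sum(delta)
        sigma2b <- (S_b + sum(beta[delta == 1L]^2)) / rchisq(1, df0 + max(m_in, 0))
        pi_in <- min(max(rbeta(1, a0 + m_in, b0 + p - m_in), 1e-6), 1 - 1e-6)
      } else if (model == "BL") {
        mu_ig <- sqrt(lambda2 * sigma2e / pmax(beta^2, 1e-16))
        mu_ig <- pmin(mu_ig, 1e8)
        tau2 <- 1 / rinvgauss(p, mu_ig, lambda2)
        tau2 <- pmin(pmax(tau2, 1e-10), 1e10)
        lambda2 <- rgamma(1, shape_l + p, rate_l + sum(tau2) / 2)
      }

      if (!fix_e) {
        if (model == "BL") {
          sigma2e <- (S_e + sum(resid^2) + sum(beta^2 / tau2)) /
            rchisq(1, df0 + n + p)
        } else {
          sigma2e <- (S_e + sum(resid^2)) / rchisq(1, df0 + n)
        }
      }

      if (t > settings$burn_in &&
          (t - settings$burn_in) %% settings$thin == 0L) {
        kept <- kept + 1L
        mu_sum <- mu_sum + mu
        beta_sum <- beta_sum + beta
        sigma2k_sum <- sigma2k_sum + s2vec
        delta_sum <- delta_sum + delta
        trace$sigma2_e[kept] <- sigma2e
        trace$sigma2_b[kept] <- sigma2b
        trace$pi[kept] <- pi_in
        trace$lambda2[kept] <- lambda2
      }
    }
    list(mu = mu_sum / kept, beta = beta_sum / kept,
         sigma2k = sigma2k_sum / kept, delta = delta_sum / kept,
         trace = trace, kept = kept)
  }

  res <- with_seed(settings$seed, run())

  beta_hat <- res$beta / scl  # back to the original marker scale
  hyper <- list(sigma2_b = NULL, sigma2_k = NULL, pi = NULL, lambda2 = NULL)
  if (model %in% c("BRR", "BayesC")) hyper$sigma2_b <- mean(res$trace$sigma2_b)
  if (model %in% c("BayesA", "BayesB", "BL")) hyper$sigma2_k <- res$sigma2k
  if (model %in% c("BayesB", "BayesC")) hyper$pi <- mean(res$trace$pi)
  if (model == "BL") hyper$lambda2 <- mean(res$trace$lambda2)

  structure(
    list(
      model = model,
      mu = res$mu,
      beta = setNames(beta_hat, colnames(M)),
      sigma2_e = mean(res$trace$sigma2_e),
      hyper = hyper,
      inclusion = setNames(res$delta, colnames(M)),
      draws = tibble::tibble(
        sample = seq_len(res$kept),
        sigma2_e = res$trace$sigma2_e,
        sigma2_b = res$trace$sigma2_b,
        pi = res$trace$pi,
        lambda2 = res$trace$lambda2
      ),
      center = setNames(ctr, colnames(M)),
      scale = setNames(scl, colnames(M)),
      kept_samples = res$kept,
      n = n, p = p,
      settings = settings, R2 = R2
    ),
    class = "wgr_fit"
  )
}

# Inverse-Gaussian sampler (Michael, Schucany & Haas 1976), vectorized.
rinvgauss <- function(n, mu, lambda) {
  nu <- rnorm(n)
  y <- nu^2
  x <- mu + mu^2 * y / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
  x <- pmax(x, 1e-12)
  u <- runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

#' @export
print.wgr_fit <- function(x, ...) {
  cat(sprintf(
    "<wgr_fit: %s, n = %d, p = %d, %d kept samples>\n  mu = %.4f, sigma2_e = %.4f\n",
    x$model, x$n, x$p, x$kept_samples, x$mu, x$sigma2_e
  ))
  invisible(x)
}

#' @rdname fit_wgr
#' @param x,object A `wgr_fit`.
#' @param ... Unused.
#' @return `tidy()` returns a tibble of posterior-mean marker effects
#'   (`marker`, `estimate`, and for spike-slab models the posterior
#'   inclusion probability); `glance()` a one-row model summary.
#' @method tidy wgr_fit
#' @export
tidy.wgr_fit <- function(x, ...) {
  out <- tibble::tibble(marker = names(x$beta), estimate = unname(x$beta))
  if (x$model %in% c("BayesB", "BayesC")) {
    out$inclusion_prob <- unname(x$inclusion)
  }
  out
}

#' @rdname fit_wgr
#' @method glance wgr_fit
#' @export
glance.wgr_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, n = x$n, p = x$p,
    mu = x$mu, sigma2_e = x$sigma2_e,
    sigma2_b = x$hyper$sigma2_b %||% NA_real_,
    pi = x$hyper$pi %||% NA_real_,
    lambda2 = x$hyper$lambda2 %||% NA_real_,
    kept_samples = x$kept_samples
  )
}

#' Posterior-mean marker effects plot
#'
#' @param object A `wgr_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wgr_fit
#' @export
autoplot.wgr_fit <- function(object, ...) {
  d <- tidy(object)
  d$index <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$estimate)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$index, yend = 0),
                          colour = "grey40") +
    ggplot2::labs(x = "marker index", y = "posterior mean effect",
                  title = object$model) +
    ggplot2::theme_minimal()
}

#' Genomic estimated breeding values from a fitted regression
#'
#' `GEBV = mu + M beta` with the fit's centring (and scaling) applied to
#' the new marker rows.
#'
#' @param fit A `wgr_fit`.
#' @param M_new Marker matrix or genotype tibble whose columns match the
#'   fit's markers.
#' @return Named numeric vector of breeding values.
#' @export
gebv <- function(fit, M_new) {
  stopifnot(inherits(fit, "wgr_fit"))
  if (is.data.frame(M_new)) M_new <- geno_matrix(M_new)
  storage.mode(M_new) <- "double"
  if (!is.null(colnames(M_new))) {
    if (!all(names(fit$beta) %in% colnames(M_new))) {
      abort("M_new is missing marker column(s) present in the fit")
    }
    M_new <- M_new[, names(fit$beta), drop = FALSE]
  } else if (ncol(M_new) != fit$p) {
    abort("M_new has a different number of markers than the fit")
  }
  W <- sweep(M_new, 2, fit$center, "-")
  drop(fit$mu + W %*% (fit$beta))
}

#' Adjust phenotypes for markers (breeding-value table)
#'
#' Fits a univariate whole-genome regression per trait-environment item
#' (each item analyzed independently on the lines observed for it) and
#' replaces every cell by the line's genomic estimated breeding value, so
#' the resulting table is fully populated for all genotyped lines. Items
#' with fewer than `min_obs` observed, genotyped lines are skipped with a
#' warning (their column is left `NA`).
#'
#' @param pheno Wide phenotype tibble.
#' @param geno Genotype tibble (QC'd; remaining missing calls are
#'   mean-imputed with a warning).
#' @param model,settings,R2 Passed to [fit_wgr()].
#' @param min_obs Minimum observed lines per item (default 30).
#' @return An `adjusted_phenotypes` object: list with `adjusted` (wide
#'   tibble of breeding values), `fits` (per-item `wgr_fit`s), `skipped`,
#'   `model` and `settings`.
#' @export
adjust_traits <- function(pheno, geno, model = "BRR",
                          settings = mcmc_settings(), R2 = 0.5,
                          min_obs = 30) {
  m <- pheno_matrix(validate_phenotypes(pheno))
  G <- geno_matrix(geno)
  shared <- intersect(rownames(m), rownames(G))
  if (length(shared) == 0L) abort("no lines shared between phenotypes and genotypes")
  unphenotyped <- setdiff(rownames(m), shared)
  if (length(unphenotyped) > 0L) {
    warn(sprintf("%d phenotyped line(s) lack genotypes and cannot enter training",
                 length(unphenotyped)))
  }
  if (anyNA(G)) {
    warn("mean-imputing missing genotype calls (run marker_qc first to control this)")
    cm <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- cm[idx[, 2]]
  }
  items <- colnames(m)
  inner <- mcmc_settings(settings$n_iter, settings$burn_in, settings$thin)
  run <- function() {
    fits <- list()
    skipped <- character()
    # breeding values are produced for every genotyped line
    adj <- matrix(NA_real_, nrow(G), length(items),
                  dimnames = list(rownames(G), items))
    for (j in items) {
      obs <- shared[!is.na(m[shared, j])]
      if (length(obs) < min_obs) {
        warn(sprintf("skipping item '%s': only %d observed genotyped line(s)",
                     j, length(obs)))
        skipped <- c(skipped, j)
        next
      }
      fit <- fit_wgr(m[obs, j], G[obs, , drop = FALSE], model = model,
                     settings = inner, R2 = R2)
      adj[, j] <- gebv(fit, G)
      fits[[j]] <- fit
    }
    if (length(fits) == 0L) abort("every item was skipped; nothing adjusted")
    list(adjusted = matrix_to_pheno(adj), fits = fits, skipped = skipped)
  }
  res <- with_seed(settings$seed, run())
  structure(
    c(res, list(model = model, settings = settings)),
    class = "adjusted_phenotypes"
  )
}

#' @export
print.adjusted_phenotypes <- function(x, ...) {
  cat(sprintf(
    "<adjusted_phenotypes: %s, %d item(s) adjusted, %d skipped>\n",
    x$model, length(x$fits), length(x$skipped)
  ))
  invisible(x)
}

#' @rdname adjust_traits
#' @param x An `adjusted_phenotypes` object.
#' @param ... Unused.
#' @return `tidy()` returns the breeding-value table in long form.
#' @method tidy adjusted_phenotypes
#' @export
tidy.adjusted_phenotypes <- function(x, ...) {
  tidyr::pivot_longer(x$adjusted, -"line", names_to = "item",
                      values_to = "gebv")
}

#' Marker-adjusted IBCF cross-validation scenario
#'
#' The two-step design: phenotypes are first adjusted for markers by
#' Bayesian whole-genome regression ([adjust_traits()]), then the IBCF
#' recommender predicts each target item for the test lines from the
#' adjusted table, and predictions are scored against the raw observed
#' phenotypes.
#'
#' With `leakage_guard = "strict"` (default) the per-item regressions are
#' refit within each partition on the training lines only, so no test-line
#' phenotype of any item is ever read before evaluation. With
#' `leakage_guard = "package"` the adjustment is done once on all lines
#' before masking, reproducing the behavior of the workflow this design
#' emulates (reported results flag the mode used).
#'
#' @param pheno Wide phenotype tibble.
#' @param geno Genotype tibble (QC'd).
#' @param plan A `cv_plan` (the reference design is 10 partitions with 20%
#'   of lines in the test set).
#' @param model,settings,R2 Passed to [fit_wgr()].
#' @param target_items Items to predict (default: every item).
#' @param leakage_guard `"strict"` or `"package"`.
#' @param min_obs Passed to [adjust_traits()].
#' @param top_k,min_abs_weight Neighbor policy for [ibcf_impute()].
#' @return A `gs_scenario`.
#' @export
scenario_marker_ibcf <- function(pheno, geno, plan, model = "BRR",
                                 settings = mcmc_settings(),
                                 target_items = NULL,
                                 leakage_guard = c("strict", "package"),
                                 R2 = 0.5, min_obs = 30,
                                 top_k = NULL, min_abs_weight = 0) {
  leakage_guard <- match.arg(leakage_guard)
  al <- align_lines(pheno, geno)
  pheno <- al$pheno
  geno <- al$geno
  m <- pheno_matrix(pheno)
  items <- colnames(m)
  if (is.null(target_items)) target_items <- items
  if (!all(target_items %in% items)) abort("target_items must be items of pheno")
  if (length(items) < 2L) abort("IBCF needs at least two items")
  n_parts <- attr(plan, "n_partitions") %||% max(plan$partition)

  if (leakage_guard == "package") {
    adj_all <- suppressWarnings(
      adjust_traits(pheno, geno, model = model, settings = settings,
                    R2 = R2, min_obs = min_obs)
    )
  }

  out <- lapply(seq_len(n_parts), function(k) {
    test <- intersect(test_lines(plan, k), rownames(m))
    train <- setdiff(rownames(m), test)
    if (leakage_guard == "strict") {
      seed_k <- if (is.null(settings$seed)) NULL else settings$seed + k
      adj <- suppressWarnings(
        adjust_traits(pheno[pheno$line %in% train, , drop = FALSE], geno,
                      model = model,
                      settings = mcmc_settings(settings$n_iter,
                                               settings$burn_in,
                                               settings$thin, seed = seed_k),
                      R2 = R2, min_obs = min_obs)
      )
    } else {
      adj <- adj_all
    }
    A <- pheno_matrix(adj$adjusted)[rownames(m), , drop = FALSE]
    usable <- setdiff(colnames(A)[colSums(is.na(A)) == 0L], character(0))
    rows <- lapply(intersect(target_items, usable), function(J) {
      others <- setdiff(usable, J)
      if (length(others) == 0L) return(NULL)
      sub <- A[, c(J, others), drop = FALSE]
      sub[test, J] <- NA
      fit <- ibcf_impute(matrix_to_pheno(sub), top_k = top_k,
                         min_abs_weight = min_abs_weight)
      truth <- m[test, J]
      keep <- !is.na(truth)
      cells <- fit$cells[match(test[keep], fit$cells$line), , drop = FALSE]
      tibble::tibble(
        partition = k, line = test[keep], item = J,
        observed = unname(truth[keep]), predicted = cells$y_hat,
        flagged = cells$flagged
      )
    })
    dplyr::bind_rows(rows)
  })
  predictions <- dplyr::bind_rows(out)
  new_scenario(
    "marker_ibcf", predictions, scenario_metrics(predictions),
    list(model = model, leakage_guard = leakage_guard,
         target_items = target_items, n_partitions = n_parts,
         test_fraction = attr(plan, "test_fraction"),
         seed = settings$seed, mcmc = settings[c("n_iter", "burn_in", "thin")])
  )
}
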