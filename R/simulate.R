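#' Default trait profiles and trial environments for simulation
#'
#' The defaults emulate a Pacific-Northwest winter wheat panel: grain yield
#' (t/ha), heading date (Julian days) and plant height (cm) measured over
#' nine site-years (Lind 2015/17/18/19, Pullman 2015-19). Heritabilities
#' are typical single-environment values for these traits; means and
#' spreads are arbitrary but realistic constants (analyses downstream
#' depend only on correlations and heritability, never on the means).
#'
#' @return `default_trait_profiles()`: a tibble with columns `trait`,
#'   `mean`, `sd`, `h2`; `default_environments()`: a tibble with columns
#'   `location`, `year`.
#' @export
default_trait_profiles <- function() {
  tibble::tribble(
    ~trait, ~mean, ~sd, ~h2,
    "GY",    4.0, 0.6, 0.4,
    "HD",  160.0, 3.0, 0.8,
    "PH",   85.0, 8.0, 0.7
  )
}

#' @rdname default_trait_profiles
#' @export
default_environments <- function() {
  tibble::tibble(
    location = c("LND", "LND", "LND", "LND", "PUL", "PUL", "PUL", "PUL", "PUL"),
    year = c(2015L, 2017L, 2018L, 2019L, 2015L, 2016L, 2017L, 2018L, 2019L)
  )
}

#' Simulate a biallelic SNP genotype panel
#'
#' Per marker an allele frequency is drawn uniformly from `maf_range` and
#' calls are drawn as `Binomial(2, p)` per line (`inbred = TRUE` draws
#' homozygotes only, as for a fully inbred wheat panel).
#'
#' @param n_lines,n_markers Panel dimensions (defaults emulate a 456-line,
#'   15,229-marker association mapping panel).
#' @param maf_range Range of simulated allele frequencies.
#' @param inbred Draw only homozygous calls (0/2).
#' @param missing_rate Fraction of calls set to missing.
#' @param seed Optional seed.
#' @return A genotype tibble (`line` plus marker columns).
#' @export
simulate_genotypes <- function(n_lines = 456, n_markers = 15229,
                               maf_range = c(0.05, 0.5), inbred = FALSE,
                               missing_rate = 0, seed = NULL) {
  stopifnot(length(maf_range) == 2L, maf_range[1] >= 0, maf_range[2] <= 1)
  with_seed(seed, {
    p <- runif(n_markers, maf_range[1], maf_range[2])
    calls <- if (inbred) {
      2 * matrix(rbinom(n_lines * n_markers, 1, rep(p, each = n_lines)),
                 n_lines, n_markers)
    } else {
      matrix(rbinom(n_lines * n_markers, 2, rep(p, each = n_lines)),
             n_lines, n_markers)
    }
    if (missing_rate > 0) {
      drop_idx <- which(runif(length(calls)) < missing_rate)
      calls[drop_idx] <- NA
    }
    dimnames(calls) <- list(sprintf("L%04d", seq_len(n_lines)),
                            sprintf("M%05d", seq_len(n_markers)))
    matrix_to_pheno(calls)
  })
}

# Population-variance helper and exact variance scaling.
pop_var <- function(x) mean((x - mean(x))^2)

scale_to_var <- function(x, target) {
  v <- pop_var(x)
  if (v == 0 || target == 0) return(rep(0, length(x)))
  (x - mean(x)) * sqrt(target / v)
}

#' Simulate multi-trait, multi-environment phenotypes
#'
#' For each trait a set of QTL is drawn from the panel's markers and the
#' QTL-effect vectors of the environments are jointly Gaussian with
#' between-environment correlation `rho_g` (the correlated-effects model:
#' the genetic signal shared across environments, which is what the IBCF
#' recommender exploits, lives in the effects). Genetic values
#' `g_e = W beta_e` are scaled to `h2 * sd^2` and residuals (orthogonalized
#' against `g_e`) to `(1 - h2) * sd^2`, so the realized
#' `var(g) / var(y)` equals the requested heritability exactly. Traits are
#' genetically independent of each other.
#'
#' @param geno Genotype tibble (no missing calls).
#' @param traits Trait-profile tibble (`trait`, `mean`, `sd`, `h2`); see
#'   [default_trait_profiles()].
#' @param environments Tibble of (`location`, `year`) site-years.
#' @param rho_g Between-environment genetic correlation: a scalar or an
#'   `n_env x n_env` PSD matrix with unit diagonal.
#' @param n_qtl Number of causal markers per trait.
#' @param h2 Optional heritability override (scalar or per-environment
#'   vector, applied to every trait); default uses each trait's profile.
#' @param missing_rate Fraction of phenotype cells masked at random.
#' @param seed Optional seed.
#' @return A list: `phenotypes` (wide tibble with
#'   `trait_location_year` items), `truth` (long tibble of true genetic
#'   values `g` per line and item) and `qtl` (tibble of causal markers per
#'   trait).
#' @export
simulate_phenotypes <- function(geno, traits = default_trait_profiles(),
                                environments = default_environments(),
                                rho_g = 0.2, n_qtl = 300, h2 = NULL,
                                missing_rate = 0, seed = NULL) {
  G <- geno_matrix(geno)
  if (anyNA(G)) abort("simulate_phenotypes needs complete genotypes (impute first)")
  n <- nrow(G)
  p <- ncol(G)
  if (n_qtl > p) abort("n_qtl cannot exceed the number of markers")
  n_env <- nrow(environments)
  Sigma <- if (is.matrix(rho_g)) rho_g else {
    s <- matrix(rho_g, n_env, n_env)
    diag(s) <- 1
    s
  }
  if (!isSymmetric(unname(Sigma)) || nrow(Sigma) != n_env) {
    abort("rho_g must be a scalar or a symmetric n_env x n_env matrix")
  }
  eg <- eigen(Sigma, symmetric = TRUE)
  if (min(eg$values) < -1e-8) abort("rho_g matrix is not positive semi-definite")
  Sroot <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))

  with_seed(seed, {
    pheno_cols <- list()
    truth_rows <- list()
    qtl_rows <- list()
    for (ti in seq_len(nrow(traits))) {
      tr <- traits[ti, ]
      h2_env <- if (is.null(h2)) rep(tr$h2, n_env) else rep_len(h2, n_env)
      qtl <- sort(sample.int(p, n_qtl))
      qtl_rows[[ti]] <- tibble::tibble(trait = tr$trait,
                                       marker = colnames(G)[qtl])
      W <- scale(G[, qtl, drop = FALSE], center = TRUE, scale = FALSE)
      B <- matrix(rnorm(n_qtl * n_env), n_qtl, n_env) %*% Sroot
      for (e in seq_len(n_env)) {
        item <- make_item_key(tr$trait, environments$location[e],
                              environments$year[e])
        g_raw <- drop(W %*% B[, e])
        g <- scale_to_var(g_raw, h2_env[e] * tr$sd^2)
        eps <- rnorm(n)
        if (h2_env[e] < 1) {
          if (pop_var(g) > 0) {
            eps <- eps - g * (stats::cov(eps, g) * (n - 1) / n / pop_var(g))
          }
          eps <- scale_to_var(eps, (1 - h2_env[e]) * tr$sd^2)
        } else {
          eps <- rep(0, n)
        }
        y <- tr$mean + g + eps
        if (missing_rate > 0) y[runif(n) < missing_rate] <- NA
        pheno_cols[[item]] <- y
        truth_rows[[item]] <- tibble::tibble(
          line = rownames(G), item = item, trait = tr$trait,
          location = environments$location[e], year = environments$year[e],
          g = g
        )
      }
    }
    pheno <- dplyr::bind_cols(tibble::tibble(line = rownames(G)),
                              tibble::as_tibble(pheno_cols))
    validate_phenotypes(pheno)
    list(
      phenotypes = pheno,
      truth = dplyr::bind_rows(truth_rows),
      qtl = dplyr::bind_rows(qtl_rows)
    )
  })
}

#' Simulate a secondary (spectral) trait genetically correlated with yield
#'
#' The secondary genetic value is
#' `rho * std(g_target) + sqrt(1 - rho^2) * z` with independent Gaussian
#' `z`, then phenotypic noise is added down to `h2`. A negative
#' `target_corr` encodes indices such as NWI-1 whose sign convention runs
#' against yield.
#'
#' @param truth_target True genetic values of the target trait (one value
#'   per line, e.g. from [simulate_phenotypes()]'s `truth`).
#' @param target_corr Desired genetic correlation with the target.
#' @param h2 Heritability of the secondary trait (default 0.7; spectral
#'   indices are typically more heritable than yield).
#' @param mean,sd Phenotype location and scale.
#' @param seed Optional seed.
#' @return A list with `phenotype` and `g` (numeric vectors aligned with
#'   `truth_target`).
#' @export
simulate_secondary <- function(truth_target, target_corr, h2 = 0.7,
                               mean = 0.6, sd = 0.1, seed = NULL) {
  if (abs(target_corr) > 1) abort("|target_corr| must be <= 1")
  n <- length(truth_target)
  with_seed(seed, {
    gs <- as.vector(scale(truth_target))
    z <- rnorm(n)
    z <- z - gs * (stats::cov(z, gs) * (n - 1) / n / pop_var(gs))
    z <- as.vector(scale(z))
    g_std <- target_corr * gs + sqrt(1 - target_corr^2) * z
    g <- scale_to_var(g_std, h2 * sd^2)
    eps <- rnorm(n)
    if (h2 < 1) {
      if (pop_var(g) > 0) {
        eps <- eps - g * (stats::cov(eps, g) * (n - 1) / n / pop_var(g))
      }
      eps <- scale_to_var(eps, (1 - h2) * sd^2)
    } else {
      eps <- rep(0, n)
    }
    list(phenotype = mean + g + eps, g = g)
  })
}

#' Discretize a latent trait onto an ordinal score
#'
#' Threshold (probit-style) discretization: thresholds are placed at the
#' latent quantiles so every category is populated for large samples, as
#' for a 0-9 visual disease score (0 = dead, 9 = unaffected).
#'
#' @param latent Numeric latent values (higher = higher category).
#' @param n_categories Number of score levels (default 10 for a 0-9 scale).
#' @return Integer scores in `0:(n_categories - 1)`, monotone in `latent`.
#' @export
simulate_ordinal <- function(latent, n_categories = 10) {
  if (n_categories < 2) abort("n_categories must be >= 2")
  br <- quantile(latent, probs = seq_len(n_categories - 1) / n_categories,
                 names = FALSE, type = 7)
  as.integer(findInterval(latent, br))
}
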