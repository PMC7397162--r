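# Shared fixtures and independent oracles used across test files.

worked_phenotypes <- function() {
  read_phenotypes(system.file("extdata", "table1_phenotypes.csv",
                              package = "ibcfgs"))
}

worked_similarity <- function() {
  read_similarity(system.file("extdata", "table3_similarity.csv",
                              package = "ibcfgs"))
}

# Literal transcription of the IBCF prediction for one cell: standardize
# with observed-cell mean and population SD, weight by pairwise-complete
# Pearson correlations of the raw columns, normalize by absolute weights,
# back-transform. Independent of the package's prediction path.
oracle_ibcf_cell <- function(m, i, J) {
  mu <- apply(m, 2, function(x) mean(x, na.rm = TRUE))
  sig <- apply(m, 2, function(x) {
    x <- x[!is.na(x)]
    sqrt(mean((x - mean(x))^2))
  })
  z <- sweep(sweep(m, 2, mu, "-"), 2, sig, "/")
  w <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  w[is.na(w)] <- 0
  nb <- setdiff(which(!is.na(m[i, ])), J)
  num <- sum(z[i, nb] * w[J, nb])
  den <- sum(abs(w[J, nb]))
  unname(if (den == 0) mu[J] else mu[J] + sig[J] * num / den)
}

# Random phenotype matrix with a controlled missingness pattern: every
# column keeps >= min_col_obs observed cells and every line >= 1.
random_pheno <- function(n_lines, n_items, n_miss, seed,
                         min_col_obs = 3L) {
  set.seed(seed)
  m <- matrix(rnorm(n_lines * n_items, mean = 5, sd = 2), n_lines, n_items,
              dimnames = list(sprintf("L%02d", seq_len(n_lines)),
                              LETTERS[seq_len(n_items)]))
  pool <- which(matrix(TRUE, n_lines, n_items))
  for (cell in sample(pool)) {
    if (n_miss == 0L) break
    cand <- m
    cand[cell] <- NA
    ok <- all(colSums(!is.na(cand)) >= min_col_obs) &&
      all(rowSums(!is.na(cand)) >= 1L)
    if (ok && !is.na(m[cell])) {
      m[cell] <- NA
      n_miss <- n_miss - 1L
    }
  }
  m
}

# Small simulated panel: genotypes plus single- or multi-environment
# phenotypes for quick scenario tests.
sim_panel <- function(n_lines, n_markers, seed, traits = NULL,
                      environments = NULL, rho_g = 0.2, h2 = NULL,
                      n_qtl = min(100L, n_markers), missing_rate = 0) {
  geno <- simulate_genotypes(n_lines, n_markers, seed = seed)
  if (is.null(traits)) traits <- default_trait_profiles()[1, ]
  if (is.null(environments)) {
    environments <- tibble::tibble(location = "LND", year = 2015L)
  }
  sim <- simulate_phenotypes(geno, traits = traits,
                             environments = environments, rho_g = rho_g,
                             n_qtl = n_qtl, h2 = h2,
                             missing_rate = missing_rate, seed = seed + 1)
  c(sim, list(geno = geno))
}

# Two-trait, two-year panel for the next-season scenario; rho controls the
# between-year genetic correlation of each trait.
sim_two_years <- function(n_lines, n_markers, rho, h2, seed) {
  traits <- tibble::tribble(
    ~trait, ~mean, ~sd, ~h2,
    "GY", 4.0, 0.6, h2,
    "PH", 85, 8.0, h2
  )
  envs <- tibble::tibble(location = "LND", year = c(2015L, 2016L))
  sim_panel(n_lines, n_markers, seed, traits = traits, environments = envs,
            rho_g = rho)
}
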