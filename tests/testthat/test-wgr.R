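# Desk-scale MCMC profile used throughout this file; the production
# defaults (20000 / 15000 / 5) are exercised only for their bookkeeping.
quick <- function(seed = NULL, n_iter = 1200, burn_in = 400, thin = 2) {
  mcmc_settings(n_iter, burn_in, thin, seed = seed)
}

sim_marker_data <- function(n, p, n_qtl, h2, seed) {
  set.seed(seed)
  geno <- simulate_genotypes(n, p, seed = seed)
  M <- ibcfgs:::geno_matrix(geno)
  qtl <- sample(p, n_qtl)
  g <- drop(scale(M[, qtl] %*% rnorm(n_qtl)))
  y <- sqrt(h2) * g + sqrt(1 - h2) * rnorm(n)
  list(M = M, y = y, g = g, geno = geno)
}

test_that("mcmc settings are validated", {
  expect_error(mcmc_settings(1000, 1000), "burn_in < n_iter")
  expect_error(mcmc_settings(1000, 500, thin = 0), "thin")
  s <- mcmc_settings()
  expect_equal(c(s$n_iter, s$burn_in, s$thin), c(20000L, 15000L, 5L))
})

test_that("samplers are deterministic given a seed and count kept samples", {
  d <- sim_marker_data(80, 60, 10, 0.5, seed = 51)
  for (mod in c("BRR", "BayesC", "BL")) {
    f1 <- fit_wgr(d$y, d$M, model = mod, settings = quick(seed = 1))
    f2 <- fit_wgr(d$y, d$M, model = mod, settings = quick(seed = 1))
    expect_equal(f1$beta, f2$beta)
    expect_equal(f1$sigma2_e, f2$sigma2_e)
    expect_equal(f1$kept_samples, 400L)  # (1200 - 400) / 2
  }
})

test_that("marker permutation leaves posterior means statistically unchanged", {
  d <- sim_marker_data(120, 60, 10, 0.6, seed = 52)
  long <- mcmc_settings(6000, 1000, 2, seed = 3)
  f1 <- fit_wgr(d$y, d$M, model = "BRR", settings = long)
  perm <- sample(ncol(d$M))
  f2 <- fit_wgr(d$y, d$M[, perm], model = "BRR", settings = long)
  b2 <- f2$beta[names(f1$beta)]
  expect_gt(cor(f1$beta, b2), 0.95)
  expect_lt(mean(abs(f1$beta - b2)), 0.02)
})

test_that("BRR with fixed variances matches the closed-form ridge solution", {
  d <- sim_marker_data(70, 40, 10, 0.5, seed = 53)
  s2e <- 0.6
  s2b <- 0.02
  f <- fit_wgr(d$y, d$M, model = "BRR",
               settings = mcmc_settings(20000, 2000, 2, seed = 4),
               fixed_hyper = list(sigma2_e = s2e, sigma2_b = s2b))
  Mc <- scale(d$M, scale = FALSE)
  ridge <- drop(solve(crossprod(Mc) + diag(s2e / s2b, ncol(Mc)),
                      crossprod(Mc, d$y - mean(d$y))))
  expect_lt(max(abs(f$beta - ridge)), 0.02)
})

test_that("pure-noise data yields heavily shrunk effects and chance accuracy", {
  accs <- numeric(5)
  for (s in 1:5) {
    set.seed(60 + s)
    geno <- simulate_genotypes(100, 50, seed = 60 + s)
    M <- ibcfgs:::geno_matrix(geno)
    y <- rnorm(100)
    f <- fit_wgr(y, M, model = "BRR", settings = quick(seed = s))
    Mc <- scale(M, scale = FALSE)
    lam <- f$sigma2_e / f$hyper$sigma2_b
    ridge <- drop(solve(crossprod(Mc) + diag(lam, ncol(Mc)),
                        crossprod(Mc, y - mean(y))))
    expect_lt(mean(abs(f$beta)), 3 * mean(abs(ridge)) + 1e-8)
    y_new <- rnorm(100)
    accs[s] <- cor(gebv(f, M), y_new)
  }
  expect_lt(abs(mean(accs)), 0.15)
})

test_that("gebv applies the training centring", {
  d <- sim_marker_data(60, 30, 5, 0.6, seed = 54)
  f <- fit_wgr(d$y, d$M, model = "BRR", settings = quick(seed = 5))
  expect_gt(cor(gebv(f, d$M), d$y), 0)
  # a line at the population mean has GEBV = mu
  mean_row <- matrix(colMeans(d$M), 1, dimnames = list("avg", colnames(d$M)))
  expect_equal(unname(gebv(f, mean_row)), f$mu, tolerance = 1e-10)
  # duplicated rows get identical values
  two <- d$M[c(1, 1), ]
  rownames(two) <- c("a", "b")
  bv <- gebv(f, two)
  expect_equal(bv[["a"]], bv[["b"]])
  expect_error(gebv(f, d$M[, 1:10]), "marker")
})

test_that("residual variance is recovered within 15 percent", {
  est <- vapply(1:6, function(s) {
    d <- sim_marker_data(400, 100, 40, 0.5, seed = 70 + s)
    f <- fit_wgr(d$y, d$M, model = "BRR", settings = quick(seed = s))
    f$sigma2_e
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.5) / 0.5, 0.15)
})

test_that("the LASSO prior shrinks null effects at least as hard as ridge", {
  diffs <- vapply(1:5, function(s) {
    set.seed(80 + s)
    geno <- simulate_genotypes(120, 60, seed = 80 + s)
    M <- ibcfgs:::geno_matrix(geno)
    qtl <- 1:5
    y <- drop(scale(M[, qtl] %*% rep(1, 5))) * sqrt(0.5) +
      sqrt(0.5) * rnorm(120)
    null_idx <- 6:60
    fb <- fit_wgr(y, M, model = "BL", settings = quick(seed = s))
    fr <- fit_wgr(y, M, model = "BRR", settings = quick(seed = s))
    mean(abs(fb$beta[null_idx])) - mean(abs(fr$beta[null_idx]))
  }, numeric(1))
  expect_lt(mean(diffs), 0.005)
})

test_that("BayesB is competitive with BRR under a sparse architecture", {
  delta <- vapply(1:5, function(s) {
    d <- sim_marker_data(150, 400, 20, 0.5, seed = 90 + s)
    hold <- sample(150, 30)
    fit2 <- function(mod) {
      f <- fit_wgr(d$y[-hold], d$M[-hold, ], model = mod,
                   settings = quick(seed = s))
      cor(gebv(f, d$M[hold, ]), d$y[hold])
    }
    fit2("BayesB") - fit2("BRR")
  }, numeric(1))
  expect_gt(mean(delta), -0.05)
})

test_that("adjust_traits recovers genetic values and skips thin items", {
  sim <- sim_panel(150, 100, seed = 95, h2 = 1,
                   environments = tibble::tibble(location = "LND",
                                                 year = c(2015L, 2016L)),
                   rho_g = 0.5)
  pheno <- sim$phenotypes
  # an item with too few observations must be skipped with a warning
  pheno$GY_LND_2016[-(1:10)] <- NA
  expect_warning(
    adj <- adjust_traits(pheno, sim$geno, model = "BRR",
                         settings = quick(seed = 6)),
    "skipping item"
  )
  expect_true(all(is.na(adj$adjusted$GY_LND_2016)))
  truth <- sim$truth[sim$truth$item == "GY_LND_2015", ]
  r <- cor(adj$adjusted$GY_LND_2015,
           truth$g[match(adj$adjusted$line, truth$line)])
  expect_gt(r, 0.9)
})

test_that("strict marker-IBCF never reads test-line target phenotypes", {
  sim <- sim_panel(90, 80, seed = 96, h2 = 0.8,
                   environments = tibble::tibble(
                     location = "LND", year = c(2015L, 2016L, 2017L)),
                   rho_g = 0.7)
  pheno <- sim$phenotypes
  plan <- make_partitions(pheno$line, 1, 0.2, seed = 7)
  target <- "GY_LND_2015"
  settings <- quick(seed = 8, n_iter = 600, burn_in = 200)
  clean <- scenario_marker_ibcf(pheno, sim$geno, plan, model = "BRR",
                                settings = settings, target_items = target,
                                min_obs = 20)
  poisoned <- pheno
  test1 <- ibcfgs:::test_lines(plan, 1)
  poisoned[[target]][poisoned$line %in% test1] <-
    poisoned[[target]][poisoned$line %in% test1] + 1000
  dirty <- scenario_marker_ibcf(poisoned, sim$geno, plan, model = "BRR",
                                settings = settings, target_items = target,
                                min_obs = 20)
  expect_equal(dirty$predictions$predicted, clean$predictions$predicted)
  expect_equal(dirty$predictions$observed,
               clean$predictions$observed + 1000)

  # the package-style mode does read them (adjustment before masking)
  loose_clean <- scenario_marker_ibcf(pheno, sim$geno, plan, model = "BRR",
                                      settings = settings,
                                      target_items = target,
                                      leakage_guard = "package",
                                      min_obs = 20)
  loose_dirty <- scenario_marker_ibcf(poisoned, sim$geno, plan,
                                      model = "BRR", settings = settings,
                                      target_items = target,
                                      leakage_guard = "package",
                                      min_obs = 20)
  expect_false(isTRUE(all.equal(loose_dirty$predictions$predicted,
                                loose_clean$predictions$predicted)))
})

test_that("BL and BRR adjustments give overlapping accuracy bands", {
  sim <- sim_panel(100, 120, seed = 97, h2 = 0.8,
                   environments = tibble::tibble(
                     location = "LND", year = c(2015L, 2016L, 2017L)),
                   rho_g = 0.8)
  plan <- make_partitions(sim$phenotypes$line, 4, 0.2, seed = 9)
  run <- function(mod) {
    res <- scenario_marker_ibcf(sim$phenotypes, sim$geno, plan, model = mod,
                                settings = quick(seed = 10, n_iter = 600,
                                                 burn_in = 200),
                                target_items = "GY_LND_2015", min_obs = 20)
    s <- summarize_scenario(res)
    s[s$metric == "predictive_ability", ]
  }
  a <- run("BL")
  b <- run("BRR")
  expect_true(a$mean - 2 * a$se <= b$mean + 2 * b$se &&
                b$mean - 2 * b$se <= a$mean + 2 * a$se)
})
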